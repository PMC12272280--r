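---
title: "Methods: effect-based water-quality evaluation with waterbeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effect-based water-quality evaluation with waterbeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`waterbeq` evaluates water quality from the *effects* water extracts cause
in high-throughput in vitro bioassays, rather than from chemical
concentrations alone. Samples are dosed as serial dilutions expressed in
relative enrichment factor (REF: litres of original water per litre of
bioassay medium). The package covers the complete chain from raw 384-well
plate signals to regulatory verdicts:

1. normalization of raw signals to an effect scale (or induction ratio),
2. concentration-response fitting and benchmark derivation
   (EC10, EC at induction ratio 1.5, cytotoxicity IC10) with standard
   errors,
3. cytotoxicity masking and activity classification,
4. bioanalytical equivalent concentrations (BEQ) with propagated
   uncertainty, specificity ratios and effect-based trigger (EBT) verdicts,
5. concentration-addition "iceberg" modeling against quantified chemicals,
6. a ground-truth synthetic-data generator so the whole chain is testable
   without laboratory data.

# Models and procedure

## Normalization

For receptor-activation and neurite-outgrowth endpoints, raw signals are
normalized against the plate's negative controls (effect 0) and the fitted
maximum of the plate's own reference-compound curve (effect 1):

    effect = (signal - mean(controls)) / (top_reference - mean(controls))

Oxidative-stress endpoints use the induction ratio instead:

    IR = signal / mean(control signals)

Anchoring the top at the reference curve's fitted plateau, not the
sample's, lets sub-maximal sample curves remain on a common absolute effect
scale across plates.

## Concentration-response fitting

Below roughly 30% absolute effect, concentration-response curves are
indistinguishable from straight lines through the origin; the low-effect
benchmarks can therefore be read from a linear regression with zero
intercept restricted to points with effect <= 0.30 (IR - 1 <= 1.5 for
induction ratios):

    EC10      = 0.1 / slope          SE = 0.1 / slope^2 * SE(slope)
    EC_IR1.5  = 0.5 / slope          SE = 0.5 / slope^2 * SE(slope)

Full curves (neurite outgrowth, and cytotoxicity for the non-linear
archetypes) are fitted with the four-parameter log-logistic model

    y(x) = bottom + (top - bottom) / (1 + exp(hill * (log(EC50) - log(x))))

by Levenberg-Marquardt least squares (`minpack.lm::nlsLM`) on the
`(bottom, top, log EC50, hill)` parameterization, with a deterministic
multi-start grid (Hill in {0.5, 1, 2, 4}, EC50 starts at the 25/50/75%
response quantiles) so the fit never depends on random initialization.
Benchmark concentrations are obtained by inverting the fitted curve, and
their standard errors by the delta method on the fitted covariance
(central-difference gradients).

Per-archetype fit routes:

| archetype            | effect benchmark         | cytotoxicity IC10 |
|----------------------|--------------------------|-------------------|
| receptor activation  | linear EC10              | linear            |
| oxidative stress     | linear EC_IR1.5          | log-logistic      |
| neurite outgrowth    | log-logistic EC10        | log-logistic      |

## Confidence gate and masking

Each benchmark carries a confidence score

    confidence = (1 - SE/value) * R^2

and estimates below the threshold (default 0.7) are referred to manual
review rather than silently used. Three masking rules protect specificity:

* wells with viability <= 0.90 (10% or more cytotoxicity) never enter
  effect fits — the boundary is inclusive;
* wells at REF strictly above the sample's IC10 are excluded from effect
  fits (the point at the IC10 itself is kept);
* a sample whose effect benchmark exceeds its IC10 (specificity ratio
  < 1) is classified `masked_by_cytotoxicity` and releases no EC or BEQ.

Samples whose curve never reaches the benchmark level below the maximum
tested REF are `inactive`; the maximum tested REF is reported so
"inactive" always means "inactive up to this enrichment".

## BEQ, specificity and triggers

The bioanalytical equivalent concentration expresses the whole sample as
an equivalent concentration of the assay's reference compound:

    BEQ_bio = EC_reference / EC_sample
    SE_BEQ  = sqrt( SE_ref^2 / EC_s^2  +  EC_ref^2 * SE_s^2 / EC_s^4 )

with the reference EC fitted on the same plate (low and high dosing ranges
merged). The specificity ratio SR = IC10 / EC separates specific effects
(SR >> 1) from cytotoxicity bursts. A sample exceeds the effect-based
trigger value when BEQ_bio is strictly greater than the assay's EBT;
masked or inactive samples are not evaluable and keep an `NA` verdict.
Unit agreement between BEQ and EBT is enforced; there is no silent
conversion.

## Iceberg modeling

Under concentration addition, each quantified chemical `i` with a
literature benchmark `EC_i` contributes

    REP_i = EC_reference / EC_i        BEQ_i = REP_i * c_i

and the predicted mixture effect is `BEQ_chem = sum(BEQ_i)` over the
chemicals with known bioactivity (the others are counted, not summed).
The fraction of the measured effect explained by known chemistry is

    %explained = 100 * BEQ_chem / BEQ_bio

and is deliberately never clipped: values above 100% are diagnostic
(reference EC mismatch, co-elution, antagonism). Contributions are ranked
with lexicographic tie-breaks so reports are reproducible, and the number
of chemicals needed to reach 90% of `BEQ_chem` summarizes how top-heavy
the mixture is.

# Key parameters and defaults

* `linear_cutoff = 0.30` — the absolute effect level below which linearity
  is assumed; also sets the IR window via `IR - 1 <= cutoff * 5`.
* `viability_threshold = 0.90` (inclusive) — the masking boundary.
* `confidence_threshold = 0.7` — the manual-review gate.
* Maximum REF per sample type: surface water 100, WWTP effluent 50, WWTP
  influent 25 — dirtier matrices cannot be enriched as far without assay
  interference.
* Serial dilution: 11 points, factor 2 — covers three orders of magnitude
  from the maximum REF.
* EBTs shipped with the default battery: 250 ng/L BaP-EQ (AhR),
  1.4e6 ng/L Dichlorvos-EQ (AREc32), 0.34 ng/L EEQ (ERalpha), 283 ng/L
  Narciclasine-EQ (SH-SY5Y neurite outgrowth).

# The synthetic generator

The generator is first-class API, not a test helper: it produces full
384-well plates (16 rows x 24 columns) with the screening layout — row A
holds the reference compound in overlapping low and high ranges, rows B-N
hold up to 26 sample series of 11 two-fold dilutions, rows O-P hold 48
negative controls — plus matched chemical-quantification tables with known
`BEQ_chem` truth, and it attaches the complete ground truth to every
plate.

Design choices worth stating explicitly:

* **Noise model.** Signals carry multiplicative lognormal noise (default
  CV 5%), matching the behaviour of luminescence/fluorescence readouts;
  viability carries additive normal noise (SD 0.02).
* **Truth curves.** For archetypes evaluated linearly the generating
  effect curve is itself linear through the origin (capped at the
  plateau): the linearity of low-effect responses is a domain fact the
  evaluation relies on, and simulating from a curved model while fitting a
  line would measure model mismatch, not implementation correctness. The
  neurite-outgrowth archetype, which is fitted log-logistically, is
  generated from a log-logistic truth. Cytotoxicity has its own
  independent truth curve; `cytotoxic_suppression = TRUE` optionally
  multiplies the effect signal by the viable fraction to emulate signal
  loss in dying cells.
* **Reference calibration.** The reference curve's lower asymptote is the
  negative-control level by construction, so calibration fixes the bottom
  at the control mean (at IR = 1 for induction-ratio endpoints) and
  weights residuals by 1/signal^2 (the multiplicative-noise weighting).
  Both choices follow from the data-generating process, not from tuning.
* **Determinism.** Every generator function takes a seed and restores the
  caller's RNG state (`with_seed_local()`), so identical seeds give
  byte-identical studies and downstream reports.
* **Limitations.** The generator does not model plate-position (edge)
  effects, carry-over, autofluorescence, or correlated noise between the
  effect and viability channels beyond the optional suppression mode; it
  emulates the dosing design, not liquid-handling artefacts.

# Validation conventions

Propagated standard errors are validated against Monte-Carlo simulation.
Because reciprocals and ratios of normal variables have no finite second
moment, the plain Monte-Carlo standard deviation does not converge; the
comparison therefore uses the central 68.27% half-width of the
Monte-Carlo distribution (the sigma-equivalent robust spread), which
agrees with first-order propagation within 5% for input CVs up to 20%.

Self-chosen validation sizes: formula oracles run on 25 randomized cases
each; benchmark recovery uses 200 noisy curves per archetype at the
default 5% CV (acceptance: >= 90% of valid estimates within +/- 25% of
truth, median absolute relative error < 10%); trigger-value classification
power uses 200 samples at 3x the trigger and 200 at 0.3x.

# Worked example

```{r, eval = FALSE}
library(waterbeq)

study <- simulate_study(n_samples = 10, seed = 42)
result <- run_pipeline(study)
summarize_run(result)

head(result$sample_report)
head(result$iceberg_report)
```

See the README for an executed version with printed output.
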