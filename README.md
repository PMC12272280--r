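# waterbeq

Effect-based evaluation of water quality from high-throughput in vitro
bioassay plate data.

## The problem

Chemical monitoring quantifies a few hundred target compounds, but water
samples contain thousands of chemicals plus their mixtures. Effect-based
methods take the complementary route: dose concentrated water extracts
into cell-based bioassays (receptor activation, oxidative stress, neurite
outgrowth) as serial dilutions expressed in **relative enrichment factor**
(REF, litres of original water per litre of bioassay medium), and read
water quality off the *effect* the whole mixture causes. `waterbeq`
implements the complete evaluation chain from raw 384-well signals to
regulatory verdicts, plus a ground-truth synthetic-data generator that
makes every stage testable without laboratory data.

## Core quantities

Signals are normalized to the plate's negative controls and the fitted
maximum of the plate's own reference-compound curve; oxidative-stress
assays use the induction ratio `IR = signal / mean(controls)` instead.
Below ~30% effect, concentration-response curves are linear through the
origin, so low-effect benchmark concentrations come from a zero-intercept
regression:

```
EC10     = 0.1 / slope        SE(EC10)     = 0.1 / slope^2 * SE(slope)
EC_IR1.5 = 0.5 / slope        SE(EC_IR1.5) = 0.5 / slope^2 * SE(slope)
```

Full curves use the four-parameter log-logistic model fitted by
Levenberg-Marquardt least squares with deterministic multi-start; each
benchmark carries a confidence score `(1 - SE/value) * R^2` gated at 0.7.
Cytotoxicity is handled by three rules: wells at viability <= 0.90 never
enter effect fits, wells above the sample's IC10 are excluded, and a
sample whose effect benchmark exceeds its IC10 is
`masked_by_cytotoxicity` (specificity ratio `SR = IC10 / EC < 1`).

Benchmarks convert to **bioanalytical equivalent concentrations**:

```
BEQ_bio = EC_reference / EC_sample
SE_BEQ  = sqrt( SE_ref^2 / EC_s^2 + EC_ref^2 * SE_s^2 / EC_s^4 )
```

compared against **effect-based trigger values** (e.g. 0.34 ng/L
estradiol-EQ for ERalpha); exceedance is strict. **Iceberg modeling**
predicts the mixture effect from quantified chemicals under concentration
addition, `BEQ_chem = sum( (EC_ref / EC_i) * c_i )`, and reports
`%explained = 100 * BEQ_chem / BEQ_bio` — never clipped, since values
above 100% are diagnostic.

## Worked example

```r
library(waterbeq)

study  <- simulate_study(n_samples = 8, seed = 42)   # 4-assay battery
result <- run_pipeline(study)
summarize_run(result)
#>   assay_id n_samples frac_active frac_masked frac_inactive frac_needs_review
#> 1      AhR         8       1.000       0.000         0.000                 0
#> 2   AREc32         8       0.875       0.125         0.000                 0
#> 3  ERalpha         8       0.875       0.000         0.125                 0
#> 4   SHSY5Y         8       0.625       0.000         0.375                 0
#>   n_ebt_evaluated n_ebt_exceeded   sr_q25 sr_median   sr_q75
#> 1               8              0 3.766368  5.148558 6.152290
#> 2               7              0 1.076804  1.243386 3.732040
#> 3               7              0 2.092954  3.258864 5.458888
#> 4               5              0       NA        NA       NA

subset(result$sample_report, assay_id == "ERalpha" & sample_id %in% c("S04", "S06"),
       select = c(sample_id, ec_value_REF, ec_se, ic10_REF, sr_cytotoxicity,
                  beq_bio, se_beq, ebt_exceeded, status))
#>    sample_id ec_value_REF     ec_se ic10_REF sr_cytotoxicity    beq_bio
#> 20       S04    11.233817 0.5942029 24.89585        2.216152 0.06402500
#> 22       S06     5.404541 0.1744264 23.24804        4.301575 0.13308163
#>         se_beq ebt_exceeded status
#> 20 0.004721088        FALSE  valid
#> 22 0.008074391        FALSE  valid
```

A single call gives the BEQ arithmetic directly:

```r
beq_bio(0.68, 2, 0.068, 0.2)   # EC_ref 0.68 ng/L, sample EC10 at REF 2
#> $beq_bio
#> [1] 0.34
#> $se_beq
#> [1] 0.04808326
```

With `phi`, the generator couples the chemical table to the plate truths
so quantified chemicals explain a known fraction of the measured effect —
the controlled setting for iceberg modeling:

```r
cfg <- assay_config("ERalpha", "receptor_activation", "estradiol", "ng/L",
                    benchmark = "EC10", ebt_value = 0.34)
st  <- simulate_study(assays = list(ERalpha = cfg), n_samples = 6, seed = 7,
                      n_chemicals = 40, inactive_fraction = 0, phi = 0.85)
res <- run_pipeline(st)
res$iceberg_report[, c("sample_id", "beq_chem", "beq_bio", "pct_explained", "n_to_90pct")]
#>   sample_id   beq_chem    beq_bio pct_explained n_to_90pct
#> 1       S01 0.03048284 0.03401097      89.62649          6
#> 2       S02 0.10248976 0.11738281      87.31241          3
#> 3       S03 0.03987832 0.04667892      85.43110          6
#> 4       S04 0.27373546 0.30689230      89.19594          4
#> 5       S05 0.01586827 0.01584589     100.14122          3
#> 6       S06 0.07366392 0.08349121      88.22955          4

head(res$driver_table[res$driver_table$sample_id == "S01",
                      c("chemical_id", "category", "rep", "beq_i", "pct_of_beq_chem")], 3)
#>   chemical_id         category       rep       beq_i pct_of_beq_chem
#> 1     chem014   pharmaceutical 0.6985096 0.010208262        33.48856
#> 2     chem034       industrial 0.2021715 0.009312988        30.55158
#> 3     chem015 polymer_additive 0.5024890 0.003074082        10.08463
```

The true closure is 85%; the recovered values scatter around it within
fit noise.

## File-driven use

`inst/scripts/run-pipeline.R` wraps the same pipeline for the command
line:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run-pipeline.R", package="waterbeq"))')" \
    simulate --seed 1 --n-samples 10 --dir study/
Rscript "$(Rscript -e 'cat(system.file("scripts/run-pipeline.R", package="waterbeq"))')" \
    analyse --dir study/ --out reports/
```

## Documentation

Function documentation lives in the roxygen comments in `R/`; the methods
vignette (`vignettes/effect-based-evaluation.Rmd`) describes the models,
assumptions, parameter defaults, the synthetic generator's scope and
limitations, and the package's validation conventions.
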