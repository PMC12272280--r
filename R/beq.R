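#' Calibrate the reference compound on one plate
#'
#' Reference compounds are dosed on every plate in a low and a high
#' concentration range, overlapping around 50\% effect. The two ranges are
#' merged and fitted with the four-parameter log-logistic model; the
#' benchmark concentration of the reference compound (EC10 at 10\% of the
#' fitted span, or EC_IR1.5 for induction-ratio endpoints) anchors the
#' bioanalytical equivalent concentration, and the fitted maximum response
#' anchors the 100\% effect scale for sample normalization. The plate passes
#' quality control when the reference benchmark falls inside the configured
#' historical band; failing plates are excluded from BEQ derivation.
#'
#' @param low,high data.frames with columns `conc` (reference-compound
#'   concentration in the assay's reference unit) and `response` (raw signal
#'   or induction ratio).
#' @param assay An [assay_config()]; its `benchmark` selects the crossing
#'   (EC10 relative 10\%, or absolute IR 1.5) and its `qc_band` the QC
#'   limits (no band: QC passes by definition).
#' @param plate_id Label carried into the result.
#' @param control_signals Optional negative-control signals from the same
#'   plate. The reference curve's lower asymptote is the unexposed-cell
#'   level by construction, so when controls are supplied the bottom is
#'   fixed at their mean (at IR = 1 for induction-ratio endpoints), which
#'   removes the bottom-hill trade-off and tightens the extrapolated
#'   benchmark considerably.
#' @return Object of class `reference_calibration`: `assay_id`, `plate_id`,
#'   `ec10_reference`, `se`, `qc_pass`, `fit` (the merged
#'   `log_logistic_fit`).
#' @export
calibrate_reference <- function(low, high, assay, plate_id = NA_character_,
                                control_signals = NULL) {
  stopifnot(inherits(assay, "assay_config"))
  if (is.null(low) || is.null(high) || !nrow(low) || !nrow(high))
    wb_validation_error("both low and high reference ranges are required")
  merged <- data.frame(conc = c(low$conc, high$conc),
                       response = c(low$response, high$response))
  fixed_bottom <- if (assay$endpoint_kind == "oxidative_stress") 1
                  else if (!is.null(control_signals)) mean(control_signals)
                  else NULL
  # raw-signal (and IR) noise is close to multiplicative
  fit <- fit_log_logistic(merged, fixed_bottom = fixed_bottom,
                          weights = 1 / merged$response^2)
  est <- if (assay$benchmark == "EC_IR1.5") {
    benchmark_from_log_logistic(fit, "EC_IR1.5", level = 1.5, relative = FALSE)
  } else {
    benchmark_from_log_logistic(fit, "EC10", level = 0.10, relative = TRUE)
  }
  if (is.na(est$value))
    wb_fit_failure("reference curve never reaches its benchmark level")
  qc_pass <- TRUE
  if (!is.null(assay$qc_band))
    qc_pass <- est$value >= assay$qc_band[1] && est$value <= assay$qc_band[2]
  structure(list(
    assay_id = assay$assay_id,
    plate_id = plate_id,
    ec10_reference = est$value,
    se = est$se,
    qc_pass = qc_pass,
    fit = fit
  ), class = "reference_calibration")
}

#' @export
print.reference_calibration <- function(x, ...) {
  cat(sprintf("<reference_calibration> %s plate %s: EC_ref = %.4g +/- %.3g (QC %s)\n",
              x$assay_id, x$plate_id, x$ec10_reference, x$se,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Bioanalytical equivalent concentration with propagated uncertainty
#'
#' `BEQ_bio = EC_reference / EC_sample`: the concentration of the assay's
#' reference compound that would produce the same response as the whole
#' water sample. With the sample benchmark in REF (litres of water per litre
#' of bioassay), the BEQ carries the reference compound's concentration unit
#' per litre of original water. The standard error follows from first-order
#' error propagation:
#' `SE_BEQ = sqrt( SE(EC_ref)^2 / EC_sample^2 +
#'                 EC_ref^2 * SE(EC_sample)^2 / EC_sample^4 )`.
#'
#' @param ec_reference Reference-compound benchmark (e.g. ng/L).
#' @param ec_sample Sample benchmark in REF.
#' @param se_reference,se_sample Standard errors (default 0).
#' @return list with `beq_bio` and `se_beq`.
#' @examples
#' beq_bio(0.68, 2, 0.068, 0.2)  # 0.34 ng/L EEQ +/- ~0.048
#' @export
beq_bio <- function(ec_reference, ec_sample, se_reference = 0, se_sample = 0) {
  if (!is.finite(ec_reference) || ec_reference <= 0)
    wb_validation_error("ec_reference must be finite and > 0")
  if (!is.finite(ec_sample) || ec_sample <= 0)
    wb_validation_error("ec_sample must be finite and > 0")
  list(
    beq_bio = ec_reference / ec_sample,
    se_beq = sqrt(se_reference^2 / ec_sample^2 +
                    ec_reference^2 * se_sample^2 / ec_sample^4)
  )
}

#' Specificity ratio of an effect versus cytotoxicity
#'
#' `SR_cytotoxicity = IC10 / EC`. Ratios near 1 mean the apparent effect
#' tracks cytotoxicity (nonspecific); large ratios mean the effect occurs
#' well below cytotoxic concentrations. `SR < 1` marks an effect masked by
#' cytotoxicity: no EC is released for such samples (see
#' [classify_activity()]).
#'
#' @param ic10 Cytotoxicity IC10 in REF, or `NA`.
#' @param ec Specific-effect benchmark in REF, or `NA`.
#' @return Numeric ratio, or `NA` when either input is absent.
#' @examples
#' specificity_ratio(20, 2)  # 10: specific
#' @export
specificity_ratio <- function(ic10, ec) {
  if (is.na(ic10) || is.na(ec)) return(NA_real_)
  if (ic10 <= 0 || ec <= 0)
    wb_validation_error("specificity ratio requires positive concentrations")
  ic10 / ec
}

#' BEQ result container
#'
#' @param sample_id,assay_id Labels.
#' @param beq_bio,se_beq BEQ and its SE in `unit` per litre of water.
#' @param unit Reference-equivalent unit (e.g. `"ng/L"`).
#' @param sr_cytotoxicity Specificity ratio, or `NA`.
#' @param status Propagated from the underlying [effect_estimate()].
#' @return Object of class `beq_result` (EBT fields unset until
#'   [ebt_verdict()] is applied).
#' @export
beq_result <- function(sample_id, assay_id, beq_bio = NA_real_,
                       se_beq = NA_real_, unit = "ng/L",
                       sr_cytotoxicity = NA_real_, status = "valid") {
  if (status == "valid" && (is.na(beq_bio) || beq_bio <= 0))
    wb_validation_error("a valid BEQ result requires beq_bio > 0")
  structure(list(sample_id = sample_id, assay_id = assay_id,
                 beq_bio = beq_bio, se_beq = se_beq, unit = unit,
                 sr_cytotoxicity = sr_cytotoxicity,
                 ebt_exceeded = NA, exceedance_ratio = NA_real_,
                 status = status),
            class = "beq_result")
}

#' @export
print.beq_result <- function(x, ...) {
  if (x$status == "valid") {
    cat(sprintf("<beq_result> %s / %s: BEQ = %.4g +/- %.3g %s (SR %.3g, EBT %s)\n",
                x$sample_id, x$assay_id, x$beq_bio, x$se_beq, x$unit,
                x$sr_cytotoxicity,
                if (is.na(x$ebt_exceeded)) "not evaluated"
                else if (x$ebt_exceeded) "EXCEEDED" else "ok"))
  } else {
    cat(sprintf("<beq_result> %s / %s: %s\n", x$sample_id, x$assay_id, x$status))
  }
  invisible(x)
}

#' Compare a BEQ against the effect-based trigger value
#'
#' Flags the sample when its bioanalytical equivalent concentration strictly
#' exceeds the assay's effect-based trigger value (EBT); the exceedance
#' ratio BEQ/EBT is recorded. Units must match the assay configuration -
#' conversion is never silent. Masked or inactive samples are not evaluable
#' and keep `ebt_exceeded = NA`.
#'
#' @param beq A [beq_result()].
#' @param config The [assay_config()] carrying `ebt_value` and
#'   `reference_unit`.
#' @return The updated [beq_result()].
#' @export
ebt_verdict <- function(beq, config) {
  stopifnot(inherits(beq, "beq_result"), inherits(config, "assay_config"))
  if (is.na(config$ebt_value)) return(beq)
  if (!identical(beq$unit, config$reference_unit))
    wb_unit_error(sprintf("BEQ unit '%s' does not match assay unit '%s'",
                          beq$unit, config$reference_unit))
  if (beq$status != "valid" || is.na(beq$beq_bio)) {
    beq$ebt_exceeded <- NA
    return(beq)
  }
  beq$ebt_exceeded <- beq$beq_bio > config$ebt_value
  beq$exceedance_ratio <- beq$beq_bio / config$ebt_value
  beq
}

#' Coefficient of variation across lateral sampling positions
#'
#' Summarizes how much a site's BEQ or EC varies across the river
#' cross-section (left/middle/right sampling): `CV = 100 * sd / mean`
#' (sample standard deviation), computed over the finite values. When some
#' positions are masked or inactive the CV is computed over the remainder
#' and flagged partial.
#'
#' @param values Numeric BEQ or EC values per lateral position (`NA` for
#'   masked/inactive positions).
#' @return list: `cv` (percent, `NA` when undefined), `n_used`, `n_total`,
#'   `partial`, `defined`.
#' @examples
#' lateral_cv(c(2, 4))  # 47.14
#' @export
lateral_cv <- function(values) {
  n_total <- length(values)
  v <- values[is.finite(values)]
  if (length(v) < 2L)
    wb_insufficient_data("lateral CV requires >= 2 finite values")
  m <- mean(v)
  defined <- m > 0
  list(cv = if (defined) 100 * stats::sd(v) / m else NA_real_,
       n_used = length(v), n_total = n_total,
       partial = length(v) < n_total, defined = defined)
}
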