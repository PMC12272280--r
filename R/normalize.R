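#' Construct a normalized concentration-response series
#'
#' @param sample_id,assay_id Labels.
#' @param ref Numeric REF values (L water / L bioassay), any order.
#' @param response Numeric response aligned to `ref`: effect fraction of the
#'   reference maximum, induction ratio (IR), or viability-inhibition
#'   fraction, per `response_type`.
#' @param viability Per-point viability as fraction of control (optional,
#'   used by [apply_viability_mask()]).
#' @param response_type `"effect"`, `"ir"` or `"viability_inhibition"`.
#' @return Object of class `normalized_series`; points sorted ascending in
#'   REF, with an (initially empty) `excluded` table carrying exclusion
#'   reasons.
#' @export
normalized_series <- function(sample_id, assay_id, ref, response,
                              viability = rep(NA_real_, length(ref)),
                              response_type = c("effect", "ir", "viability_inhibition")) {
  response_type <- match.arg(response_type)
  stopifnot(length(ref) == length(response), length(viability) == length(ref))
  if (any(!is.finite(ref)) || any(ref <= 0))
    wb_validation_error("REF values must be finite and > 0")
  if (response_type == "ir" && any(response < 0, na.rm = TRUE))
    wb_validation_error("induction ratios must be >= 0")
  ord <- order(ref)
  pts <- data.frame(ref = ref[ord], response = response[ord],
                    viability = viability[ord])
  structure(list(
    sample_id = sample_id,
    assay_id = assay_id,
    response_type = response_type,
    points = pts,
    excluded = data.frame(ref = numeric(0), response = numeric(0),
                          viability = numeric(0), reason = character(0),
                          stringsAsFactors = FALSE)
  ), class = "normalized_series")
}

#' @export
print.normalized_series <- function(x, ...) {
  cat(sprintf("<normalized_series> %s / %s (%s): %d points, %d excluded\n",
              x$sample_id, x$assay_id, x$response_type,
              nrow(x$points), nrow(x$excluded)))
  invisible(x)
}

exclude_points <- function(series, idx, reason) {
  if (!length(idx)) return(series)
  moved <- series$points[idx, , drop = FALSE]
  moved$reason <- reason
  series$excluded <- rbind(series$excluded, moved)
  series$points <- series$points[-idx, , drop = FALSE]
  rownames(series$points) <- NULL
  rownames(series$excluded) <- NULL
  series
}

#' Normalize raw sample signals to the reference-compound effect scale
#'
#' Maps raw well signals onto the fraction-of-maximum effect scale by
#' anchoring 0\% at the plate's negative-control mean and 100\% at the fitted
#' maximum response (top) of the plate's reference compound:
#' `effect = (signal - mean(controls)) / (top - mean(controls))`. Small
#' negative effects from noise are retained; clipping would bias slopes near
#' zero.
#'
#' @param sample_id,assay_id Labels for the resulting series.
#' @param ref REF of each sample well.
#' @param signal Raw signal (e.g. RLU) of each sample well.
#' @param control_signals Raw signals of all negative-control wells on the
#'   same plate.
#' @param reference_fit [fit_log_logistic()] result for the plate's
#'   reference compound, on the raw signal scale.
#' @param viability Optional per-well viability fractions.
#' @return A `normalized_series` with `response_type = "effect"`.
#' @export
normalize_effect <- function(sample_id, assay_id, ref, signal, control_signals,
                             reference_fit, viability = rep(NA_real_, length(ref))) {
  ctrl <- mean(control_signals)
  top <- reference_fit$top
  if (!is.finite(top) || top <= ctrl)
    wb_degenerate_error("reference maximum response does not exceed the control mean")
  effect <- (signal - ctrl) / (top - ctrl)
  normalized_series(sample_id, assay_id, ref, effect,
                    viability = viability, response_type = "effect")
}

#' Induction ratio
#'
#' Ratio of a sample well's signal to the mean signal of unexposed
#' (negative-control) cells. The induction ratio replaces the effect scale
#' for oxidative-stress assays, where no reference maximum exists; the
#' activity benchmark is the concentration reaching IR = 1.5.
#'
#' @param signal Numeric vector of sample signals (RLU).
#' @param control_signals Signals of unexposed control wells (>= 1 well).
#' @return Numeric vector of induction ratios.
#' @examples
#' induction_ratio(3000, c(1800, 2200, 2000, 2000))
#' @export
induction_ratio <- function(signal, control_signals) {
  if (!length(control_signals))
    wb_degenerate_error("at least one control well is required")
  m <- mean(control_signals)
  if (!is.finite(m) || m <= 0)
    wb_degenerate_error("control mean must be > 0")
  signal / m
}

#' Exclude cytotoxic concentrations by the viability rule
#'
#' Concentrations reducing cell viability by 10\% or more (viability at or
#' below 0.90 of the negative control) are excluded from effect evaluation;
#' excluded points are moved to the series' exclusion table with reason
#' `"viability"`.
#'
#' @param series A `normalized_series` whose points carry viability.
#' @param viability Optional viability vector overriding the stored one
#'   (aligned to the sorted points).
#' @param threshold Exclusion boundary (default 0.90, inclusive).
#' @return The filtered `normalized_series`. An empty retained set is legal;
#'   downstream fits handle it.
#' @export
apply_viability_mask <- function(series, viability = NULL, threshold = 0.90) {
  stopifnot(inherits(series, "normalized_series"))
  if (!is.null(viability)) {
    stopifnot(length(viability) == nrow(series$points))
    series$points$viability <- viability
  }
  v <- series$points$viability
  idx <- which(!is.na(v) & v <= threshold)
  exclude_points(series, idx, "viability")
}

#' Exclude concentrations above the cytotoxicity IC10
#'
#' Points at REF strictly above the sample's cytotoxicity IC10 are removed
#' from the effect concentration-response curve (reason `"cytotoxicity"`),
#' so specific-effect benchmarks are derived only from concentrations where
#' the cells are viable. A point exactly at the IC10 is kept.
#'
#' @param series A `normalized_series`.
#' @param ic10 An [effect_estimate()] of kind `"IC10"`, or `NULL`/non-valid
#'   when no cytotoxicity was observed up to the maximum tested REF (series
#'   returned unchanged).
#' @return The filtered `normalized_series`.
#' @export
mask_above_ic10 <- function(series, ic10) {
  stopifnot(inherits(series, "normalized_series"))
  if (is.null(ic10) || is.na(ic10$value) || ic10$status == "inactive")
    return(series)
  idx <- which(series$points$ref > ic10$value)
  exclude_points(series, idx, "cytotoxicity")
}
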