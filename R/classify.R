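#' Classify a benchmark estimate against cytotoxicity and the tested range
#'
#' Applies the activity rules after fitting: a sample that never reaches its
#' benchmark within the tested concentration range is `inactive` (the
#' highest tested REF is recorded); a benchmark lying above the
#' cytotoxicity IC10 is not a specific effect — cytotoxicity sets in first —
#' and the estimate is `masked_by_cytotoxicity` (equivalently, specificity
#' ratio IC10/EC < 1); everything else keeps its current status (`valid`,
#' or `needs_manual_review` from the confidence gate, which is sticky).
#'
#' @param effect_est [effect_estimate()] for the specific effect.
#' @param ic10 [effect_estimate()] of kind `"IC10"` from the same sample and
#'   assay, or `NULL` when no cytotoxicity was observed.
#' @param max_ref Highest tested REF for this sample.
#' @return The reclassified effect [effect_estimate()].
#' @export
classify_activity <- function(effect_est, ic10 = NULL, max_ref = NA_real_) {
  stopifnot(inherits(effect_est, "effect_estimate"))
  effect_est$max_ref <- max_ref
  if (is.na(effect_est$value) || effect_est$status == "inactive") {
    effect_est$status <- "inactive"
    effect_est$value <- NA_real_
    effect_est$se <- NA_real_
    return(effect_est)
  }
  if (is.finite(max_ref) && effect_est$value > max_ref) {
    effect_est$status <- "inactive"
    effect_est$value <- NA_real_
    effect_est$se <- NA_real_
    return(effect_est)
  }
  if (!is.null(ic10) && !is.na(ic10$value) && effect_est$value > ic10$value) {
    effect_est$status <- "masked_by_cytotoxicity"
    return(effect_est)
  }
  effect_est
}
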