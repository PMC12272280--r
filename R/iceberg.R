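#' Relative effect potency of a chemical versus the reference compound
#'
#' `REP_i = EC(reference) / EC(chemical i)`, both in the same concentration
#' unit. Potent chemicals (low EC) have high REP; REP 1 means
#' reference-equivalent potency.
#'
#' @param ec_reference Benchmark concentration of the reference compound.
#' @param ec_chemical Benchmark concentration of the chemical.
#' @param unit_reference,unit_chemical Optional units; when both given they
#'   must match (no silent conversion).
#' @return Numeric REP.
#' @examples
#' relative_effect_potency(1, 100)  # 0.01
#' @export
relative_effect_potency <- function(ec_reference, ec_chemical,
                                    unit_reference = NULL, unit_chemical = NULL) {
  if (!is.null(unit_reference) && !is.null(unit_chemical) &&
      !identical(unit_reference, unit_chemical))
    wb_unit_error(sprintf("EC units differ: reference '%s' vs chemical '%s'",
                          unit_reference, unit_chemical))
  if (!is.finite(ec_reference) || ec_reference <= 0 ||
      any(!is.finite(ec_chemical)) || any(ec_chemical <= 0))
    wb_validation_error("EC values must be finite and > 0")
  ec_reference / ec_chemical
}

#' Predicted mixture effect from quantified chemicals (concentration addition)
#'
#' Under concentration addition, every detected chemical with a literature
#' EC contributes `BEQ_i = REP_i * C_i` reference equivalents, and the
#' predicted mixture potency is their sum `BEQ_chem = sum(BEQ_i)`. Chemicals
#' without a literature EC in this assay cannot be potency-scaled; they
#' contribute zero and are counted separately as bioactivity-unknown (a
#' known downward bias of the prediction, not imputed). Contributions are
#' ranked descending by `BEQ_i`, ties broken lexicographically by
#' `chemical_id` for reproducible reports.
#'
#' @param chemicals data.frame with columns `chemical_id`, `category`,
#'   `concentration_ng_L` and `ec10` (literature EC in the reference unit;
#'   `NA` when unknown), as produced by [sample_chemicals()].
#' @param ec_reference Literature benchmark of the assay's reference
#'   compound, same unit as `ec10`.
#' @param sample_id,assay_id Labels carried into the result.
#' @return Object of class `iceberg_result` with `beq_chem`,
#'   `contributions` (ranked `chemical_id, category, concentration_ng_L,
#'   rep, beq_i, pct_of_beq_chem`), `n_quantified`, `n_bioactivity_unknown`;
#'   `beq_bio`/`pct_explained`/`n_to_90pct` are filled by
#'   [percent_explained()] and [n_chemicals_to_fraction()].
#' @export
beq_chem <- function(chemicals, ec_reference, sample_id = NA_character_,
                     assay_id = NA_character_) {
  if (!is.finite(ec_reference) || ec_reference <= 0)
    wb_validation_error("ec_reference must be finite and > 0")
  if (any(chemicals$concentration_ng_L < 0, na.rm = TRUE))
    wb_validation_error("chemical concentrations must be >= 0")
  known <- chemicals[!is.na(chemicals$ec10), , drop = FALSE]
  unknown_n <- sum(is.na(chemicals$ec10))
  if (nrow(known)) {
    rep_i <- relative_effect_potency(ec_reference, known$ec10)
    beq_i <- rep_i * known$concentration_ng_L
    contrib <- data.frame(
      chemical_id = known$chemical_id,
      category = if ("category" %in% names(known)) known$category else "uncategorized",
      concentration_ng_L = known$concentration_ng_L,
      rep = rep_i,
      beq_i = beq_i,
      stringsAsFactors = FALSE
    )
    contrib <- contrib[order(-contrib$beq_i, contrib$chemical_id), , drop = FALSE]
    rownames(contrib) <- NULL
    total <- sum(contrib$beq_i)
    contrib$pct_of_beq_chem <- if (total > 0) 100 * contrib$beq_i / total else NA_real_
  } else {
    contrib <- data.frame(chemical_id = character(0), category = character(0),
                          concentration_ng_L = numeric(0), rep = numeric(0),
                          beq_i = numeric(0), pct_of_beq_chem = numeric(0),
                          stringsAsFactors = FALSE)
    total <- 0
  }
  structure(list(
    sample_id = sample_id, assay_id = assay_id,
    beq_chem = total,
    beq_bio = NA_real_, pct_explained = NA_real_, n_to_90pct = NA_integer_,
    contributions = contrib,
    n_quantified = nrow(contrib),
    n_bioactivity_unknown = unknown_n
  ), class = "iceberg_result")
}

#' @export
print.iceberg_result <- function(x, ...) {
  cat(sprintf("<iceberg_result> %s / %s: BEQ_chem = %.4g (%d chemicals, %d bioactivity-unknown)\n",
              x$sample_id, x$assay_id, x$beq_chem, x$n_quantified,
              x$n_bioactivity_unknown))
  if (!is.na(x$pct_explained))
    cat(sprintf("  BEQ_bio = %.4g -> %.1f%% of effect explained (top %s chemicals reach 90%%)\n",
                x$beq_bio, x$pct_explained, x$n_to_90pct))
  invisible(x)
}

#' Fraction of the measured mixture effect explained by known chemicals
#'
#' `% effect explained = 100 * BEQ_chem / BEQ_bio`. Values above 100\% are
#' diagnostically meaningful (e.g. over-additive literature ECs or
#' non-detected antagonism) and are never clipped.
#'
#' @param result An `iceberg_result` (or numeric `BEQ_chem`).
#' @param beq_bio Measured bioanalytical equivalent concentration; must be
#'   valid and > 0.
#' @return The updated `iceberg_result` (or the numeric percentage when
#'   `result` is numeric).
#' @examples
#' percent_explained(0.72, 1.0)  # 72
#' @export
percent_explained <- function(result, beq_bio) {
  if (!is.finite(beq_bio) || beq_bio <= 0)
    wb_validation_error("beq_bio must be finite and > 0 (masked/inactive samples are not evaluable)")
  if (is.numeric(result)) return(100 * result / beq_bio)
  stopifnot(inherits(result, "iceberg_result"))
  result$beq_bio <- beq_bio
  result$pct_explained <- 100 * result$beq_chem / beq_bio
  result$n_to_90pct <- n_chemicals_to_fraction(result, 0.90)
  result
}

#' Top drivers of the predicted mixture effect
#'
#' First `k` chemicals by share of `BEQ_chem` (contributions are already
#' ranked with deterministic tie-breaks).
#'
#' @param result An `iceberg_result` with `beq_chem > 0`.
#' @param k Number of drivers (a `k` beyond the list returns the full list).
#' @return data.frame of the top contributions.
#' @export
top_drivers <- function(result, k = 10) {
  stopifnot(inherits(result, "iceberg_result"))
  if (result$beq_chem <= 0)
    wb_validation_error("top drivers require beq_chem > 0")
  utils::head(result$contributions, k)
}

#' Number of chemicals needed to reach a cumulative effect fraction
#'
#' Smallest m such that the top-m contributions cover at least
#' `100 * fraction` percent of `BEQ_chem` (e.g. how many chemicals explain
#' 90\% of the explained effect).
#'
#' @param result An `iceberg_result` with `beq_chem > 0`.
#' @param fraction Cumulative fraction in (0, 1], default 0.90.
#' @return Integer count.
#' @export
n_chemicals_to_fraction <- function(result, fraction = 0.90) {
  stopifnot(inherits(result, "iceberg_result"))
  if (result$beq_chem <= 0)
    wb_validation_error("cumulative coverage requires beq_chem > 0")
  cum <- cumsum(result$contributions$pct_of_beq_chem)
  as.integer(which(cum >= 100 * fraction - 1e-9)[1])
}

#' Category-resolved BEQ profile
#'
#' Sums `BEQ_i` within chemical categories (pesticides, pharmaceuticals,
#' polymer additives, ...). Chemicals without a category fall back to
#' `"uncategorized"`. The category sums re-add exactly to `BEQ_chem`.
#'
#' @param result An `iceberg_result`.
#' @return data.frame `category, beq, pct`, sorted descending by `beq`.
#' @export
category_profile <- function(result) {
  stopifnot(inherits(result, "iceberg_result"))
  contrib <- result$contributions
  cat_lbl <- contrib$category
  cat_lbl[is.na(cat_lbl) | cat_lbl == ""] <- "uncategorized"
  if (!nrow(contrib))
    return(data.frame(category = character(0), beq = numeric(0), pct = numeric(0)))
  agg <- stats::aggregate(list(beq = contrib$beq_i), list(category = cat_lbl), sum)
  agg <- agg[order(-agg$beq, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  agg$pct <- if (result$beq_chem > 0) 100 * agg$beq / result$beq_chem else NA_real_
  agg
}
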