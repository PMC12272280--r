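#' Linear fit of the low-effect region of a concentration-response curve
#'
#' Below roughly 30\% absolute effect, concentration-response curves are
#' close to linear, which permits a simplified regression in place of the
#' full log-logistic model. The line is forced through the origin (through
#' IR = 1 for induction-ratio series): the benchmark formulas
#' `EC10 = 0.1/slope` and `EC_IR1.5 = 0.5/slope` are only exact with a zero
#' intercept. Ordinary least squares of response against REF on the points
#' inside the linear region; points above the cutoff are ignored (not
#' excluded from the series).
#'
#' @param series A `normalized_series` (already viability- and
#'   cytotoxicity-masked as appropriate).
#' @param cutoff Absolute effect fraction bounding the linear region
#'   (default 0.30). For induction-ratio series the bound is applied to
#'   `IR - 1 <= cutoff * 5`, placing the benchmark IR 1.5 at the same
#'   relative depth into the fitted range as a 10\% effect is to 30\%.
#' @param free_intercept Fit with a free intercept instead (diagnostic
#'   comparison only; the benchmark formulas assume zero intercept).
#' @return Object of class `linear_fit`: `slope`, `se_slope`, `r_squared`
#'   (uncentered for through-origin fits, as returned by
#'   [stats::lm()]), `n_used`.
#' @export
fit_linear <- function(series, cutoff = 0.30, free_intercept = FALSE) {
  stopifnot(inherits(series, "normalized_series"))
  x <- series$points$ref
  y <- series$points$response
  if (series$response_type == "ir") {
    y <- y - 1
    bound <- cutoff * 5  # IR excess 1.5 at the default 0.30 cutoff
  } else {
    bound <- cutoff
  }
  keep <- which(is.finite(y) & y <= bound)
  if (length(keep) < 2L)
    wb_insufficient_data(sprintf(
      "only %d point(s) below the %.2f cutoff; >= 2 required", length(keep), bound))
  x <- x[keep]; y <- y[keep]
  fit <- if (free_intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  # summary.lm warns on zero-residual input; a perfect fit is legitimate here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- sm$coefficients["x", ]
  structure(list(
    slope = unname(co["Estimate"]),
    se_slope = unname(co["Std. Error"]),
    r_squared = sm$r.squared,
    n_used = length(keep),
    free_intercept = free_intercept
  ), class = "linear_fit")
}

#' Effect estimate container
#'
#' A benchmark concentration (EC10, EC_IR1.5 or IC10) in REF units with its
#' standard error, goodness-of-fit, confidence score and validity status.
#'
#' @param kind `"EC10"`, `"EC_IR1.5"` or `"IC10"`.
#' @param value Benchmark concentration in REF, or `NA` when none exists.
#' @param se Standard error, same units.
#' @param r_squared Goodness-of-fit of the underlying regression.
#' @param status `"valid"`, `"masked_by_cytotoxicity"`, `"inactive"` or
#'   `"needs_manual_review"`.
#' @param fit_used `"linear"` or `"log_logistic"`.
#' @param n_used Number of points used in the fit.
#' @param max_ref Highest tested REF (recorded for inactive samples).
#' @param confidence Confidence score, filled by [gate_confidence()].
#' @return Object of class `effect_estimate`.
#' @export
effect_estimate <- function(kind, value, se = NA_real_, r_squared = NA_real_,
                            status = "valid", fit_used = NA_character_,
                            n_used = NA_integer_, max_ref = NA_real_,
                            confidence = NA_real_) {
  stopifnot(kind %in% c("EC10", "EC_IR1.5", "IC10"))
  if (status == "valid" && (is.na(value) || value <= 0))
    wb_validation_error("a valid estimate requires value > 0")
  structure(list(kind = kind, value = value, se = se, r_squared = r_squared,
                 confidence = confidence, status = status, fit_used = fit_used,
                 n_used = n_used, max_ref = max_ref),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("<effect_estimate> %s: %s (max tested REF %g)\n",
                x$kind, x$status, x$max_ref))
  } else {
    cat(sprintf("<effect_estimate> %s = %.4g +/- %.3g REF (%s, %s fit, conf %.3g)\n",
                x$kind, x$value, x$se, x$status, x$fit_used, x$confidence))
  }
  invisible(x)
}

#' Benchmark concentration from a linear fit
#'
#' `EC10 = 0.1/slope` (likewise `IC10`) and `EC_IR1.5 = 0.5/slope`, with the
#' standard error propagated from the slope:
#' `SE = (0.1/slope^2) * SE(slope)` (0.5 for `EC_IR1.5`).
#'
#' @param fit A `linear_fit`.
#' @param kind `"EC10"`, `"EC_IR1.5"` or `"IC10"`.
#' @param max_ref Highest tested REF, recorded when no response exists.
#' @return An [effect_estimate()]. A non-positive slope yields no benchmark:
#'   the estimate is returned with status `"inactive"` and the maximum
#'   tested REF recorded.
#' @examples
#' f <- structure(list(slope = 0.02, se_slope = 0.002, r_squared = 0.99,
#'                     n_used = 5), class = "linear_fit")
#' benchmark_from_linear(f, "EC10")  # 0.1/0.02 = 5 REF
#' @export
benchmark_from_linear <- function(fit, kind, max_ref = NA_real_) {
  stopifnot(inherits(fit, "linear_fit"))
  num <- if (kind == "EC_IR1.5") 0.5 else 0.1
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    return(effect_estimate(kind, NA_real_, status = "inactive",
                           fit_used = "linear", n_used = fit$n_used,
                           max_ref = max_ref))
  }
  effect_estimate(kind,
                  value = num / fit$slope,
                  se = num / fit$slope^2 * fit$se_slope,
                  r_squared = fit$r_squared,
                  fit_used = "linear",
                  n_used = fit$n_used,
                  max_ref = max_ref)
}

#' Confidence score of a benchmark estimate
#'
#' `confidence = (1 - SE/value) * R^2`. Precise estimates from well-fitting
#' regressions score near 1; estimates whose SE approaches or exceeds the
#' value score near or below 0.
#'
#' @param estimate An [effect_estimate()] with value and SE.
#' @param r_squared Goodness-of-fit; defaults to the one stored in the
#'   estimate.
#' @return The numeric score.
#' @examples
#' e <- effect_estimate("EC10", 5, se = 0.5, r_squared = 0.95, fit_used = "linear")
#' confidence_score(e)  # (1 - 0.1) * 0.95 = 0.855
#' @export
confidence_score <- function(estimate, r_squared = estimate$r_squared) {
  stopifnot(inherits(estimate, "effect_estimate"))
  if (is.na(estimate$value) || is.na(estimate$se))
    wb_validation_error("confidence requires both value and SE")
  (1 - estimate$se / estimate$value) * r_squared
}

#' Apply the confidence gate to an estimate
#'
#' Stores the confidence score on the estimate and flags it
#' `needs_manual_review` when the score falls below the threshold (default
#' 0.7). Manual expert review is a terminal status here: the pipeline never
#' silently promotes such estimates.
#'
#' @param estimate An [effect_estimate()].
#' @param threshold Minimum acceptable score.
#' @return The updated [effect_estimate()].
#' @export
gate_confidence <- function(estimate, threshold = 0.7) {
  if (is.na(estimate$value)) return(estimate)
  score <- confidence_score(estimate)
  estimate$confidence <- score
  if (score < threshold && estimate$status == "valid")
    estimate$status <- "needs_manual_review"
  estimate
}
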