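#' Four-parameter log-logistic response function
#'
#' `f(x) = bottom + (top - bottom) / (1 + exp(hill * (log(ec50) - log(x))))`,
#' increasing in `x` for `hill > 0`, with `f(ec50)` at the midpoint between
#' `bottom` and `top`.
#'
#' @param x Concentration (REF or reference-compound concentration), > 0.
#' @param bottom,top Lower/upper response asymptotes.
#' @param ec50 Midpoint concentration.
#' @param hill Hill slope (> 0 for increasing curves).
#' @return Response values.
#' @export
ll4 <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (log(ec50) - log(x))))
}

ll4_loge <- function(x, bottom, top, log_ec50, hill) {
  bottom + (top - bottom) / (1 + exp(hill * (log_ec50 - log(x))))
}

#' Fit a four-parameter log-logistic concentration-response model
#'
#' Nonlinear least squares of response against log concentration
#' (Levenberg-Marquardt), with deterministic multi-start initialization:
#' `bottom`/`top` start at the observed response range, `ec50` at the
#' concentrations nearest the 25/50/75\% response quantiles, and the Hill
#' slope over \{0.5, 1, 2, 4\}. The best converged start by residual sum of
#' squares wins; the start order is fixed so fits are reproducible. The
#' parameter covariance comes from the Jacobian at the optimum
#' (fitted internally on `log(ec50)`, then mapped back by the delta method).
#'
#' @param series A `normalized_series`, or a data.frame with columns
#'   `ref`/`conc` and `response`.
#' @param min_points Minimum retained points (default 5).
#' @param min_decades Minimum concentration span in decades (default 2).
#' @param fixed_bottom When the lower asymptote is known by construction
#'   (the negative-control signal for effect curves, IR = 1 for
#'   induction-ratio curves), fixing it removes the bottom-hill trade-off
#'   that otherwise inflates the variance of benchmark concentrations far
#'   down the curve. `NULL` (default) fits all four parameters.
#' @param weights Optional observation weights for the least squares
#'   (variance assumed proportional to `1/weights`). Raw luminescence
#'   noise is close to multiplicative, so reference curves on the signal
#'   scale are fitted with `1/signal^2` weights; normalized fraction-scale
#'   series keep unit weights.
#' @return Object of class `log_logistic_fit`: `bottom`, `top`, `ec50`,
#'   `hill`, `covariance` (4x4, parameter order bottom/top/ec50/hill),
#'   `r_squared`, `rss`, `n_used`.
#' @export
fit_log_logistic <- function(series, min_points = 5L, min_decades = 2,
                             fixed_bottom = NULL, weights = NULL) {
  if (inherits(series, "normalized_series")) {
    x <- series$points$ref
    y <- series$points$response
  } else {
    x <- series$ref %||% series$conc
    y <- series$response
  }
  ok <- is.finite(x) & is.finite(y) & x > 0
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(x))
    w <- weights[ok]
  } else w <- rep(1, sum(ok))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_points)
    wb_insufficient_data(sprintf("%d points retained; >= %d required for a 4PL fit",
                                 n, min_points))
  if (log10(max(x) / min(x)) < min_decades)
    wb_insufficient_data(sprintf("concentrations span %.2f decades; >= %g required",
                                 log10(max(x) / min(x)), min_decades))
  if (stats::sd(y) < 1e-12 * max(abs(y), 1))
    wb_fit_failure("constant response; log-logistic model is unidentifiable")

  b0 <- min(y); t0 <- max(y)
  qs <- b0 + c(0.25, 0.5, 0.75) * (t0 - b0)
  ec_starts <- unique(vapply(qs, function(q) x[which.min(abs(y - q))], numeric(1)))
  free_bottom <- is.null(fixed_bottom)
  best <- NULL
  for (h0 in c(0.5, 1, 2, 4)) {
    for (e0 in ec_starts) {
      fit <- tryCatch({
        if (free_bottom) {
          minpack.lm::nlsLM(
            y ~ ll4_loge(x, bottom, top, log_ec50, hill),
            start = list(bottom = b0, top = t0, log_ec50 = log(e0), hill = h0),
            lower = c(-Inf, -Inf, log(min(x)) - 12, 1e-3),
            upper = c(Inf, Inf, log(max(x)) + 12, 50),
            weights = w,
            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          minpack.lm::nlsLM(
            y ~ ll4_loge(x, fixed_bottom, top, log_ec50, hill),
            start = list(top = t0, log_ec50 = log(e0), hill = h0),
            lower = c(-Inf, log(min(x)) - 12, 1e-3),
            upper = c(Inf, log(max(x)) + 12, 50),
            weights = w,
            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) NULL)
      if (!is.null(fit)) {
        rss_w <- sum(w * stats::resid(fit)^2)  # weighted: comparable across starts
        if (is.null(best) || rss_w < best$rss_w - 1e-12 * best$rss_w)
          best <- list(fit = fit, rss_w = rss_w, rss = sum(stats::resid(fit)^2))
      }
    }
  }
  if (is.null(best))
    wb_fit_failure("log-logistic fit failed to converge from every start")
  fit <- best$fit
  cf <- stats::coef(fit)
  if (!free_bottom) cf <- c(bottom = fixed_bottom, cf)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc)) {
    vc <- matrix(NA_real_, 4, 4)
  } else if (!free_bottom) {
    # fixed bottom contributes zero variance
    vc4 <- matrix(0, 4, 4)
    vc4[2:4, 2:4] <- vc
    vc <- vc4
  }
  ec50 <- exp(cf[["log_ec50"]])
  jac <- diag(c(1, 1, ec50, 1))       # delta method: log(ec50) -> ec50
  vc_nat <- jac %*% vc %*% t(jac)
  dimnames(vc_nat) <- list(c("bottom", "top", "ec50", "hill"),
                           c("bottom", "top", "ec50", "hill"))
  tss <- sum((y - mean(y))^2)
  structure(list(
    bottom = cf[["bottom"]], top = cf[["top"]], ec50 = ec50, hill = cf[["hill"]],
    covariance = vc_nat,
    r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
    rss = best$rss, n_used = n
  ), class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, ...) {
  cat(sprintf("<log_logistic_fit> bottom %.4g, top %.4g, ec50 %.4g, hill %.3g (n=%d, R2=%.3f)\n",
              x$bottom, x$top, x$ec50, x$hill, x$n_used, x$r_squared))
  invisible(x)
}

ll4_level_crossing <- function(bottom, top, ec50, hill, y_abs) {
  ec50 * ((y_abs - bottom) / (top - y_abs))^(1 / hill)
}

#' Benchmark concentration from a log-logistic fit
#'
#' Inverts the fitted curve at an absolute response level `y`:
#' `value = ec50 * ((y - bottom) / (top - y))^(1/hill)`. For benchmark kinds
#' on the fraction-of-maximum effect scale the level is absolute 0.10 (10\%
#' effect); for induction-ratio series it is the absolute IR 1.5; with
#' `relative = TRUE` the level is taken as a fraction of the fitted
#' bottom-to-top span (used for reference-compound calibration, where the
#' curve itself defines 100\%). The standard error is first-order
#' propagation of the full 4x4 parameter covariance through the crossing
#' formula (central-difference gradient).
#'
#' @param fit A `log_logistic_fit`.
#' @param kind `"EC10"`, `"EC_IR1.5"` or `"IC10"`.
#' @param level Response level; default 0.10 absolute.
#' @param relative Interpret `level` as a fraction of the fitted span.
#' @param max_ref Highest tested concentration, recorded when the curve
#'   never reaches the level (status `"inactive"`).
#' @return An [effect_estimate()].
#' @examples
#' f <- structure(list(bottom = 0, top = 100, ec50 = 10, hill = 1,
#'                     covariance = diag(0, 4), r_squared = 1, n_used = 11),
#'                class = "log_logistic_fit")
#' benchmark_from_log_logistic(f, "EC10", level = 10)$value  # 10 * (10/90)
#' @export
benchmark_from_log_logistic <- function(fit, kind, level = 0.10,
                                        relative = FALSE, max_ref = NA_real_) {
  stopifnot(inherits(fit, "log_logistic_fit"))
  value_fn <- function(p) {
    y_abs <- if (relative) p[1] + level * (p[2] - p[1]) else level
    ll4_level_crossing(p[1], p[2], p[3], p[4], y_abs)
  }
  p <- c(fit$bottom, fit$top, fit$ec50, fit$hill)
  y_abs <- if (relative) p[1] + level * (p[2] - p[1]) else level
  if (!relative && (fit$top <= y_abs || y_abs <= fit$bottom)) {
    return(effect_estimate(kind, NA_real_, status = "inactive",
                           fit_used = "log_logistic", n_used = fit$n_used,
                           max_ref = max_ref))
  }
  value <- value_fn(p)
  se <- NA_real_
  if (all(is.finite(fit$covariance))) {
    grad <- numeric(4)
    for (i in seq_len(4)) {
      hstep <- max(abs(p[i]), 1e-8) * 1e-6
      up <- p; up[i] <- up[i] + hstep
      dn <- p; dn[i] <- dn[i] - hstep
      grad[i] <- (value_fn(up) - value_fn(dn)) / (2 * hstep)
    }
    se <- sqrt(drop(t(grad) %*% fit$covariance %*% grad))
  }
  effect_estimate(kind, value = value, se = se, r_squared = fit$r_squared,
                  fit_used = "log_logistic", n_used = fit$n_used,
                  max_ref = max_ref)
}
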