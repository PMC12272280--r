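test_that("effect normalization anchors controls at 0 and the reference top at 1", {
  fit <- fake_ll4_fit(bottom = 2000, top = 12000, ec50 = 5, hill = 1.2)
  ctrl <- c(1900, 2100, 2000)
  s <- normalize_effect("S1", "ERalpha", ref = c(1, 2, 4),
                        signal = c(2000, 12000, 7000),
                        control_signals = ctrl, reference_fit = fit)
  expect_equal(s$points$response, c(0, 1, 0.5))

  bad_fit <- fake_ll4_fit(bottom = 0, top = 1500, ec50 = 5, hill = 1)
  expect_error(
    normalize_effect("S1", "ERalpha", 1, 1000, ctrl, bad_fit),
    class = "wb_degenerate_error")
})

test_that("induction ratio is signal over mean unexposed-control signal", {
  expect_equal(induction_ratio(3000, c(2000)), 1.5)
  expect_equal(induction_ratio(2000, c(1800, 2200)), 1.0)
  # hand-computed: mean(1800, 2200, 2000, 2000) = 2000; 3300/2000
  expect_equal(induction_ratio(3300, c(1800, 2200, 2000, 2000)), 1.65)
  expect_error(induction_ratio(1000, numeric(0)), class = "wb_degenerate_error")
  expect_error(induction_ratio(1000, c(0, 0)), class = "wb_degenerate_error")
})

test_that("the viability rule excludes wells at 10% loss or more, inclusive", {
  s <- normalized_series("S", "A", ref = c(1, 2, 4), response = c(0.1, 0.2, 0.4),
                         viability = c(1.0, 0.95, 0.89))
  m <- apply_viability_mask(s)
  expect_equal(nrow(m$points), 2)
  expect_equal(m$excluded$ref, 4)
  expect_equal(m$excluded$reason, "viability")

  # exactly 10% loss is excluded
  s2 <- normalized_series("S", "A", ref = c(1, 2), response = c(0.1, 0.2),
                          viability = c(1.0, 0.90))
  expect_equal(apply_viability_mask(s2)$excluded$ref, 2)

  # all viable: unchanged
  s3 <- normalized_series("S", "A", ref = c(1, 2), response = c(0.1, 0.2),
                          viability = c(1, 0.99))
  expect_equal(nrow(apply_viability_mask(s3)$excluded), 0)
})

test_that("linear fit recovers an exact line through the origin and applies the cutoff", {
  s <- normalized_series("S", "A", ref = c(1, 2, 5, 10),
                         response = c(0.02, 0.04, 0.10, 0.20))
  f <- fit_linear(s)
  expect_equal(f$slope, 0.02, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(f$n_used, 4)

  # a 50% effect point lies above the 30% cutoff and must not alter the slope
  s2 <- normalized_series("S", "A", ref = c(1, 2, 5, 10, 20),
                          response = c(0.02, 0.04, 0.10, 0.20, 0.50))
  f2 <- fit_linear(s2)
  expect_equal(f2$slope, 0.02, tolerance = 1e-12)
  expect_equal(f2$n_used, 4)

  expect_error(fit_linear(normalized_series("S", "A", 1, 0.1)),
               class = "wb_insufficient_data")
})

test_that("linear slope equals the closed-form through-origin OLS on noisy data", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- 100 / 2^(0:10)
    y <- 0.002 * x + rnorm(11, 0, 0.01)
    s <- normalized_series("S", "A", x, y)
    f <- fit_linear(s, cutoff = 0.30)
    keep <- sort(x)[y[order(x)] <= 0.30]
    yy <- y[order(x)][y[order(x)] <= 0.30]
    expect_equal(f$slope, sum(keep * yy) / sum(keep^2), tolerance = 1e-10)
  }
})

test_that("linear benchmarks follow EC10 = 0.1/slope and EC_IR1.5 = 0.5/slope", {
  expect_equal(benchmark_from_linear(fake_linear_fit(0.02), "EC10")$value, 5)
  expect_equal(benchmark_from_linear(fake_linear_fit(0.05), "EC_IR1.5")$value, 10)
  expect_equal(benchmark_from_linear(fake_linear_fit(0.02), "IC10")$value, 5)
  # error propagation: SE = 0.1/slope^2 * SE(slope)
  est <- benchmark_from_linear(fake_linear_fit(0.02, se_slope = 0.002), "EC10")
  expect_equal(est$se, 0.5)
  # non-positive slope: no response
  inact <- benchmark_from_linear(fake_linear_fit(-0.01), "EC10", max_ref = 100)
  expect_equal(inact$status, "inactive")
  expect_true(is.na(inact$value))
  expect_equal(inact$max_ref, 100)
})

test_that("benchmark times slope is exactly the response increment", {
  # algebraic identity: value * slope = 0.1 (0.5 for the IR benchmark)
  for (slope in c(0.001, 0.02, 0.7, 13)) {
    expect_equal(benchmark_from_linear(fake_linear_fit(slope), "EC10")$value * slope,
                 0.1, tolerance = 1e-12)
    expect_equal(benchmark_from_linear(fake_linear_fit(slope), "EC_IR1.5")$value * slope,
                 0.5, tolerance = 1e-12)
  }
})

test_that("the 4PL fit recovers noiseless parameters to high precision", {
  x <- 10^seq(-2, 2, length.out = 11)
  y <- ll4(x, bottom = 0, top = 100, ec50 = 10, hill = 1)
  f <- fit_log_logistic(data.frame(ref = x, response = y))
  expect_equal(f$bottom, 0, tolerance = 1e-6)
  expect_equal(f$top, 100, tolerance = 1e-6)
  expect_equal(f$ec50, 10, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
})

test_that("degenerate inputs to the 4PL fit fail loudly", {
  x <- 10^seq(-2, 2, length.out = 11)
  expect_error(fit_log_logistic(data.frame(ref = x, response = rep(5, 11))),
               class = "wb_fit_failure")
  expect_error(fit_log_logistic(data.frame(ref = x[1:3], response = c(1, 2, 3))),
               class = "wb_insufficient_data")
  expect_error(fit_log_logistic(data.frame(ref = c(1, 1.2, 1.4, 1.6, 1.8),
                                           response = c(1, 2, 3, 4, 5))),
               class = "wb_insufficient_data")
})

test_that("4PL ec50 recovery under 5% multiplicative noise is accurate", {
  x <- 100 / 2^(0:10)
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    y <- ll4(x, 0, 1, ec50 = 8, hill = 1.5) * rlnorm(11, 0, sqrt(log(1.0025)))
    f <- fit_log_logistic(data.frame(ref = x, response = y))
    abs(f$ec50 / 8 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("log-logistic benchmarks match the closed-form level crossing", {
  f1 <- fake_ll4_fit(0, 100, ec50 = 10, hill = 1)
  expect_equal(benchmark_from_log_logistic(f1, "EC10", level = 10)$value,
               10 * (10 / 90), tolerance = 1e-12)
  f2 <- fake_ll4_fit(0, 100, ec50 = 10, hill = 2)
  expect_equal(benchmark_from_log_logistic(f2, "EC10", level = 10)$value,
               10 * (1 / 9)^(1 / 2), tolerance = 1e-12)
  # curve that never reaches the level
  f3 <- fake_ll4_fit(0, 0.08, ec50 = 10, hill = 1)
  est <- benchmark_from_log_logistic(f3, "EC10", level = 0.1, max_ref = 100)
  expect_equal(est$status, "inactive")
})

test_that("4PL benchmark SE agrees with Monte-Carlo propagation of the covariance", {
  set.seed(42)
  x <- 100 / 2^(0:10)
  y <- ll4(x, 0, 1, ec50 = 8, hill = 1.5) * rlnorm(11, 0, sqrt(log(1.0025)))
  f <- fit_log_logistic(data.frame(ref = x, response = y))
  est <- benchmark_from_log_logistic(f, "EC10", level = 0.1)
  # draw parameters from the fitted covariance and recompute the crossing
  L <- chol(f$covariance + diag(1e-12, 4))
  draws <- matrix(rnorm(4 * 1e5), ncol = 4) %*% L
  p0 <- c(f$bottom, f$top, f$ec50, f$hill)
  vals <- apply(draws, 1, function(d) {
    p <- p0 + d
    if (p[4] <= 0 || p[3] <= 0 || p[2] <= 0.1) return(NA_real_)
    p[3] * ((0.1 - p[1]) / (p[2] - 0.1))^(1 / p[4])
  })
  mc <- robust_mc_sd(vals[is.finite(vals)])
  expect_lt(abs(est$se / mc - 1), 0.05)
})

test_that("confidence scoring and gating follow (1 - SE/value) * R2 with threshold 0.7", {
  e1 <- effect_estimate("EC10", 5, se = 0.5, r_squared = 0.95, fit_used = "linear")
  expect_equal(confidence_score(e1), 0.855)
  expect_equal(gate_confidence(e1)$status, "valid")

  e2 <- effect_estimate("EC10", 5, se = 2.5, r_squared = 0.8, fit_used = "linear")
  expect_equal(confidence_score(e2), 0.4)
  expect_equal(gate_confidence(e2)$status, "needs_manual_review")

  e3 <- effect_estimate("EC10", 5, se = 0, r_squared = 1, fit_used = "linear")
  expect_equal(confidence_score(e3), 1)

  # SE exceeding the value drives the score negative: always flagged
  e4 <- effect_estimate("EC10", 5, se = 6, r_squared = 1, fit_used = "linear")
  expect_lt(confidence_score(e4), 0)
  expect_equal(gate_confidence(e4)$status, "needs_manual_review")
})

test_that("concentrations above the IC10 are excluded from the effect curve", {
  s <- normalized_series("S", "A", ref = c(1, 3, 10, 30, 100),
                         response = c(0.01, 0.03, 0.1, 0.3, 0.9))
  ic10 <- effect_estimate("IC10", 10, se = 1, fit_used = "linear")
  m <- mask_above_ic10(s, ic10)
  expect_equal(m$excluded$ref, c(30, 100))
  expect_equal(unique(m$excluded$reason), "cytotoxicity")
  expect_equal(m$points$ref, c(1, 3, 10))  # the boundary point is kept

  # no cytotoxicity observed: unchanged
  none <- effect_estimate("IC10", NA, status = "inactive", max_ref = 100)
  expect_equal(nrow(mask_above_ic10(s, none)$excluded), 0)
  expect_equal(nrow(mask_above_ic10(s, NULL)$excluded), 0)

  # everything cytotoxic: empty retained set
  all_gone <- mask_above_ic10(s, effect_estimate("IC10", 0.5, fit_used = "linear"))
  expect_equal(nrow(all_gone$points), 0)
})

test_that("activity classification applies the masking and inactivity rules", {
  ec <- effect_estimate("EC_IR1.5", 40, se = 4, fit_used = "linear")
  ic <- effect_estimate("IC10", 25, se = 2, fit_used = "linear")
  expect_equal(classify_activity(ec, ic, max_ref = 100)$status,
               "masked_by_cytotoxicity")

  ec2 <- effect_estimate("EC10", 5, se = 0.5, fit_used = "linear")
  ic2 <- effect_estimate("IC10", 20, se = 2, fit_used = "linear")
  expect_equal(classify_activity(ec2, ic2, max_ref = 100)$status, "valid")

  # benchmark beyond the tested range: inactive, with the range recorded
  ec3 <- effect_estimate("EC10", 170, se = 20, fit_used = "linear")
  out <- classify_activity(ec3, NULL, max_ref = 100)
  expect_equal(out$status, "inactive")
  expect_true(is.na(out$value))
  expect_equal(out$max_ref, 100)
})

test_that("linear and 4PL benchmarks agree on data linear below the cutoff", {
  slope <- 0.02
  x <- 15 / 2^(0:10)          # all effects at or below 30%
  y <- slope * x
  s <- data.frame(ref = x, response = y)
  lin <- benchmark_from_linear(fit_linear(normalized_series("S", "A", x, y)), "EC10")
  ll <- benchmark_from_log_logistic(fit_log_logistic(s), "EC10", level = 0.1)
  expect_equal(ll$value / lin$value, 1, tolerance = 0.02)
})

test_that("masking at the IC10 does not worsen benchmark accuracy under suppression", {
  cfg <- era_config()
  errs <- vapply(1:30, function(seed) {
    tr <- sample_truth("S1", ec_true = 3, ic10_true = 9, active = TRUE)
    p <- generate_plate(cfg, tr, seed = seed, cytotoxic_suppression = TRUE)
    w <- p$wells
    sw <- w[w$role == "sample", ]
    ctrl <- w$signal[w$role == "negative_control"]
    lo <- w[w$role == "reference_low", ]; hi <- w[w$role == "reference_high", ]
    cal <- calibrate_reference(
      data.frame(conc = lo$ref_concentration, response = lo$signal),
      data.frame(conc = hi$ref_concentration, response = hi$signal),
      cfg, control_signals = ctrl)
    s <- normalize_effect("S1", "ERalpha", sw$ref_concentration, sw$signal,
                          ctrl, cal$fit, viability = sw$viability)
    ic10 <- effect_estimate("IC10", 9, fit_used = "linear")
    fit_of <- function(series)
      benchmark_from_linear(fit_linear(series), "EC10")$value
    masked <- fit_of(mask_above_ic10(apply_viability_mask(s), ic10))
    unmasked <- fit_of(s)
    # a suppressed, unmasked series may fail to fit at all; that counts as
    # the worst possible unmasked error
    c(abs(masked / 3 - 1),
      if (is.na(unmasked)) Inf else abs(unmasked / 3 - 1))
  }, numeric(2))
  expect_true(all(is.finite(errs[1, ])))
  expect_lt(mean(errs[1, ]), 0.25)
  expect_true(all(errs[1, ] <= errs[2, ] + 0.005))
})
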