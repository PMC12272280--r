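test_that("the generator is deterministic given a seed", {
  cfg <- era_config()
  tr <- sample_truth(c("S1", "S2"), c(5, 20), ic10_true = c(Inf, 60))
  a <- generate_plate(cfg, tr, seed = 7)
  b <- generate_plate(cfg, tr, seed = 7)
  expect_identical(a$wells, b$wells)
  c <- generate_plate(cfg, tr, seed = 8)
  expect_false(identical(a$wells$signal, c$wells$signal))

  s1 <- simulate_study(n_samples = 3, seed = 5, n_chemicals = 10)
  s2 <- simulate_study(n_samples = 3, seed = 5, n_chemicals = 10)
  expect_identical(s1$plates[[1]]$wells, s2$plates[[1]]$wells)
  expect_identical(s1$chemicals$chemicals, s2$chemicals$chemicals)
})

test_that("seeding does not disturb the caller's random-number stream", {
  set.seed(42); before <- stats::runif(3)
  set.seed(42); invisible(stats::runif(1))
  invisible(generate_plate(era_config(), sample_truth("S1", 5), seed = 3))
  after <- stats::runif(2)
  expect_identical(before[2:3], after)
})

test_that("noise realism: control wells show the configured multiplicative CV", {
  cfg <- era_config()
  cvs <- vapply(1:20, function(seed) {
    p <- generate_plate(cfg, sample_truth("S1", 5), seed = seed,
                        signal_cv = 0.05)
    ctrl <- p$wells$signal[p$wells$role == "negative_control"]
    stats::sd(ctrl) / mean(ctrl)
  }, numeric(1))
  expect_lt(abs(mean(cvs) / 0.05 - 1), 0.20)
  expect_true(all(cvs > 0.01 & cvs < 0.12))
})

test_that("a noiseless plate reproduces the true benchmark exactly", {
  cfg <- era_config()
  p <- generate_plate(cfg, sample_truth("S1", 5), seed = 1,
                      signal_cv = 0, viability_sd = 0)
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
  est <- benchmark_from_linear(fit_linear(s), "EC10")
  expect_equal(est$value, 5, tolerance = 1e-3)
  # the reference calibration itself recovers its own truth
  expect_equal(cal$ec10_reference,
               attr(p, "truth")$reference$ec_benchmark, tolerance = 1e-6)
})

test_that("truth scenarios produce every downstream status", {
  cfg <- era_config()
  tr <- sample_truth(
    c("active", "inactive", "masked", "cytotox_only"),
    ec_true = c(5, Inf, 40, Inf),
    ic10_true = c(Inf, Inf, 25, 10))
  p <- generate_plate(cfg, tr, seed = 3)
  ev <- evaluate_plate(p)
  eff <- ev$fit_rows[ev$fit_rows$channel == "effect", ]
  st <- setNames(eff$status, eff$sample_id)
  expect_equal(st[["active"]], "valid")
  expect_equal(st[["inactive"]], "inactive")
  expect_equal(st[["masked"]], "masked_by_cytotoxicity")
  # a purely cytotoxic sample has no specific effect to report
  expect_true(st[["cytotox_only"]] %in% c("inactive", "masked_by_cytotoxicity"))
  cy <- ev$fit_rows[ev$fit_rows$channel == "cytotoxicity", ]
  ic <- setNames(cy$value_REF, cy$sample_id)
  expect_lt(abs(ic[["cytotox_only"]] / 10 - 1), 0.35)
})

test_that("truths labelled active must be reachable within the max REF", {
  expect_error(
    generate_plate(era_config(), sample_truth("S1", 500, active = TRUE),
                   seed = 1),
    class = "wb_generator_error")
  # unlabelled truths above max REF are allowed (they simply read inactive)
  expect_silent(generate_plate(era_config(), sample_truth("S1", 500), seed = 1))
})

test_that("at most 26 sample series fit on one plate", {
  tr <- sample_truth(sprintf("S%02d", 1:27), rep(5, 27))
  expect_error(generate_plate(era_config(), tr, seed = 1),
               class = "wb_generator_error")
})

test_that("chemical tables carry consistent REP and closure truths", {
  cfg <- era_config()
  chem <- generate_chemical_table(
    25, c("S01", "S02"), list(ERalpha = cfg),
    ec_reference = c(ERalpha = 0.68), seed = 9, fraction_with_ec = 0.8)
  tab <- chem$table
  # every library entry reproduces its generating REP
  rt <- chem$truth$rep$ERalpha
  lib <- tab$ec_library[tab$ec_library$chemical_id %in% rt$chemical_id, ]
  got <- 0.68 / lib$ec10
  want <- rt$rep[match(lib$chemical_id, rt$chemical_id)]
  expect_equal(got, want, tolerance = 1e-12)
  # the recorded BEQ_chem truth equals the package's own iceberg sum
  for (sid in c("S01", "S02")) {
    ice <- beq_chem(sample_chemicals(tab, sid, "ERalpha"), 0.68, sid, "ERalpha")
    truth <- chem$truth$beq$beq_chem_true[
      chem$truth$beq$sample_id == sid & chem$truth$beq$assay_id == "ERalpha"]
    expect_equal(ice$beq_chem, truth, tolerance = 1e-9)
  }
  expect_error(
    generate_chemical_table(5, "S01", list(ERalpha = cfg),
                            c(ERalpha = 0.68), seed = 1,
                            fraction_with_ec = 1.2),
    class = "wb_parameter_error")
})

test_that("phi coupling enforces the intended iceberg closure in truth", {
  phi <- 0.8
  st <- simulate_study(assays = list(ERalpha = era_config()),
                       n_samples = 6, seed = 21, n_chemicals = 30,
                       inactive_fraction = 0, phi = phi)
  bq <- st$truth$chemicals$beq
  tr <- st$truth$samples$ERalpha
  for (i in seq_len(nrow(tr))) {
    beq_bio_true <- st$truth$ec_reference[["ERalpha"]] / tr$ec_true[i]
    chem_true <- bq$beq_chem_true[bq$sample_id == tr$sample_id[i]]
    expect_equal(chem_true / beq_bio_true, phi, tolerance = 1e-9)
  }
})

test_that("simulated studies write and re-read as plain text", {
  st <- simulate_study(assays = list(ERalpha = era_config()),
                       n_samples = 3, seed = 2, n_chemicals = 8)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  files <- list.files(dir)
  expect_true(any(grepl("^ERalpha_plate", files)))
  expect_true("chemicals.csv" %in% files)
  expect_true("ec_library.csv" %in% files)
  expect_true("truth.json" %in% files)
  # refuses to clobber
  expect_error(write_study(st, dir), class = "wb_validation_error")
  # plates re-read losslessly
  p1 <- st$plates[[1]]
  back <- read_plate_table(file.path(dir, paste0(p1$plate_id, ".csv")),
                           p1$assay, p1$samples)
  expect_equal(back$wells$signal, p1$wells$signal, tolerance = 1e-12)
})

test_that("parameter validation rejects invalid generator settings", {
  expect_error(sample_truth("S1", -3), class = "wb_parameter_error")
  expect_error(generate_plate(era_config(), sample_truth("S1", 5), seed = 1,
                              sample_type = "lake"),
               class = "wb_parameter_error")
  cy <- assay_config("CY", "cytotoxicity", "ref", benchmark = "EC10")
  expect_error(generate_plate(cy, sample_truth("S1", 5), seed = 1),
               class = "wb_parameter_error")
})
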