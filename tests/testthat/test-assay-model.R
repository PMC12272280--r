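test_that("assay configuration enforces its invariants", {
  cfg <- era_config()
  expect_s3_class(cfg, "assay_config")
  expect_equal(cfg$linear_cutoff, 0.30)
  expect_equal(cfg$confidence_threshold, 0.7)

  expect_error(era_config(ebt_value = -1), class = "wb_parameter_error")
  expect_error(era_config(linear_cutoff = 0), class = "wb_parameter_error")
  expect_error(era_config(confidence_threshold = 1.2), class = "wb_parameter_error")
  # the induction-ratio benchmark only exists for oxidative stress
  expect_error(
    assay_config("X", "receptor_activation", "ref", benchmark = "EC_IR1.5"),
    class = "wb_parameter_error")
  expect_silent(
    assay_config("X", "oxidative_stress", "ref", benchmark = "EC_IR1.5"))
})

test_that("sample records validate types, lateral positions and EF", {
  sr <- sample_records(c("A", "B"), sample_type = "surface",
                       lateral_position = c("left", "middle"))
  expect_equal(nrow(sr), 2)
  expect_error(sample_records("A", sample_type = "lake"),
               class = "wb_validation_error")
  expect_error(sample_records("A", extraction_factor = 0),
               class = "wb_validation_error")
  # lateral positions are a river-sampling concept
  expect_error(sample_records("A", sample_type = "wwtp_influent",
                              lateral_position = "left"),
               class = "wb_validation_error")
})

test_that("a well-formed plate file parses with the documented composition", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_minimal_plate_csv(path, n_series = 32, n_points = 11, n_controls = 32)
  plate <- read_plate_table(path, era_config())
  expect_equal(sum(plate$wells$role == "sample"), 352)
  expect_equal(sum(plate$wells$role == "negative_control"), 32)
  expect_equal(nrow(plate$wells), 384)
})

test_that("malformed plate files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_minimal_plate_csv(path, drop_col = "viability")
  expect_error(read_plate_table(path, era_config()), "viability",
               class = "wb_format_error")

  # zero negative controls
  path2 <- withr::local_tempfile(fileext = ".csv")
  df <- write_minimal_plate_csv(path2)
  df <- df[df$role != "negative_control", ]
  utils::write.csv(df, path2, row.names = FALSE, na = "")
  expect_error(read_plate_table(path2, era_config()),
               class = "wb_validation_error")

  # negative signal
  path3 <- withr::local_tempfile(fileext = ".csv")
  df <- write_minimal_plate_csv(path3)
  df$signal[3] <- -5
  utils::write.csv(df, path3, row.names = FALSE, na = "")
  expect_error(read_plate_table(path3, era_config()),
               class = "wb_validation_error")
})

test_that("plate datasets round-trip through CSV unchanged", {
  plate <- generate_plate(era_config(), sample_truth(c("S1", "S2"), c(5, 12)),
                          seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(plate, path)
  back <- read_plate_table(path, plate$assay, plate$samples)
  expect_equal(back$wells$signal, plate$wells$signal, tolerance = 1e-12)
  expect_equal(back$wells$ref_concentration, plate$wells$ref_concentration,
               tolerance = 1e-12)
  expect_identical(back$wells$role, plate$wells$role)
  expect_identical(back$wells$well, plate$wells$well)
})

test_that("REF decomposes as extraction factor times dilution factor", {
  # EF 1000 with in-assay dilutions reconstructs the stored REF exactly
  plate <- generate_plate(era_config(), sample_truth("S1", 5), seed = 2)
  sw <- plate$wells[plate$wells$role == "sample", ]
  ef <- plate$samples$extraction_factor[1]
  df_assay <- sw$ref_concentration / ef
  expect_equal(ef * df_assay, sw$ref_concentration, tolerance = 1e-9)
})

test_that("chemical tables join EC libraries and flag unknown bioactivity", {
  chem <- data.frame(sample_id = "S1",
                     chemical_id = c("a", "b", "c"),
                     category = "pesticide",
                     concentration_ng_L = c(10, 20, 30))
  lib <- data.frame(chemical_id = c("a", "b"), assay_id = "ERalpha",
                    ec10 = c(100, 200), unit = "ng/L")
  tab <- chemical_table(chem, lib)
  joined <- sample_chemicals(tab, "S1", "ERalpha")
  expect_equal(nrow(joined), 3)
  expect_equal(sum(joined$bioactivity_known), 2)

  expect_error(chemical_table(transform(chem, concentration_ng_L = c(-1, 1, 1)), lib),
               class = "wb_validation_error")
  expect_error(chemical_table(rbind(chem, chem[1, ]), lib),
               class = "wb_validation_error")
  expect_error(chemical_table(chem, transform(lib, unit = c("ng/L", "mg/L")),
                              expected_unit = "ng/L"),
               class = "wb_unit_error")
})

test_that("iceberg input is restricted to chemicals with a literature EC", {
  # 487 detected chemicals of which 92 carry an EC in this assay
  ids <- sprintf("chem%03d", 1:487)
  chem <- data.frame(sample_id = "S1", chemical_id = ids, category = "x",
                     concentration_ng_L = 10)
  lib <- data.frame(chemical_id = ids[1:92], assay_id = "SHSY5Y",
                    ec10 = 1000, unit = "ng/L")
  tab <- chemical_table(chem, lib)
  ice <- beq_chem(sample_chemicals(tab, "S1", "SHSY5Y"), ec_reference = 1000,
                  "S1", "SHSY5Y")
  expect_equal(ice$n_quantified, 92)
  expect_equal(ice$n_bioactivity_unknown, 395)
})

test_that("the bundled EC library reproduces known relative potencies", {
  lib <- utils::read.csv(system.file("extdata", "ec_library_synthetic.csv",
                                     package = "waterbeq"))
  nar <- lib$ec10[lib$chemical_id == "narciclasine" & lib$assay_id == "SHSY5Y"]
  meb <- lib$ec10[lib$chemical_id == "mebendazole" & lib$assay_id == "SHSY5Y"]
  expect_equal(relative_effect_potency(nar, meb), 0.0367, tolerance = 1e-10)
})

test_that("randomly generated plates always satisfy the structural invariants", {
  for (seed in 1:8) {
    n <- 1 + seed %% 5
    tr <- sample_truth(sprintf("S%d", seq_len(n)),
                       ec_true = 2 + 3 * seq_len(n),
                       ic10_true = c(Inf, 50)[1 + seq_len(n) %% 2])
    plate <- generate_plate(era_config(), tr, seed = seed)
    expect_s3_class(plate, "plate_dataset")  # constructor validates on build
    path <- tempfile(fileext = ".csv")
    write_plate_table(plate, path)
    expect_s3_class(read_plate_table(path, plate$assay, plate$samples),
                    "plate_dataset")
    unlink(path)
  }
})
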