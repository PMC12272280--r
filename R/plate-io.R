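well_roles <- c("sample", "reference_low", "reference_high", "negative_control", "blank")

plate_columns <- c("plate_id", "well", "role", "sample_id",
                   "ref_concentration", "signal", "viability")

#' Construct a validated plate dataset
#'
#' Bundles one 384-well plate's well-level measurements with its assay
#' configuration and sample metadata, enforcing the structural invariants the
#' downstream fitting relies on: at least two negative-control wells, every
#' sample well resolvable to a sample record, no concentration attached to
#' negative controls, non-negative finite signals, and strictly monotone
#' dilution series per sample.
#'
#' @param wells data.frame with columns `plate_id`, `well`, `role`,
#'   `sample_id`, `ref_concentration` (REF for sample wells, reference
#'   compound concentration for reference wells, `NA` for controls),
#'   `signal` (raw readout, e.g. relative light units) and `viability`
#'   (fraction of negative-control viability).
#' @param assay An [assay_config()].
#' @param samples A [sample_records()] table covering every `sample_id`
#'   appearing in `wells`.
#' @return Object of class `plate_dataset`: list with `plate_id`, `assay`,
#'   `wells`, `samples`.
#' @export
plate_dataset <- function(wells, assay, samples) {
  stopifnot(inherits(assay, "assay_config"), is.data.frame(wells))
  missing_cols <- setdiff(plate_columns, names(wells))
  if (length(missing_cols))
    wb_format_error(paste0("plate table is missing required column(s): ",
                           paste(missing_cols, collapse = ", ")))
  bad_role <- !wells$role %in% well_roles
  if (any(bad_role))
    wb_validation_error(paste0("unknown well role(s) at row(s) ",
                               paste(which(bad_role), collapse = ", ")))
  if (sum(wells$role == "negative_control") < 2L)
    wb_validation_error("plate must contain at least 2 negative-control wells")
  if (any(!is.na(wells$ref_concentration[wells$role == "negative_control"])))
    wb_validation_error("negative_control wells must not carry a concentration")
  bad_sig <- !is.finite(wells$signal) | wells$signal < 0
  if (any(bad_sig))
    wb_validation_error(paste0("negative or non-finite signal at row(s) ",
                               paste(which(bad_sig), collapse = ", ")))
  if (any(wells$viability < 0, na.rm = TRUE))
    wb_validation_error("viability must be >= 0")
  samp_wells <- wells[wells$role == "sample", , drop = FALSE]
  unknown <- setdiff(unique(samp_wells$sample_id), samples$sample_id)
  if (length(unknown))
    wb_validation_error(paste0("sample well(s) reference unknown sample_id: ",
                               paste(unknown, collapse = ", ")))
  # each sample's dilution series must have distinct, orderable REFs
  for (sid in unique(samp_wells$sample_id)) {
    refs <- samp_wells$ref_concentration[samp_wells$sample_id == sid]
    if (anyNA(refs) || any(refs <= 0))
      wb_validation_error(paste0("sample ", sid, " has missing/non-positive REF"))
    if (anyDuplicated(refs))
      wb_validation_error(paste0("sample ", sid, " has duplicated REF values"))
  }
  structure(list(
    plate_id = as.character(wells$plate_id[1]),
    assay = assay,
    wells = wells,
    samples = samples
  ), class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  tab <- table(x$wells$role)
  cat(sprintf("<plate_dataset> %s, assay %s: %d wells (%s)\n",
              x$plate_id, x$assay$assay_id, nrow(x$wells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a plate table from CSV
#'
#' Reads one plate's well-level export: plain UTF-8 CSV with a header row and
#' one row per well (`plate_id, well, role, sample_id, ref_concentration,
#' signal, viability`). Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param assay [assay_config()] for the plate.
#' @param samples [sample_records()]; when `NULL`, minimal surface-water
#'   records are synthesized from the sample ids found in the file.
#' @return A [plate_dataset()].
#' @export
read_plate_table <- function(path, assay, samples = NULL) {
  if (!file.exists(path)) wb_format_error(paste0("file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(plate_columns, names(raw))
  if (length(missing_cols))
    wb_format_error(paste0("plate table ", path, " is missing required column(s): ",
                           paste(missing_cols, collapse = ", ")))
  for (col in c("ref_concentration", "signal", "viability")) {
    v <- raw[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        wb_format_error(paste0("non-numeric ", col, " at line(s) ",
                               paste(bad + 1L, collapse = ", "), " of ", path))
      conv[v == ""] <- NA_real_
      raw[[col]] <- conv
    }
  }
  raw$sample_id[is.na(raw$sample_id) | raw$sample_id == ""] <- NA_character_
  if (is.null(samples)) {
    sids <- unique(raw$sample_id[raw$role == "sample"])
    samples <- sample_records(sids[!is.na(sids)])
  }
  plate_dataset(raw, assay, samples)
}

#' Write a plate dataset to CSV
#'
#' Inverse of [read_plate_table()]; round-trips all well-level fields.
#'
#' @param plate A [plate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plate, path) {
  stopifnot(inherits(plate, "plate_dataset"))
  utils::write.csv(plate$wells[plate_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a chemical quantification table and EC library
#'
#' Loads per-sample chemical concentrations (long CSV: `sample_id,
#' chemical_id, category, concentration_ng_L`) together with a library of
#' literature single-chemical effect concentrations (`chemical_id, assay_id,
#' ec10, unit`). Chemicals without a literature EC for a given assay are
#' retained and later flagged bioactivity-unknown; only chemicals with an EC
#' enter concentration-addition predictions.
#'
#' @param chem_path Concentrations CSV.
#' @param ec_path EC-library CSV.
#' @param expected_unit When given, every EC-library unit must equal it
#'   (no silent conversion).
#' @return Object of class `chemical_table`: list with `chemicals` and
#'   `ec_library` data.frames.
#' @export
read_chemical_table <- function(chem_path, ec_path, expected_unit = NULL) {
  chem <- utils::read.csv(chem_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chemical_id", "category", "concentration_ng_L")
  miss <- setdiff(need, names(chem))
  if (length(miss))
    wb_format_error(paste0("chemical table missing column(s): ",
                           paste(miss, collapse = ", ")))
  ec <- utils::read.csv(ec_path, stringsAsFactors = FALSE)
  need_ec <- c("chemical_id", "assay_id", "ec10", "unit")
  miss <- setdiff(need_ec, names(ec))
  if (length(miss))
    wb_format_error(paste0("EC library missing column(s): ",
                           paste(miss, collapse = ", ")))
  chemical_table(chem, ec, expected_unit = expected_unit)
}

#' Construct a chemical table from in-memory data frames
#'
#' @param chemicals data.frame `sample_id, chemical_id, category,
#'   concentration_ng_L`.
#' @param ec_library data.frame `chemical_id, assay_id, ec10, unit`.
#' @param expected_unit Optional required EC unit.
#' @return Object of class `chemical_table`.
#' @export
chemical_table <- function(chemicals, ec_library, expected_unit = NULL) {
  if (any(chemicals$concentration_ng_L < 0, na.rm = TRUE))
    wb_validation_error("chemical concentrations must be >= 0")
  dup <- duplicated(chemicals[c("sample_id", "chemical_id")])
  if (any(dup))
    wb_validation_error(paste0("duplicate (sample, chemical) rows: ",
                               paste(unique(chemicals$chemical_id[dup]), collapse = ", ")))
  if (any(ec_library$ec10 <= 0, na.rm = TRUE))
    wb_validation_error("literature EC10 values must be > 0")
  if (!is.null(expected_unit) && !all(ec_library$unit == expected_unit))
    wb_unit_error(paste0("EC library units differ from expected '", expected_unit,
                         "': ", paste(unique(ec_library$unit), collapse = ", ")))
  structure(list(chemicals = chemicals, ec_library = ec_library),
            class = "chemical_table")
}

#' Chemicals of one sample joined to one assay's EC library
#'
#' @param chemtab A [chemical_table()].
#' @param sample_id Sample to extract.
#' @param assay_id Assay whose literature ECs are joined.
#' @return data.frame `chemical_id, category, concentration_ng_L, ec10,
#'   unit, bioactivity_known`; `ec10` is `NA` for chemicals lacking a
#'   literature EC in this assay.
#' @export
sample_chemicals <- function(chemtab, sample_id, assay_id) {
  stopifnot(inherits(chemtab, "chemical_table"))
  ch <- chemtab$chemicals[chemtab$chemicals$sample_id == sample_id, , drop = FALSE]
  lib <- chemtab$ec_library[chemtab$ec_library$assay_id == assay_id, , drop = FALSE]
  out <- merge(ch, lib[c("chemical_id", "ec10", "unit")],
               by = "chemical_id", all.x = TRUE, sort = TRUE)
  out$bioactivity_known <- !is.na(out$ec10)
  out
}
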