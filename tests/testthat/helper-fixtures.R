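# Shared fixture builders. All randomness is seeded locally; plates and
# series are constructed in code so no binary fixtures are needed.

era_config <- function(...) {
  args <- list(assay_id = "ERalpha", endpoint_kind = "receptor_activation",
               reference_compound = "estradiol", reference_unit = "ng/L",
               benchmark = "EC10", ebt_value = 0.34)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(assay_config, args)
}

# exact 4PL fit object without fitting (for closed-form benchmark checks)
fake_ll4_fit <- function(bottom, top, ec50, hill, covariance = diag(0, 4),
                         r_squared = 1, n = 11) {
  structure(list(bottom = bottom, top = top, ec50 = ec50, hill = hill,
                 covariance = covariance, r_squared = r_squared,
                 rss = 0, n_used = n),
            class = "log_logistic_fit")
}

fake_linear_fit <- function(slope, se_slope = 0, r_squared = 1, n = 5) {
  structure(list(slope = slope, se_slope = se_slope, r_squared = r_squared,
                 n_used = n, free_intercept = FALSE), class = "linear_fit")
}

# a small plate CSV with a given composition, written to a temp file
write_minimal_plate_csv <- function(path, n_series = 2, n_points = 11,
                                    n_controls = 4, drop_col = NULL) {
  rows <- list()
  for (i in seq_len(n_series)) {
    refs <- 100 / 2^(seq_len(n_points) - 1)
    rows[[i]] <- data.frame(
      plate_id = "T1", well = paste0(LETTERS[i], seq_len(n_points)),
      role = "sample", sample_id = sprintf("S%02d", i),
      ref_concentration = refs,
      signal = 2000 + 100 * refs / max(refs), viability = 1)
  }
  rows[[n_series + 1]] <- data.frame(
    plate_id = "T1", well = paste0("P", seq_len(n_controls)),
    role = "negative_control", sample_id = NA,
    ref_concentration = NA, signal = 2000, viability = 1)
  df <- do.call(rbind, rows)
  if (!is.null(drop_col)) df <- df[setdiff(names(df), drop_col)]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}

# central 68.27% half-width of a Monte-Carlo sample: the sigma-equivalent
# robust spread (plain SD does not converge for reciprocal/ratio draws)
robust_mc_sd <- function(x)
  unname(diff(stats::quantile(x, c(0.158655, 0.841345))) / 2)

# iceberg result built directly from contributions (bypasses table plumbing)
make_iceberg <- function(beq_i, ids = sprintf("c%02d", seq_along(beq_i)),
                         categories = rep("x", length(beq_i))) {
  chems <- data.frame(chemical_id = ids, category = categories,
                      concentration_ng_L = beq_i, ec10 = 1,
                      stringsAsFactors = FALSE)
  beq_chem(chems, ec_reference = 1, "S", "A")
}
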