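# End-to-end orchestration: calibrate -> normalize -> mask -> fit ->
# benchmark -> confidence -> classify -> BEQ/SR/EBT -> iceberg, with a
# partial-failure contract (one sample's failure never aborts the run) and
# a machine-readable log of every exclusion and flag.

effect_kind_for <- function(assay) {
  if (assay$benchmark == "EC_IR1.5") "EC_IR1.5" else "EC10"
}

# Fit one sample's specific-effect series by the assay's designated route:
# linear below the cutoff for receptor activation and oxidative stress,
# four-parameter log-logistic for neurite outgrowth.
fit_effect_series <- function(series, assay, max_ref) {
  kind <- effect_kind_for(assay)
  if (nrow(series$points) == 0L) {
    status <- if (any(series$excluded$reason == "cytotoxicity"))
      "masked_by_cytotoxicity" else "needs_manual_review"
    return(effect_estimate(kind, NA_real_, status = status, max_ref = max_ref))
  }
  est <- tryCatch({
    if (assay$endpoint_kind == "neurite_outgrowth") {
      fit <- fit_log_logistic(series)
      benchmark_from_log_logistic(fit, kind, level = 0.10, max_ref = max_ref)
    } else {
      fit <- fit_linear(series, cutoff = assay$linear_cutoff)
      benchmark_from_linear(fit, kind, max_ref = max_ref)
    }
  }, wb_error = function(e) {
    effect_estimate(kind, NA_real_, status = "needs_manual_review",
                    max_ref = max_ref)
  })
  gate_confidence(est, assay$confidence_threshold)
}

# Fit the cytotoxicity channel (viability inhibition vs REF): linear IC10
# for receptor-activation plates, log-logistic IC10 for the oxidative-stress
# and neurite-outgrowth archetypes.
fit_cytotox_series <- function(series, assay, max_ref) {
  if (nrow(series$points) == 0L || max(series$points$response) < 0.10)
    return(effect_estimate("IC10", NA_real_, status = "inactive",
                           max_ref = max_ref))
  est <- tryCatch({
    if (assay$endpoint_kind == "receptor_activation") {
      fit <- fit_linear(series, cutoff = assay$linear_cutoff)
      benchmark_from_linear(fit, "IC10", max_ref = max_ref)
    } else {
      fit <- fit_log_logistic(series)
      benchmark_from_log_logistic(fit, "IC10", level = 0.10, max_ref = max_ref)
    }
  }, wb_error = function(e) {
    effect_estimate("IC10", NA_real_, status = "needs_manual_review",
                    max_ref = max_ref)
  })
  est <- gate_confidence(est, assay$confidence_threshold)
  if (!is.na(est$value) && is.finite(max_ref) && est$value > max_ref) {
    est$status <- "inactive"; est$value <- NA_real_; est$se <- NA_real_
  }
  est
}

#' Evaluate a single plate
#'
#' Runs the per-plate stages of the pipeline: reference calibration with
#' quality control, normalization, viability and cytotoxicity masking,
#' effect and cytotoxicity fitting with benchmark derivation, the
#' confidence gate and activity classification. [run_pipeline()] calls this
#' per plate and adds cross-plate pooling, BEQ derivation, EBT verdicts and
#' iceberg modeling.
#'
#' @param plate A [plate_dataset()].
#' @return list: `fit_rows` (one row per sample and channel), `results`
#'   (per-sample estimate objects), `log` (data.frame of recorded events,
#'   or `NULL`), `calibration` (the plate's [calibrate_reference()] result,
#'   or `NULL` when calibration failed).
#' @export
evaluate_plate <- function(plate) {
  assay <- plate$assay
  wells <- plate$wells
  ctrl <- wells$signal[wells$role == "negative_control"]
  log_rows <- list(); fit_rows <- list(); results <- list()
  log_add <- function(sample_id, stage, code, message) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      plate_id = plate$plate_id, assay_id = assay$assay_id,
      sample_id = sample_id, stage = stage, code = code, message = message,
      stringsAsFactors = FALSE)
  }

  is_ir <- assay$endpoint_kind == "oxidative_stress"
  low <- wells[wells$role == "reference_low", ]
  high <- wells[wells$role == "reference_high", ]
  ref_df <- function(w) {
    resp <- if (is_ir) induction_ratio(w$signal, ctrl) else w$signal
    data.frame(conc = w$ref_concentration, response = resp)
  }
  calib <- tryCatch(
    calibrate_reference(ref_df(low), ref_df(high), assay, plate$plate_id,
                        control_signals = if (is_ir) NULL else ctrl),
    wb_error = function(e) {
      log_add(NA_character_, "calibration", "calibration_failed", conditionMessage(e))
      NULL
    })
  if (!is.null(calib) && !calib$qc_pass)
    log_add(NA_character_, "calibration", "qc_failed",
            sprintf("reference benchmark %.4g outside QC band", calib$ec10_reference))

  for (sid in unique(wells$sample_id[wells$role == "sample"])) {
    sw <- wells[wells$role == "sample" & !is.na(wells$sample_id) &
                  wells$sample_id == sid, ]
    max_ref <- max(sw$ref_concentration)

    # cytotoxicity channel
    cyto <- normalized_series(sid, assay$assay_id, sw$ref_concentration,
                              1 - sw$viability,
                              response_type = "viability_inhibition")
    ic10 <- fit_cytotox_series(cyto, assay, max_ref)

    # specific-effect channel
    series <- tryCatch({
      if (is_ir) {
        normalized_series(sid, assay$assay_id, sw$ref_concentration,
                          induction_ratio(sw$signal, ctrl),
                          viability = sw$viability, response_type = "ir")
      } else {
        if (is.null(calib)) wb_degenerate_error("no reference calibration on this plate")
        normalize_effect(sid, assay$assay_id, sw$ref_concentration, sw$signal,
                         ctrl, calib$fit, viability = sw$viability)
      }
    }, wb_error = function(e) {
      log_add(sid, "normalize", "normalization_failed", conditionMessage(e)); NULL
    })
    if (is.null(series)) next

    series <- apply_viability_mask(series)
    n_viab <- sum(series$excluded$reason == "viability")
    if (n_viab) log_add(sid, "mask", "viability_excluded",
                        sprintf("%d well(s) at viability <= 0.90", n_viab))
    series <- mask_above_ic10(series, ic10)
    n_cyto <- sum(series$excluded$reason == "cytotoxicity")
    if (n_cyto) log_add(sid, "mask", "cytotoxicity_excluded",
                        sprintf("%d well(s) above IC10 = %.4g", n_cyto, ic10$value))

    est <- fit_effect_series(series, assay, max_ref)
    est <- classify_activity(est, ic10, max_ref)
    if (est$status != "valid")
      log_add(sid, "classify", paste0("status_", est$status), est$kind)

    sr <- specificity_ratio(ic10$value, est$value)

    for (e in list(list(ch = "effect", est = est),
                   list(ch = "cytotoxicity", est = ic10))) {
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        plate_id = plate$plate_id, assay_id = assay$assay_id, sample_id = sid,
        channel = e$ch, kind = e$est$kind, value_REF = e$est$value,
        se = e$est$se, r_squared = e$est$r_squared,
        confidence = e$est$confidence, status = e$est$status,
        fit_used = e$est$fit_used, n_used = e$est$n_used,
        n_excluded_viability = if (e$ch == "effect") n_viab else 0L,
        n_excluded_cytotoxicity = if (e$ch == "effect") n_cyto else 0L,
        stringsAsFactors = FALSE)
    }
    results[[sid]] <- list(sample_id = sid, effect = est, ic10 = ic10, sr = sr,
                           calibration = calib, max_ref = max_ref)
  }
  list(fit_rows = do.call(rbind, fit_rows),
       results = results,
       log = if (length(log_rows)) do.call(rbind, log_rows) else NULL,
       calibration = calib)
}

pool_inverse_variance <- function(values, ses) {
  w <- 1 / ses^2
  list(value = sum(w * values) / sum(w), se = sqrt(1 / sum(w)))
}

#' Run the full effect-based evaluation pipeline
#'
#' Executes, for every plate: reference calibration with quality control,
#' normalization to the effect or induction-ratio scale, viability and
#' cytotoxicity masking, linear / log-logistic fitting, benchmark
#' derivation with error propagation, the confidence gate, activity
#' classification, BEQ and specificity-ratio computation and the EBT
#' verdict; then, when a chemical table is supplied, concentration-addition
#' iceberg modeling per sample and assay. Samples measured on several
#' plates are pooled inverse-variance weighted and flagged. Failures are
#' contained per sample and recorded in the run log; remaining samples are
#' unaffected.
#'
#' @param plates A `study_bundle` from [simulate_study()], or a list of
#'   [plate_dataset()]s.
#' @param chemicals Optional [chemical_table()] enabling iceberg modeling
#'   (taken from the bundle when `plates` is one).
#' @param output_dir Optional directory; all reports are written there as
#'   CSV (refusing to overwrite unless `overwrite = TRUE`).
#' @param overwrite Allow overwriting existing report files.
#' @return list of class `pipeline_result`: `fit_report`, `sample_report`,
#'   `iceberg_report`, `driver_table`, `category_profile`, `run_log`
#'   data.frames.
#' @export
run_pipeline <- function(plates, chemicals = NULL, output_dir = NULL,
                         overwrite = FALSE) {
  if (inherits(plates, "study_bundle")) {
    chemicals <- chemicals %||% plates$chemicals
    plates <- plates$plates
  }
  if (inherits(plates, "plate_dataset")) plates <- list(plates)

  fit_report <- list(); logs <- list(); per_assay <- list()
  for (plate in plates) {
    ev <- evaluate_plate(plate)
    fit_report[[length(fit_report) + 1L]] <- ev$fit_rows
    if (!is.null(ev$log)) logs[[length(logs) + 1L]] <- ev$log
    aid <- plate$assay$assay_id
    per_assay[[aid]] <- c(per_assay[[aid]] %||% list(),
                          lapply(ev$results, function(r) {
                            r$assay <- plate$assay; r
                          }))
  }
  fit_report <- do.call(rbind, fit_report)

  sample_rows <- list(); beqs <- list()
  for (aid in names(per_assay)) {
    res <- per_assay[[aid]]
    sids <- vapply(res, `[[`, "", "sample_id")
    for (sid in unique(sids)) {
      rs <- res[sids == sid]
      assay <- rs[[1]]$assay
      valid <- Filter(function(r) r$effect$status == "valid" &&
                        !is.null(r$calibration) && r$calibration$qc_pass, rs)
      pooled <- length(valid) > 1L
      status <- if (length(valid)) "valid" else rs[[1]]$effect$status
      ec_value <- ec_se <- beq_v <- beq_se <- NA_real_
      if (length(valid)) {
        ecs <- vapply(valid, function(r) r$effect$value, numeric(1))
        ses <- vapply(valid, function(r) r$effect$se, numeric(1))
        bq <- lapply(valid, function(r)
          beq_bio(r$calibration$ec10_reference, r$effect$value,
                  r$calibration$se, r$effect$se))
        if (pooled) {
          p_ec <- pool_inverse_variance(ecs, ses)
          ec_value <- p_ec$value; ec_se <- p_ec$se
          p_bq <- pool_inverse_variance(vapply(bq, `[[`, 0, "beq_bio"),
                                        vapply(bq, `[[`, 0, "se_beq"))
          beq_v <- p_bq$value; beq_se <- p_bq$se
        } else {
          ec_value <- ecs[1]; ec_se <- ses[1]
          beq_v <- bq[[1]]$beq_bio; beq_se <- bq[[1]]$se_beq
        }
      } else if (length(rs) > 1L) {
        # report the most informative non-valid status deterministically
        pri <- c(masked_by_cytotoxicity = 1, needs_manual_review = 2, inactive = 3)
        status <- names(sort(pri[unique(vapply(rs, function(r) r$effect$status, ""))]))[1]
      }
      ic10s <- vapply(rs, function(r) r$ic10$value %||% NA_real_, numeric(1))
      ic10_v <- if (all(is.na(ic10s))) NA_real_ else min(ic10s, na.rm = TRUE)
      sr <- if (length(valid)) specificity_ratio(ic10_v, ec_value) else rs[[1]]$sr
      bres <- beq_result(sid, aid,
                         beq_bio = beq_v, se_beq = beq_se,
                         unit = assay$reference_unit,
                         sr_cytotoxicity = sr, status = status)
      bres <- ebt_verdict(bres, assay)
      beqs[[paste(sid, aid)]] <- bres
      sample_rows[[length(sample_rows) + 1L]] <- data.frame(
        sample_id = sid, assay_id = aid, kind = effect_kind_for(assay),
        ec_value_REF = if (status == "valid") ec_value else NA_real_,
        ec_se = if (status == "valid") ec_se else NA_real_,
        ic10_REF = ic10_v,
        sr_cytotoxicity = sr,
        beq_bio = beq_v, se_beq = beq_se, unit = assay$reference_unit,
        ebt_value = assay$ebt_value,
        ebt_exceeded = bres$ebt_exceeded,
        exceedance_ratio = bres$exceedance_ratio,
        status = status, pooled = pooled,
        stringsAsFactors = FALSE)
    }
  }
  sample_report <- do.call(rbind, sample_rows)
  sample_report <- sample_report[order(sample_report$assay_id,
                                       sample_report$sample_id), ]
  rownames(sample_report) <- NULL

  iceberg_report <- driver_table <- cat_profile <- NULL
  if (!is.null(chemicals)) {
    ice_rows <- list(); drv_rows <- list(); cat_rows <- list()
    assays_by_id <- list()
    for (plate in plates) assays_by_id[[plate$assay$assay_id]] <- plate$assay
    for (key in names(beqs)) {
      b <- beqs[[key]]
      assay <- assays_by_id[[b$assay_id]]
      lib <- chemicals$ec_library
      ec_ref <- lib$ec10[lib$assay_id == b$assay_id &
                           lib$chemical_id == assay$reference_compound]
      if (!length(ec_ref)) {
        logs[[length(logs) + 1L]] <- data.frame(
          plate_id = NA, assay_id = b$assay_id, sample_id = b$sample_id,
          stage = "iceberg", code = "no_reference_ec",
          message = "reference compound missing from EC library",
          stringsAsFactors = FALSE)
        next
      }
      ch <- sample_chemicals(chemicals, b$sample_id, b$assay_id)
      ice <- beq_chem(ch, ec_ref[1], b$sample_id, b$assay_id)
      if (b$status == "valid" && is.finite(b$beq_bio) && b$beq_bio > 0)
        ice <- percent_explained(ice, b$beq_bio)
      ice_rows[[key]] <- data.frame(
        sample_id = b$sample_id, assay_id = b$assay_id,
        beq_chem = ice$beq_chem, beq_bio = ice$beq_bio,
        pct_explained = ice$pct_explained, n_to_90pct = ice$n_to_90pct,
        n_quantified = ice$n_quantified,
        n_bioactivity_unknown = ice$n_bioactivity_unknown,
        status = b$status, stringsAsFactors = FALSE)
      if (ice$beq_chem > 0) {
        drv <- top_drivers(ice, 10)
        drv_rows[[key]] <- cbind(sample_id = b$sample_id,
                                 assay_id = b$assay_id, drv)
        cp <- category_profile(ice)
        cat_rows[[key]] <- cbind(sample_id = b$sample_id,
                                 assay_id = b$assay_id, cp)
      }
    }
    iceberg_report <- do.call(rbind, ice_rows)
    driver_table <- do.call(rbind, drv_rows)
    cat_profile <- do.call(rbind, cat_rows)
    for (df in c("iceberg_report", "driver_table", "cat_profile")) {
      v <- get(df)
      if (!is.null(v)) {
        v <- v[order(v$assay_id, v$sample_id), , drop = FALSE]
        rownames(v) <- NULL
        assign(df, v)
      }
    }
  }

  run_log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(plate_id = character(0), assay_id = character(0),
               sample_id = character(0), stage = character(0),
               code = character(0), message = character(0))

  out <- structure(list(fit_report = fit_report, sample_report = sample_report,
                        iceberg_report = iceberg_report,
                        driver_table = driver_table,
                        category_profile = cat_profile,
                        run_log = run_log),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_reports(out, output_dir, overwrite)
  out
}

write_reports <- function(result, output_dir, overwrite = FALSE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(fit_report = "fit_report.csv", sample_report = "sample_report.csv",
             iceberg_report = "iceberg_report.csv",
             driver_table = "driver_table.csv",
             category_profile = "category_profile.csv", run_log = "run_log.csv")
  for (nm in names(files)) {
    df <- result[[nm]]
    if (is.null(df)) next
    path <- file.path(output_dir, files[[nm]])
    if (file.exists(path) && !overwrite)
      wb_validation_error(paste0("refusing to overwrite ", path,
                                 "; use overwrite = TRUE"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(output_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d fits, %d sample rows, %d log entries\n",
              nrow(x$fit_report), nrow(x$sample_report), nrow(x$run_log)))
  invisible(x)
}

#' Summarize a pipeline run per assay
#'
#' Per assay: fraction of samples with a valid (active) benchmark, masked
#' by cytotoxicity, inactive, or referred to manual review; EBT exceedance
#' counts among the evaluable samples; and quartiles of the specificity
#' ratio.
#'
#' @param result A `pipeline_result`, or its `sample_report` data.frame.
#' @return data.frame, one row per assay.
#' @export
summarize_run <- function(result) {
  sr <- if (inherits(result, "pipeline_result")) result$sample_report else result
  out <- lapply(split(sr, sr$assay_id), function(d) {
    n <- nrow(d)
    q <- stats::quantile(d$sr_cytotoxicity, c(0.25, 0.5, 0.75), na.rm = TRUE,
                         names = FALSE)
    data.frame(
      assay_id = d$assay_id[1], n_samples = n,
      frac_active = mean(d$status == "valid"),
      frac_masked = mean(d$status == "masked_by_cytotoxicity"),
      frac_inactive = mean(d$status == "inactive"),
      frac_needs_review = mean(d$status == "needs_manual_review"),
      n_ebt_evaluated = sum(!is.na(d$ebt_exceeded)),
      n_ebt_exceeded = sum(d$ebt_exceeded, na.rm = TRUE),
      sr_q25 = q[1], sr_median = q[2], sr_q75 = q[3],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
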