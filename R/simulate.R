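# Synthetic plate and chemical-table generator with known ground truth.
# The design constants mirror the screening study design: 384-well plates,
# 11-point serial dilutions (factor 2) from a sample-type-specific maximum
# REF (100 surface, 50 WWTP effluent, 25 WWTP influent), reference compound
# in overlapping low/high ranges, negative-control rows, multiplicative
# lognormal signal noise and additive normal viability noise.

#' Evaluate code under a local random seed
#'
#' Runs `code` with the random-number generator seeded to `seed`, then
#' restores the caller's RNG state exactly, so seeded simulation never
#' disturbs surrounding randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @examples
#' with_seed_local(1, runif(2))
#' @export
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# truth curves ---------------------------------------------------------------

# linear-through-origin effect, saturating at `top`; benchmark at 10% effect
truth_effect_linear <- function(x, ec_true, top = 1) {
  pmin(0.1 * x / ec_true, top)
}

# induction ratio, linear in concentration up to saturation; EC_IR1.5 at IR 1.5
truth_ir_linear <- function(x, ec_true, ir_max = 6) {
  1 + pmin(0.5 * x / ec_true, ir_max - 1)
}

# 4PL effect anchored so the 10% absolute crossing sits at ec_true
truth_effect_4pl <- function(x, ec_true, hill = 1.5, top = 1) {
  ec50 <- ec_true * ((top - 0.1) / 0.1)^(1 / hill)
  top / (1 + (ec50 / x)^hill)
}

# cytotoxic inhibition (1 - viability); IC10 at 10% inhibition
truth_inhibition_linear <- function(x, ic10) pmin(0.1 * x / ic10, 1)
truth_inhibition_4pl <- function(x, ic10, hill = 1.5) {
  ec50 <- ic10 * 9^(1 / hill)
  1 / (1 + (ec50 / x)^hill)
}

#' Ground-truth table for synthetic samples
#'
#' @param sample_id Labels.
#' @param ec_true True benchmark concentration in REF (EC10, or EC_IR1.5
#'   for oxidative-stress assays). `Inf` means no effect at any tested
#'   concentration.
#' @param ic10_true True cytotoxicity IC10 in REF (`Inf`: no cytotoxicity).
#' @param hill_effect,hill_cytotox Hill slopes of the 4PL truth curves
#'   (ignored for archetypes with linear truth).
#' @param top_effect Effect plateau as fraction of the reference maximum.
#' @param active Optional logical label asserting the sample responds
#'   within the tested range; [generate_plate()] rejects truths labelled
#'   active whose benchmark lies above the maximum tested REF.
#' @return data.frame of class `sample_truth`.
#' @export
sample_truth <- function(sample_id, ec_true, ic10_true = Inf,
                         hill_effect = 1.5, hill_cytotox = 1.5,
                         top_effect = 1, active = NA) {
  out <- data.frame(sample_id = as.character(sample_id),
                    ec_true = ec_true,
                    ic10_true = rep_len(ic10_true, length(sample_id)),
                    hill_effect = rep_len(hill_effect, length(sample_id)),
                    hill_cytotox = rep_len(hill_cytotox, length(sample_id)),
                    top_effect = rep_len(top_effect, length(sample_id)),
                    active = rep_len(active, length(sample_id)),
                    stringsAsFactors = FALSE)
  if (any(out$ec_true <= 0) || any(out$ic10_true <= 0))
    wb_parameter_error("true benchmarks must be > 0 (Inf for no effect)")
  class(out) <- c("sample_truth", "data.frame")
  out
}

#' Default reference-compound truth for a synthetic assay
#'
#' The generating parameters of the reference compound's curve per assay:
#' its true benchmark concentration (`ec_benchmark`, in the assay's
#' reference unit), Hill slope, signal plateau and, for induction-ratio
#' endpoints, the maximum induction ratio.
#'
#' @param assay An [assay_config()].
#' @return list: `ec_benchmark`, `hill`, `top_signal`, `ir_max`.
#' @export
default_reference_truth <- function(assay) {
  switch(assay$endpoint_kind,
    receptor_activation = ,
    neurite_outgrowth = list(
      ec_benchmark = switch(assay$assay_id,
                            ERalpha = 0.68, AhR = 500, SHSY5Y = 1000, 100),
      hill = 1.2, top_signal = 20000, ir_max = NA_real_),
    oxidative_stress = list(
      ec_benchmark = 1e5, hill = 1.5, top_signal = NA_real_, ir_max = 6),
    wb_parameter_error("no reference truth defaults for this endpoint kind")
  )
}

plate_row_names <- LETTERS[1:16]

#' Generate a synthetic 384-well bioassay plate with known truth
#'
#' Lays out a full screening plate: reference compound in a low and a high
#' 11-point range in row A (overlapping near 50\% effect), up to 26 sample
#' dilution series (11 points, factor `dilution_factor` down from the
#' sample type's maximum REF) in rows B-N, and the last two rows (O, P) as
#' negative controls. Effect signals follow the archetype's truth curve -
#' linear through the origin with saturation for endpoints evaluated
#' linearly (receptor activation, oxidative stress), four-parameter
#' log-logistic for neurite outgrowth - and carry multiplicative lognormal
#' noise; viability follows an independent cytotoxicity curve with additive
#' normal noise.
#'
#' @param assay An [assay_config()].
#' @param truth A [sample_truth()] table (max 26 samples per plate).
#' @param seed Integer seed; identical (parameters, seed) give identical
#'   plates. The caller's RNG state is left untouched.
#' @param sample_type Sample type; fixes the maximum REF via the assay
#'   config.
#' @param plate_id Plate label.
#' @param n_points,dilution_factor Serial-dilution design (11 points,
#'   factor 2).
#' @param signal_cv Coefficient of variation of the multiplicative signal
#'   noise (default 0.05).
#' @param viability_sd SD of the additive viability noise (default 0.02).
#' @param control_signal Mean negative-control signal (RLU).
#' @param cytotoxic_suppression When `TRUE`, effect-well signals are
#'   additionally scaled by the true viable fraction, mimicking the loss of
#'   reporter signal from dying cells that motivates the masking rules.
#'   Default `FALSE`: the effect and cytotoxicity channels are generated
#'   independently, so effect recovery can be assessed without confounding.
#' @param reference Optional list overriding the reference-compound truth
#'   (`ec_benchmark`, `hill`, `top_signal`, `ir_max`).
#' @return A [plate_dataset()]; the generating truth (sample truths,
#'   reference truth, noise parameters, seed) is attached as
#'   `attr(, "truth")`.
#' @export
generate_plate <- function(assay, truth, seed, sample_type = "surface",
                           plate_id = "P1", n_points = 11, dilution_factor = 2,
                           signal_cv = 0.05, viability_sd = 0.02,
                           control_signal = 2000, cytotoxic_suppression = FALSE,
                           reference = NULL) {
  stopifnot(inherits(assay, "assay_config"), inherits(truth, "sample_truth"))
  if (assay$endpoint_kind == "cytotoxicity")
    wb_parameter_error("generate whole plates for effect archetypes; cytotoxicity is read from their viability channel")
  if (nrow(truth) > 26L)
    wb_generator_error("at most 26 sample series fit on one plate")
  if (!sample_type %in% names(assay$max_ref_by_sample_type))
    wb_parameter_error(paste0("no max REF configured for sample type ", sample_type))
  max_ref <- assay$max_ref_by_sample_type[[sample_type]]
  if ("active" %in% names(truth)) {
    bad <- !is.na(truth$active) & truth$active &
      is.finite(truth$ec_true) & truth$ec_true > max_ref
    if (any(bad))
      wb_generator_error(paste0("truth labelled active but benchmark above max REF: ",
                                paste(truth$sample_id[bad], collapse = ", ")))
  }
  ref_truth <- reference %||% default_reference_truth(assay)
  is_ir <- assay$endpoint_kind == "oxidative_stress"

  with_seed_local(seed, {
    refs <- max_ref / dilution_factor^(seq_len(n_points) - 1)

    # reference compound ranges (concentration units of the reference compound)
    hill_r <- ref_truth$hill
    if (is_ir) {
      ec50_r <- ref_truth$ec_benchmark * ((ref_truth$ir_max - 1.5) / 0.5)^(1 / hill_r)
    } else {
      ec50_r <- ref_truth$ec_benchmark * 9^(1 / hill_r)
    }
    low_conc <- ec50_r * 1.5 / dilution_factor^(seq_len(n_points) - 1)
    high_conc <- ec50_r * 0.6 * dilution_factor^(seq_len(n_points) - 1)
    ref_response <- function(conc) {
      if (is_ir) {
        ir <- 1 + (ref_truth$ir_max - 1) / (1 + (ec50_r / conc)^hill_r)
        control_signal * ir
      } else {
        control_signal + (ref_truth$top_signal - control_signal) /
          (1 + (ec50_r / conc)^hill_r)
      }
    }

    wells <- list()
    add_wells <- function(row, cols, role, sample_id, conc, signal, viability) {
      wells[[length(wells) + 1L]] <<- data.frame(
        plate_id = plate_id,
        well = paste0(row, cols),
        role = role,
        sample_id = sample_id,
        ref_concentration = conc,
        signal = signal,
        viability = viability,
        stringsAsFactors = FALSE
      )
    }

    sig_lo <- ref_response(low_conc) * lognormal_noise(n_points, signal_cv)
    sig_hi <- ref_response(high_conc) * lognormal_noise(n_points, signal_cv)
    add_wells("A", 1:n_points, "reference_low", NA_character_, low_conc,
              sig_lo, pmax(0, 1 + stats::rnorm(n_points, 0, viability_sd)))
    add_wells("A", (n_points + 1):(2 * n_points), "reference_high", NA_character_,
              high_conc, sig_hi,
              pmax(0, 1 + stats::rnorm(n_points, 0, viability_sd)))

    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      resp <- switch(assay$endpoint_kind,
        receptor_activation = truth_effect_linear(refs, tr$ec_true, tr$top_effect),
        oxidative_stress = truth_ir_linear(refs, tr$ec_true),
        neurite_outgrowth = truth_effect_4pl(refs, tr$ec_true, tr$hill_effect,
                                             tr$top_effect))
      sig_true <- if (is_ir) control_signal * resp
                  else control_signal + resp * (ref_truth$top_signal - control_signal)
      inhib <- switch(assay$endpoint_kind,
        receptor_activation = truth_inhibition_linear(refs, tr$ic10_true),
        truth_inhibition_4pl(refs, tr$ic10_true, tr$hill_cytotox))
      if (cytotoxic_suppression) sig_true <- sig_true * (1 - inhib)
      sig <- sig_true * lognormal_noise(n_points, signal_cv)
      viab <- pmax(0, 1 - inhib + stats::rnorm(n_points, 0, viability_sd))
      row <- plate_row_names[1 + ceiling(i / 2)]
      cols <- if (i %% 2 == 1) 1:n_points else (n_points + 1):(2 * n_points)
      add_wells(row, cols, "sample", tr$sample_id, refs, sig, viab)
    }

    for (row in c("O", "P")) {
      add_wells(row, 1:24, "negative_control", NA_character_, NA_real_,
                control_signal * lognormal_noise(24, signal_cv),
                pmax(0, 1 + stats::rnorm(24, 0, viability_sd)))
    }

    wells <- do.call(rbind, wells)
    samples <- sample_records(truth$sample_id, sample_type = sample_type)
    plate <- plate_dataset(wells, assay, samples)
    attr(plate, "truth") <- list(
      samples = truth, reference = ref_truth,
      sample_type = sample_type, max_ref = max_ref,
      noise = list(signal_cv = signal_cv, viability_sd = viability_sd),
      seed = seed
    )
    plate
  })
}

#' Generate a synthetic chemical quantification table with known truth
#'
#' Emulates a target-screening result: `n_chemicals` chemicals with
#' log-uniform relative effect potencies (REP, default over 1e-6..1),
#' lognormal concentrations per sample, and a configurable fraction of
#' chemicals carrying a literature EC per assay (the rest are
#' bioactivity-unknown and excluded from concentration-addition
#' predictions, as in real iceberg studies). The per-sample true BEQ_chem
#' over EC-covered chemicals is recorded, and when an explained fraction
#' `phi` is given, a matched true `BEQ_bio = BEQ_chem / phi` is constructed
#' so the percent-explained computation can be exercised end to end.
#'
#' @param n_chemicals Number of chemicals.
#' @param sample_ids Sample labels.
#' @param assays Named list of [assay_config()] (REPs and EC coverage drawn
#'   per assay).
#' @param ec_reference Named numeric: literature benchmark of each assay's
#'   reference compound in its reference unit.
#' @param seed Integer seed.
#' @param fraction_with_ec Probability a chemical has a literature EC in a
#'   given assay.
#' @param rep_range REP range, sampled log-uniformly.
#' @param conc_meanlog,conc_sdlog Lognormal concentration parameters (ng/L).
#' @param categories Category labels sampled per chemical.
#' @param phi Optional explained fraction used to construct matched
#'   `beq_bio` truths.
#' @return list: `table` (a [chemical_table()] whose EC library includes the
#'   reference compounds), `truth` (list with per-chemical REPs and a
#'   per-sample-x-assay data.frame `beq` of true `beq_chem`/`beq_bio`),
#'   `seed`.
#' @export
generate_chemical_table <- function(n_chemicals, sample_ids, assays,
                                    ec_reference, seed,
                                    fraction_with_ec = 0.8,
                                    rep_range = c(1e-6, 1),
                                    conc_meanlog = log(50), conc_sdlog = 1.5,
                                    categories = c("pesticide", "pharmaceutical",
                                                   "polymer_additive", "industrial"),
                                    phi = NULL) {
  if (fraction_with_ec < 0 || fraction_with_ec > 1)
    wb_parameter_error("fraction_with_ec must lie in [0, 1]")
  stopifnot(all(names(assays) %in% names(ec_reference) |
                  vapply(assays, function(a) a$assay_id, "") %in% names(ec_reference)))
  with_seed_local(seed, {
    chem_ids <- sprintf("chem%03d", seq_len(n_chemicals))
    cat_i <- sample(categories, n_chemicals, replace = TRUE)

    chem <- expand.grid(sample_id = sample_ids, chemical_id = chem_ids,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    chem <- chem[order(chem$sample_id, chem$chemical_id), ]
    rownames(chem) <- NULL
    chem$category <- cat_i[match(chem$chemical_id, chem_ids)]
    chem$concentration_ng_L <- stats::rlnorm(nrow(chem), conc_meanlog, conc_sdlog)

    ec_rows <- list(); rep_truth <- list()
    for (aname in names(assays)) {
      aid <- assays[[aname]]$assay_id
      ecr <- ec_reference[[aid]] %||% ec_reference[[aname]]
      reps <- exp(stats::runif(n_chemicals, log(rep_range[1]), log(rep_range[2])))
      has_ec <- stats::runif(n_chemicals) < fraction_with_ec
      rep_truth[[aid]] <- data.frame(chemical_id = chem_ids, rep = reps,
                                     has_ec = has_ec, stringsAsFactors = FALSE)
      ec_rows[[aid]] <- rbind(
        data.frame(chemical_id = chem_ids[has_ec], assay_id = aid,
                   ec10 = ecr / reps[has_ec],
                   unit = assays[[aname]]$reference_unit,
                   stringsAsFactors = FALSE),
        data.frame(chemical_id = assays[[aname]]$reference_compound,
                   assay_id = aid, ec10 = ecr,
                   unit = assays[[aname]]$reference_unit,
                   stringsAsFactors = FALSE))
    }
    ec_library <- do.call(rbind, ec_rows)
    rownames(ec_library) <- NULL
    tab <- chemical_table(chem, ec_library)

    beq <- expand.grid(sample_id = sample_ids,
                       assay_id = vapply(assays, function(a) a$assay_id, ""),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    beq$beq_chem_true <- mapply(function(sid, aid) {
      rt <- rep_truth[[aid]]
      ci <- chem$concentration_ng_L[chem$sample_id == sid]
      ids <- chem$chemical_id[chem$sample_id == sid]
      sum(rt$rep[match(ids, rt$chemical_id)] * ci * rt$has_ec[match(ids, rt$chemical_id)])
    }, beq$sample_id, beq$assay_id)
    beq$beq_bio_true <- if (!is.null(phi)) beq$beq_chem_true / phi else NA_real_
    rownames(beq) <- NULL

    list(table = tab,
         truth = list(rep = rep_truth, beq = beq, phi = phi, seed = seed),
         seed = seed)
  })
}

#' Simulate a complete synthetic screening study
#'
#' Draws per-sample effect and cytotoxicity truths for each assay, lays the
#' samples out on as many plates as needed (up to 26 series per plate), and
#' generates a matching chemical quantification table. True benchmark
#' concentrations are drawn log-uniformly inside the quantifiable range and
#' true specificity ratios log-uniformly over 1-100, spanning the specific
#' and cytotoxicity-masked regimes; a fraction of samples is made inactive.
#'
#' @param assays Named list of [assay_config()] (default:
#'   [default_assay_battery()]).
#' @param n_samples Number of water samples.
#' @param seed Integer seed; everything (truths, plates, chemicals) derives
#'   from it deterministically.
#' @param sample_type Sample type for all samples.
#' @param inactive_fraction Fraction of sample-x-assay truths with no
#'   effect in the tested range.
#' @param n_chemicals Chemicals in the quantification table.
#' @param signal_cv,viability_sd Noise parameters passed to
#'   [generate_plate()].
#' @param phi Optional explained fraction coupling the chemical table to
#'   the plate truths: each sample's chemical concentrations are rescaled
#'   so that the concentration-addition sum over EC-covered chemicals
#'   equals `phi` times the sample's true BEQ_bio in the first assay
#'   (`BEQ_bio = EC_ref / EC_true`). With `phi = 1` the quantified
#'   chemicals fully explain the measured mixture effect - the ideal
#'   iceberg limit.
#' @return list of class `study_bundle`: `plates` (list of
#'   [plate_dataset()]), `chemicals` (a [chemical_table()]), `assays`,
#'   `truth` (per-assay sample truths plus chemical truths), `seed`.
#' @export
simulate_study <- function(assays = default_assay_battery(), n_samples = 10,
                           seed = 1, sample_type = "surface",
                           inactive_fraction = 0.1, n_chemicals = 60,
                           signal_cv = 0.05, viability_sd = 0.02, phi = NULL) {
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  plates <- list(); truths <- list()
  ec_reference <- vapply(assays, function(a) default_reference_truth(a)$ec_benchmark,
                         numeric(1))
  names(ec_reference) <- vapply(assays, function(a) a$assay_id, "")
  k <- 0L
  for (aname in names(assays)) {
    a <- assays[[aname]]
    k <- k + 1L
    max_ref <- a$max_ref_by_sample_type[[sample_type]]
    tr <- with_seed_local(seed + 1000L * k, {
      ec <- exp(stats::runif(n_samples, log(max_ref / 50), log(max_ref / 2)))
      sr <- exp(stats::runif(n_samples, log(1), log(100)))
      inact <- stats::runif(n_samples) < inactive_fraction
      ec[inact] <- Inf
      sample_truth(sample_ids, ec_true = ec,
                   ic10_true = ifelse(inact, Inf, ec * sr))
    })
    truths[[a$assay_id]] <- tr
    idx <- split(seq_len(n_samples), ceiling(seq_len(n_samples) / 26))
    for (j in seq_along(idx)) {
      pid <- sprintf("%s_plate%02d", a$assay_id, j)
      plates[[pid]] <- generate_plate(
        a, tr[idx[[j]], ], seed = seed + 1000L * k + j,
        sample_type = sample_type, plate_id = pid,
        signal_cv = signal_cv, viability_sd = viability_sd)
    }
  }
  chem <- generate_chemical_table(n_chemicals, sample_ids, assays,
                                  ec_reference, seed = seed + 99L)
  if (!is.null(phi)) {
    # couple the chemical table to the first assay's plate truths: rescale
    # each sample's concentrations so BEQ_chem = phi * true BEQ_bio
    aid <- vapply(assays, function(a) a$assay_id, "")[1]
    tr <- truths[[aid]]
    bq <- chem$truth$beq
    for (i in seq_len(nrow(tr))) {
      sid <- tr$sample_id[i]
      if (!is.finite(tr$ec_true[i])) next
      target <- phi * ec_reference[[aid]] / tr$ec_true[i]
      cur <- bq$beq_chem_true[bq$sample_id == sid & bq$assay_id == aid]
      if (cur <= 0) next
      fac <- target / cur
      rows <- chem$table$chemicals$sample_id == sid
      chem$table$chemicals$concentration_ng_L[rows] <-
        chem$table$chemicals$concentration_ng_L[rows] * fac
      for (a2 in unique(bq$assay_id)) {
        j <- bq$sample_id == sid & bq$assay_id == a2
        bq$beq_chem_true[j] <- bq$beq_chem_true[j] * fac
      }
      bq$beq_bio_true[bq$sample_id == sid & bq$assay_id == aid] <- target / phi
    }
    chem$truth$beq <- bq
    chem$truth$phi <- phi
  }
  structure(list(plates = plates, chemicals = chem$table, assays = assays,
                 truth = list(samples = truths, chemicals = chem$truth,
                              ec_reference = ec_reference),
                 seed = seed),
            class = "study_bundle")
}

#' Write a simulated study bundle to plain-text files
#'
#' Emits one CSV per plate, the chemical quantification CSV, the EC-library
#' CSV and a ground-truth manifest (JSON) into a directory, so a full
#' analysis can be driven from files alone.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse to overwrite existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, paste0(names(bundle$plates), ".csv")),
             file.path(dir, c("chemicals.csv", "ec_library.csv", "truth.json")))
  if (!overwrite && any(file.exists(paths)))
    wb_validation_error("output files already exist; use overwrite = TRUE")
  for (pid in names(bundle$plates))
    write_plate_table(bundle$plates[[pid]], file.path(dir, paste0(pid, ".csv")))
  utils::write.csv(bundle$chemicals$chemicals, file.path(dir, "chemicals.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$chemicals$ec_library, file.path(dir, "ec_library.csv"),
                   row.names = FALSE)
  truth <- bundle$truth
  truth$samples <- lapply(truth$samples, as.data.frame)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
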