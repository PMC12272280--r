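#' Assay endpoint configuration
#'
#' Describes one bioassay endpoint: what kind of effect it reads out, which
#' reference compound anchors the response scale and the bioanalytical
#' equivalent concentration (BEQ), which benchmark concentration is reported
#' (EC10 at 10\% absolute effect, or the concentration reaching an induction
#' ratio of 1.5 for oxidative stress), the effect-based trigger value (EBT)
#' the BEQ is compared against, and the evaluation constants: the 30\% effect
#' cutoff bounding the linear portion of the concentration-response curve and
#' the 0.7 confidence threshold below which a fit is referred to manual
#' review.
#'
#' @param assay_id Short assay label, e.g. `"ERalpha"`.
#' @param endpoint_kind One of `"receptor_activation"`, `"oxidative_stress"`,
#'   `"neurite_outgrowth"`, `"cytotoxicity"`.
#' @param reference_compound Name of the reference compound run on every
#'   plate (e.g. estradiol, benzo\[a\]pyrene, dichlorvos, narciclasine).
#' @param reference_unit Concentration unit of the reference compound and of
#'   the EBT, e.g. `"ng/L"`. BEQ results carry this unit.
#' @param benchmark `"EC10"` or `"EC_IR1.5"`. `"EC_IR1.5"` is only valid for
#'   oxidative-stress endpoints, where the induction ratio replaces the
#'   effect scale.
#' @param ebt_value Effect-based trigger value in `reference_unit`, or `NA`
#'   when no EBT exists for the endpoint.
#' @param linear_cutoff Absolute effect fraction bounding the linear fit
#'   region (default 0.30).
#' @param confidence_threshold Minimum confidence score (default 0.7); fits
#'   scoring below are flagged `needs_manual_review`.
#' @param max_ref_by_sample_type Named numeric vector mapping sample type to
#'   the highest tested relative enrichment factor (REF), e.g.
#'   `c(surface = 100, wwtp_effluent = 50, wwtp_influent = 25)`.
#' @param qc_band Optional length-2 numeric: acceptable range for the
#'   reference compound benchmark concentration (plate quality control).
#'
#' @return An object of class `assay_config`.
#' @examples
#' cfg <- assay_config("ERalpha", "receptor_activation", "estradiol", "ng/L",
#'                     benchmark = "EC10", ebt_value = 0.34)
#' cfg$ebt_value
#' @export
assay_config <- function(assay_id,
                         endpoint_kind = c("receptor_activation", "oxidative_stress",
                                           "neurite_outgrowth", "cytotoxicity"),
                         reference_compound,
                         reference_unit = "ng/L",
                         benchmark = c("EC10", "EC_IR1.5"),
                         ebt_value = NA_real_,
                         linear_cutoff = 0.30,
                         confidence_threshold = 0.7,
                         max_ref_by_sample_type = c(surface = 100, tributary = 100,
                                                    tidal = 100, german_bight = 100,
                                                    field_blank = 100, process_blank = 100,
                                                    wwtp_effluent = 50, wwtp_influent = 25),
                         qc_band = NULL) {
  endpoint_kind <- match.arg(endpoint_kind)
  benchmark <- match.arg(benchmark)
  stopifnot(is.character(assay_id), length(assay_id) == 1L,
            is.character(reference_compound), length(reference_compound) == 1L)
  if (!is.na(ebt_value) && ebt_value <= 0)
    wb_parameter_error("ebt_value must be > 0 when present")
  if (!(linear_cutoff > 0 && linear_cutoff <= 1))
    wb_parameter_error("linear_cutoff must lie in (0, 1]")
  if (!(confidence_threshold > 0 && confidence_threshold <= 1))
    wb_parameter_error("confidence_threshold must lie in (0, 1]")
  if (benchmark == "EC_IR1.5" && endpoint_kind != "oxidative_stress")
    wb_parameter_error("benchmark EC_IR1.5 is only defined for oxidative_stress endpoints")
  if (any(max_ref_by_sample_type <= 0) || is.null(names(max_ref_by_sample_type)))
    wb_parameter_error("max_ref_by_sample_type must be a named vector of positive REFs")
  if (!is.null(qc_band) && (length(qc_band) != 2L || qc_band[1] >= qc_band[2]))
    wb_parameter_error("qc_band must be c(lower, upper) with lower < upper")
  structure(list(
    assay_id = assay_id,
    endpoint_kind = endpoint_kind,
    reference_compound = reference_compound,
    reference_unit = reference_unit,
    benchmark = benchmark,
    ebt_value = ebt_value,
    linear_cutoff = linear_cutoff,
    confidence_threshold = confidence_threshold,
    max_ref_by_sample_type = max_ref_by_sample_type,
    qc_band = qc_band
  ), class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("<assay_config> %s (%s)\n", x$assay_id, x$endpoint_kind))
  cat(sprintf("  reference: %s [%s], benchmark %s\n",
              x$reference_compound, x$reference_unit, x$benchmark))
  if (!is.na(x$ebt_value))
    cat(sprintf("  EBT: %g %s\n", x$ebt_value, x$reference_unit))
  cat(sprintf("  linear cutoff %.2f, confidence threshold %.2f\n",
              x$linear_cutoff, x$confidence_threshold))
  invisible(x)
}

#' Bundled example assay battery
#'
#' Four endpoint configurations mirroring a typical surface-water screening
#' battery: aryl-hydrocarbon receptor activation (BaP-EQ, EBT 250 ng/L),
#' oxidative stress response (Dichlorvos-EQ, EBT 1.4e6 ng/L), estrogen
#' receptor alpha activation (EEQ, EBT 0.34 ng/L), and neurite outgrowth
#' inhibition (Narciclasine-EQ, EBT 283 ng/L). All EBTs are expressed in
#' ng/L of the respective quality-control surrogate reference compound.
#'
#' @return Named list of [assay_config()] objects.
#' @export
default_assay_battery <- function() {
  list(
    AhR = assay_config("AhR", "receptor_activation", "benzo[a]pyrene", "ng/L",
                       benchmark = "EC10", ebt_value = 250),
    AREc32 = assay_config("AREc32", "oxidative_stress", "dichlorvos", "ng/L",
                          benchmark = "EC_IR1.5", ebt_value = 1.4e6),
    ERalpha = assay_config("ERalpha", "receptor_activation", "estradiol", "ng/L",
                           benchmark = "EC10", ebt_value = 0.34),
    SHSY5Y = assay_config("SHSY5Y", "neurite_outgrowth", "narciclasine", "ng/L",
                          benchmark = "EC10", ebt_value = 283)
  )
}

sample_types <- c("surface", "tributary", "tidal", "german_bight",
                  "wwtp_influent", "wwtp_effluent", "field_blank", "process_blank")

#' Sample metadata records
#'
#' Builds the per-sample metadata table: sample type (which fixes the highest
#' tested REF), site, lateral position in the river cross-section, and the
#' solid-phase extraction enrichment factor EF (litres of water per litre of
#' extract) from which REF = EF x DF is reconstructed.
#'
#' @param sample_id Character vector of sample labels.
#' @param sample_type One of the recognized sample types (recycled).
#' @param site Site labels (recycled).
#' @param lateral_position `"left"`, `"middle"`, `"right"` or `"na"` (recycled).
#' @param extraction_factor EF in L water / L extract (recycled, default 1000).
#' @return A data.frame of class `sample_records`.
#' @export
sample_records <- function(sample_id, sample_type = "surface", site = "site",
                           lateral_position = "na", extraction_factor = 1000) {
  if (!all(sample_type %in% sample_types))
    wb_validation_error(paste0("unknown sample_type: ",
                               paste(setdiff(sample_type, sample_types), collapse = ", ")))
  if (!all(lateral_position %in% c("left", "middle", "right", "na")))
    wb_validation_error("lateral_position must be left/middle/right/na")
  if (any(extraction_factor <= 0))
    wb_validation_error("extraction_factor must be > 0")
  river <- sample_type %in% c("surface", "tributary", "tidal")
  lp <- rep_len(lateral_position, length(sample_id))
  if (any(lp != "na" & !rep_len(river, length(sample_id))))
    wb_validation_error("lateral_position is only defined for river samples")
  out <- data.frame(
    sample_id = as.character(sample_id),
    sample_type = rep_len(sample_type, length(sample_id)),
    site = rep_len(as.character(site), length(sample_id)),
    lateral_position = lp,
    extraction_factor = rep_len(extraction_factor, length(sample_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sample_records", "data.frame")
  out
}
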