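# Domain types: one constructor + validator per spec type.  All objects are
# plain lists with an S3 class; validators stop() with the offending field
# name so I/O can report line numbers.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

.check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  x
}

.check_enum <- function(x, levels, field) {
  if (!is.character(x) || length(x) != 1L || !(x %in% levels)) {
    abort_field(field, sprintf("must be one of %s", paste(levels, collapse = ", ")))
  }
  x
}

#' Create a tumor measurement
#'
#' One diameter observation within a report history.  Reports after surgery
#' or systemic therapy often carry several measurements; the staging rules
#' use the most recent one obtained after the current treatment cycle (see
#' [select_current_diameter()]).
#'
#' @param diameter_mm Positive diameter in millimetres.
#' @param sequence_index Integer order of the measurement in the report
#'   history (unique within one case).
#' @param post_current_treatment Was the measurement taken after the current
#'   treatment cycle?
#' @return A `measurement` object.
#' @export
#' @examples
#' measurement(39, 1)
measurement <- function(diameter_mm, sequence_index = 1L,
                        post_current_treatment = FALSE) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      is.na(diameter_mm) || diameter_mm <= 0) {
    abort_field("diameter_mm", "must be a positive number of millimetres")
  }
  if (!is.numeric(sequence_index) || length(sequence_index) != 1L ||
      is.na(sequence_index) || sequence_index != as.integer(sequence_index)) {
    abort_field("sequence_index", "must be an integer")
  }
  structure(
    list(diameter_mm = as.numeric(diameter_mm),
         sequence_index = as.integer(sequence_index),
         post_current_treatment = .check_flag(post_current_treatment,
                                              "post_current_treatment")),
    class = "measurement"
  )
}

#' Structured primary-tumor findings
#'
#' @param measurements List of [measurement()] objects (possibly empty).
#' @param lobe Lung lobe code (`RUL`, `RML`, `RLL`, `LUL`, `LLL`, `unknown`).
#' @param trans_lobar Tumor crosses a lobe boundary.
#' @param invasion_sites Character vector of invasion-site codes (see
#'   [invasion_sites()]).
#' @param nodule_same_lobe Isolated cancer nodule in the same lobe.
#' @param nodule_other_ipsilateral_lobe Cancer nodule in a different
#'   ipsilateral lobe.
#' @param atelectasis_to_hilum Atelectasis or obstructive pneumonia extending
#'   to the hilar region.
#' @param carcinoma_in_situ Explicit in-situ carcinoma statement.
#' @param minimally_invasive_adeno Explicit minimally invasive adenocarcinoma
#'   diagnosis.
#' @param primary_tumor_mentioned Is a primary tumor mentioned at all?
#'   Defaults to `TRUE` when any measurement or tumor-positive flag is
#'   present.
#' @param evaluable Can the primary tumor be evaluated from the report?
#' @return A `tumor_findings` object.
#' @export
tumor_findings <- function(measurements = list(),
                           lobe = "unknown",
                           trans_lobar = FALSE,
                           invasion_sites = character(),
                           nodule_same_lobe = FALSE,
                           nodule_other_ipsilateral_lobe = FALSE,
                           atelectasis_to_hilum = FALSE,
                           carcinoma_in_situ = FALSE,
                           minimally_invasive_adeno = FALSE,
                           primary_tumor_mentioned = NULL,
                           evaluable = TRUE) {
  if (!is.list(measurements) ||
      !all(vapply(measurements, inherits, logical(1), "measurement"))) {
    abort_field("measurements", "must be a list of measurement() objects")
  }
  idx <- vapply(measurements, `[[`, integer(1), "sequence_index")
  if (anyDuplicated(idx)) {
    abort_field("sequence_index", "must be unique within one case")
  }
  invasion_sites <- unique(as.character(invasion_sites))
  bad <- setdiff(invasion_sites, invasion_sites()$code)
  if (length(bad)) {
    abort_field("invasion_sites", paste("unknown site:", paste(bad, collapse = ", ")))
  }
  flags <- c(trans_lobar = .check_flag(trans_lobar, "trans_lobar"),
             nodule_same_lobe = .check_flag(nodule_same_lobe, "nodule_same_lobe"),
             nodule_other = .check_flag(nodule_other_ipsilateral_lobe,
                                        "nodule_other_ipsilateral_lobe"),
             atelectasis = .check_flag(atelectasis_to_hilum, "atelectasis_to_hilum"),
             cis = .check_flag(carcinoma_in_situ, "carcinoma_in_situ"),
             mia = .check_flag(minimally_invasive_adeno, "minimally_invasive_adeno"))
  if (is.null(primary_tumor_mentioned)) {
    primary_tumor_mentioned <- length(measurements) > 0L ||
      length(invasion_sites) > 0L || any(flags[c("nodule_same_lobe",
                                                 "nodule_other", "cis", "mia")])
  }
  primary_tumor_mentioned <- .check_flag(primary_tumor_mentioned,
                                         "primary_tumor_mentioned")
  if (length(measurements) > 0L && !primary_tumor_mentioned) {
    abort_field("primary_tumor_mentioned",
                "must be TRUE when measurements are present")
  }
  structure(
    list(measurements = measurements,
         lobe = .check_enum(lobe, lobe_levels(), "lobe"),
         trans_lobar = trans_lobar,
         invasion_sites = invasion_sites,
         nodule_same_lobe = nodule_same_lobe,
         nodule_other_ipsilateral_lobe = nodule_other_ipsilateral_lobe,
         atelectasis_to_hilum = atelectasis_to_hilum,
         carcinoma_in_situ = carcinoma_in_situ,
         minimally_invasive_adeno = minimally_invasive_adeno,
         primary_tumor_mentioned = primary_tumor_mentioned,
         evaluable = .check_flag(evaluable, "evaluable")),
    class = "tumor_findings"
  )
}

#' Structured nodal findings
#'
#' @param stations Character vector of nodal-station codes with explicit
#'   metastasis evidence (see [nodal_stations()]).
#' @param suggestive_only Only nonspecific descriptions (e.g. mild FDG
#'   uptake) are present.
#' @param modality Imaging modality backing the nodal assessment; when
#'   `neither`, downstream staging yields `Nx`.
#' @param explicitly_indeterminate Report states nodal status cannot be
#'   determined.
#' @return A `nodal_findings` object.
#' @export
nodal_findings <- function(stations = character(),
                           suggestive_only = FALSE,
                           modality = "neither",
                           explicitly_indeterminate = FALSE) {
  stations <- unique(as.character(stations))
  bad <- setdiff(stations, nodal_stations()$code)
  if (length(bad)) {
    abort_field("stations", paste("unknown station:", paste(bad, collapse = ", ")))
  }
  structure(
    list(stations = stations,
         suggestive_only = .check_flag(suggestive_only, "suggestive_only"),
         modality = .check_enum(modality, modality_levels(), "modality"),
         explicitly_indeterminate = .check_flag(explicitly_indeterminate,
                                                "explicitly_indeterminate")),
    class = "nodal_findings"
  )
}

#' Structured distant-metastasis findings
#'
#' @param pleural_or_pericardial_nodules Metastatic nodules of the pleura or
#'   pericardium.
#' @param malignant_effusion Malignant pleural or pericardial effusion.
#' @param contralateral_lung_nodule Metastatic nodule in the contralateral
#'   lung.
#' @param extrathoracic_lesions Data frame with columns `organ` and
#'   `evidence` (`confirmatory` or `nonspecific`), one row per distant
#'   lesion.
#' @param explicitly_indeterminate Report states metastasis status cannot be
#'   determined.
#' @param coverage_adequate Were the relevant body regions imaged?
#' @return A `metastasis_findings` object.
#' @export
metastasis_findings <- function(pleural_or_pericardial_nodules = FALSE,
                                malignant_effusion = FALSE,
                                contralateral_lung_nodule = FALSE,
                                extrathoracic_lesions = NULL,
                                explicitly_indeterminate = FALSE,
                                coverage_adequate = TRUE) {
  if (is.null(extrathoracic_lesions)) {
    extrathoracic_lesions <- data.frame(organ = character(),
                                        evidence = character(),
                                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(extrathoracic_lesions) ||
      !all(c("organ", "evidence") %in% names(extrathoracic_lesions))) {
    abort_field("extrathoracic_lesions",
                "must be a data frame with columns organ, evidence")
  }
  extrathoracic_lesions <- extrathoracic_lesions[, c("organ", "evidence")]
  if (!all(extrathoracic_lesions$evidence %in% evidence_levels())) {
    abort_field("evidence", "each lesion carries evidence confirmatory or nonspecific")
  }
  structure(
    list(intrathoracic = list(
           pleural_or_pericardial_nodules =
             .check_flag(pleural_or_pericardial_nodules,
                         "pleural_or_pericardial_nodules"),
           malignant_effusion = .check_flag(malignant_effusion,
                                            "malignant_effusion"),
           contralateral_lung_nodule = .check_flag(contralateral_lung_nodule,
                                                   "contralateral_lung_nodule")),
         extrathoracic_lesions = extrathoracic_lesions,
         explicitly_indeterminate = .check_flag(explicitly_indeterminate,
                                                "explicitly_indeterminate"),
         coverage_adequate = .check_flag(coverage_adequate, "coverage_adequate")),
    class = "metastasis_findings"
  )
}

#' A TNM stage triple with its rule-firing trace
#'
#' @param t,n,m Component labels from the closed vocabularies ([t_levels()],
#'   [n_levels()], [m_levels()]).
#' @param trace Character vector of rule identifiers fired while staging.
#' @return A `tnm_stage` object.
#' @export
#' @examples
#' tnm_stage("T2a", "N0", "M0")
tnm_stage <- function(t, n, m, trace = character()) {
  structure(
    list(t = .check_enum(t, t_levels(), "t"),
         n = .check_enum(n, n_levels(), "n"),
         m = .check_enum(m, m_levels(), "m"),
         trace = as.character(trace)),
    class = "tnm_stage"
  )
}

#' @export
format.tnm_stage <- function(x, ...) paste(x$t, x$n, x$m)

#' @export
print.tnm_stage <- function(x, ...) {
  cat("<tnm_stage>", format(x), "\n")
  if (length(x$trace)) cat("trace:", paste(x$trace, collapse = " -> "), "\n")
  invisible(x)
}

#' A clinical stage group
#'
#' @param group One of [stage_levels()].
#' @return A `clinical_stage` object.
#' @export
clinical_stage <- function(group) {
  structure(list(group = .check_enum(group, stage_levels(), "group")),
            class = "clinical_stage")
}

#' @export
format.clinical_stage <- function(x, ...) x$group

#' @export
print.clinical_stage <- function(x, ...) {
  cat("<clinical_stage>", x$group, "\n")
  invisible(x)
}

#' One patient case
#'
#' A case carries structured findings, an optional free-text report, and
#' optional gold TNM labels.  Findings may be `NULL` when only report text
#' is available; [stage_case()] then runs the lexicon extractor first.
#'
#' @param case_id Unique case identifier within a cohort.
#' @param tumor,nodal,metastasis Structured findings, or `NULL` when only
#'   `report_text` is supplied.
#' @param report_text Optional free-text radiology report.
#' @param gold Optional [tnm_stage()] with the annotated labels.
#' @return A `case_record` object.
#' @export
case_record <- function(case_id,
                        tumor = tumor_findings(),
                        nodal = nodal_findings(),
                        metastasis = metastasis_findings(),
                        report_text = NULL,
                        gold = NULL) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id)) {
    abort_field("case_id", "must be a non-empty string")
  }
  if (!is.null(tumor) && !inherits(tumor, "tumor_findings")) {
    abort_field("tumor", "must be tumor_findings() or NULL")
  }
  if (!is.null(nodal) && !inherits(nodal, "nodal_findings")) {
    abort_field("nodal", "must be nodal_findings() or NULL")
  }
  if (!is.null(metastasis) && !inherits(metastasis, "metastasis_findings")) {
    abort_field("metastasis", "must be metastasis_findings() or NULL")
  }
  if (!is.null(report_text) &&
      (!is.character(report_text) || length(report_text) != 1L)) {
    abort_field("report_text", "must be a single string or NULL")
  }
  if (is.null(tumor) && is.null(report_text)) {
    abort_field("tumor", "structured findings or report_text required")
  }
  if (!is.null(gold) && !inherits(gold, "tnm_stage")) {
    abort_field("gold", "must be a tnm_stage() or NULL")
  }
  structure(
    list(case_id = case_id, report_text = report_text, tumor = tumor,
         nodal = nodal, metastasis = metastasis, gold = gold),
    class = "case_record"
  )
}

#' Convert a length to canonical millimetres
#'
#' The engine works in millimetres internally; centimetres appear only at
#' I/O boundaries.
#'
#' @param value Positive length.
#' @param unit `"mm"` or `"cm"`.
#' @return Length in millimetres (no rounding).
#' @export
#' @examples
#' canonical_mm(3.9, "cm") # 39
canonical_mm <- function(value, unit = c("mm", "cm")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || any(is.na(value)) || any(value <= 0)) {
    stop("`value` must be positive", call. = FALSE)
  }
  if (unit == "cm") value * 10 else value * 1
}
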