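# JSON-lines cohort I/O and flat CSV label files.
#
# JSONL is the canonical case format (nested findings); CSV is supported
# only for flat label files (case_id, t, n, m).  Output is bit-stable for a
# fixed input: keys are sorted recursively and floats use a fixed
# 6-significant-digit representation.

.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, .sort_keys)
  } else if (is.list(x)) {
    lapply(x, .sort_keys)
  } else {
    x
  }
}

.case_to_list <- function(case) {
  out <- list(case_id = case$case_id)
  if (!is.null(case$report_text)) out$report_text <- case$report_text
  if (!is.null(case$tumor)) {
    tm <- unclass(case$tumor)
    tm$measurements <- lapply(tm$measurements, unclass)
    out$tumor <- tm
  }
  if (!is.null(case$nodal)) out$nodal <- unclass(case$nodal)
  if (!is.null(case$metastasis)) {
    mt <- unclass(case$metastasis)
    les <- mt$extrathoracic_lesions
    mt$extrathoracic_lesions <- lapply(seq_len(nrow(les)), function(i) {
      list(organ = les$organ[i], evidence = les$evidence[i])
    })
    out$metastasis <- mt
  }
  if (!is.null(case$gold)) {
    out$gold <- list(t = case$gold$t, n = case$gold$n, m = case$gold$m)
  }
  .sort_keys(out)
}

.list_to_case <- function(x) {
  tumor <- NULL
  if (!is.null(x$tumor)) {
    tm <- x$tumor
    tumor <- tumor_findings(
      measurements = lapply(tm$measurements, function(m) {
        measurement(m$diameter_mm, m$sequence_index,
                    isTRUE(m$post_current_treatment))
      }),
      lobe = tm$lobe %||% "unknown",
      trans_lobar = isTRUE(tm$trans_lobar),
      invasion_sites = unlist(tm$invasion_sites) %||% character(),
      nodule_same_lobe = isTRUE(tm$nodule_same_lobe),
      nodule_other_ipsilateral_lobe = isTRUE(tm$nodule_other_ipsilateral_lobe),
      atelectasis_to_hilum = isTRUE(tm$atelectasis_to_hilum),
      carcinoma_in_situ = isTRUE(tm$carcinoma_in_situ),
      minimally_invasive_adeno = isTRUE(tm$minimally_invasive_adeno),
      primary_tumor_mentioned = isTRUE(tm$primary_tumor_mentioned),
      evaluable = isTRUE(tm$evaluable)
    )
  }
  nodal <- NULL
  if (!is.null(x$nodal)) {
    nd <- x$nodal
    nodal <- nodal_findings(
      stations = unlist(nd$stations) %||% character(),
      suggestive_only = isTRUE(nd$suggestive_only),
      modality = nd$modality %||% "neither",
      explicitly_indeterminate = isTRUE(nd$explicitly_indeterminate)
    )
  }
  metastasis <- NULL
  if (!is.null(x$metastasis)) {
    mt <- x$metastasis
    les <- mt$extrathoracic_lesions
    les_df <- if (length(les)) {
      data.frame(organ = vapply(les, `[[`, character(1), "organ"),
                 evidence = vapply(les, `[[`, character(1), "evidence"),
                 stringsAsFactors = FALSE)
    } else NULL
    it <- mt$intrathoracic
    metastasis <- metastasis_findings(
      pleural_or_pericardial_nodules = isTRUE(it$pleural_or_pericardial_nodules),
      malignant_effusion = isTRUE(it$malignant_effusion),
      contralateral_lung_nodule = isTRUE(it$contralateral_lung_nodule),
      extrathoracic_lesions = les_df,
      explicitly_indeterminate = isTRUE(mt$explicitly_indeterminate),
      coverage_adequate = isTRUE(mt$coverage_adequate)
    )
  }
  gold <- if (!is.null(x$gold)) tnm_stage(x$gold$t, x$gold$n, x$gold$m)
  case_record(case_id = x$case_id, tumor = tumor, nodal = nodal,
              metastasis = metastasis, report_text = x$report_text,
              gold = gold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort of cases
#'
#' Reads a JSON-lines cohort file (one case object per line) or a flat CSV
#' label file (columns `case_id`, `t`, `n`, `m`; each row becomes a case
#' with default findings and gold labels).  Every record is validated
#' against the type invariants; malformed records are reported with their
#' line number and field name.
#'
#' @param path File to read.
#' @param format `"jsonl"` (canonical) or `"csv"` (flat label files only).
#' @return List of [case_record()] objects in input order.
#' @export
read_cases <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    lab <- read_labels(path)
    cases <- lapply(seq_len(nrow(lab)), function(i) {
      case_record(lab$case_id[i],
                  gold = tnm_stage(lab$t[i], lab$n[i], lab$m[i]))
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    cases <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      cases[[i]] <- tryCatch(
        .list_to_case(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)),
        error = function(e) {
          stop(sprintf("line %d: %s", i, conditionMessage(e)), call. = FALSE)
        }
      )
    }
  }
  ids <- vapply(cases, `[[`, character(1), "case_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate case_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  cases
}

#' Write a cohort of cases
#'
#' Inverse of [read_cases()].  Output is deterministic: the same cohort
#' written twice yields byte-identical files.
#'
#' @param cases List of [case_record()] objects.
#' @param path Output file.
#' @param format `"jsonl"` or `"csv"` (gold labels only).
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(is.list(cases))
  if (format == "csv") {
    lab <- data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      t = vapply(cases, function(x) x$gold$t, character(1)),
      n = vapply(cases, function(x) x$gold$n, character(1)),
      m = vapply(cases, function(x) x$gold$m, character(1)),
      stringsAsFactors = FALSE
    )
    return(write_labels(lab, path))
  }
  lines <- vapply(cases, function(case) {
    as.character(jsonlite::toJSON(.case_to_list(case), auto_unbox = TRUE,
                                  digits = I(6), null = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read or write a flat label file
#'
#' Label files are CSV with columns `case_id`, `t`, `n`, `m` and are used
#' for truth/prediction pairs in evaluation.
#'
#' @param path CSV file.
#' @return Data frame with columns `case_id`, `t`, `n`, `m`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  need <- c("case_id", "t", "n", "m")
  if (!all(need %in% names(lab))) {
    stop("label file must have columns case_id, t, n, m", call. = FALSE)
  }
  lab <- lab[, need]
  for (i in seq_len(nrow(lab))) {
    ok <- lab$t[i] %in% t_levels() && lab$n[i] %in% n_levels() &&
      lab$m[i] %in% m_levels()
    if (!ok) stop(sprintf("line %d: label outside vocabulary (%s %s %s)",
                          i + 1L, lab$t[i], lab$n[i], lab$m[i]), call. = FALSE)
  }
  dup <- unique(lab$case_id[duplicated(lab$case_id)])
  if (length(dup)) {
    stop("duplicate case_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  lab
}

#' @rdname read_labels
#' @param labels Data frame with columns `case_id`, `t`, `n`, `m`.
#' @export
write_labels <- function(labels, path) {
  need <- c("case_id", "t", "n", "m")
  stopifnot(all(need %in% names(labels)))
  utils::write.csv(labels[, need], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
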