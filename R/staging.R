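# The prioritized T/N/M staging rules and the AJCC 8th-edition stage
# grouping.  Every rule tested is appended to the trace; the entry for the
# rule that fired is prefixed "fired:".

#' Staging configuration
#'
#' @param m_strategy Metastasis interpretation strategy (`strict` default:
#'   only high-specificity wording counts as distant-lesion evidence).
#' @param t2_descriptor_mode How a T2 descriptor (atelectasis to hilum,
#'   T2-site invasion) interacts with the size ladder.  `size_precedence`
#'   (default) applies the descriptor only when the diameter is unknown or
#'   at most 50 mm, preserving size monotonicity; `literal_box3` applies it
#'   before the ladder regardless of size.
#' @param t2_subdivision How a descriptor-triggered T2 without a 30-50 mm
#'   size is labelled: `bare_T2` (default) emits `T2`; `size_subdivided`
#'   never emits the bare label and falls through to the ladder.
#' @param unknown_laterality Resolution for nodal mentions whose laterality
#'   cannot be determined (`assume_ipsilateral`, the conservative default).
#' @return A `staging_config` object.
#' @export
staging_config <- function(m_strategy = "strict",
                           t2_descriptor_mode = c("size_precedence", "literal_box3"),
                           t2_subdivision = c("bare_T2", "size_subdivided"),
                           unknown_laterality = c("assume_ipsilateral",
                                                  "assume_indeterminate")) {
  structure(
    list(m_strategy = interpretation_strategy(m_strategy),
         t2_descriptor_mode = match.arg(t2_descriptor_mode),
         t2_subdivision = match.arg(t2_subdivision),
         unknown_laterality = match.arg(unknown_laterality)),
    class = "staging_config"
  )
}

# size ladder in mm: (lo, hi] -> label
.t_ladder <- function(d) {
  if (d <= 10) c("T1a", "t_ladder_le10")
  else if (d <= 20) c("T1b", "t_ladder_10_20")
  else if (d <= 30) c("T1c", "t_ladder_20_30")
  else if (d <= 40) c("T2a", "t_ladder_30_40")
  else if (d <= 50) c("T2b", "t_ladder_40_50")
  else if (d <= 70) c("T3", "t_ladder_50_70")
  else c("T4", "t_ladder_gt70")
}

#' Stage the primary tumor (T)
#'
#' Evaluates, in priority order: T4 triggers (50-70 mm with trans-lobar
#' growth; invasion of a T4 site; nodules in a different ipsilateral lobe),
#' T3 triggers (T3-site invasion; isolated same-lobe nodule; under 50 mm
#' with trans-lobar growth), T2 descriptor triggers (atelectasis or
#' obstructive pneumonia to the hilum; T2-site invasion), then the size
#' ladder (<=10 T1a; >10-20 T1b; >20-30 T1c; >30-40 T2a; >40-50 T2b;
#' >50-70 T3; >70 T4), then explicit in-situ / minimally-invasive
#' diagnoses, T0 when no primary tumor is mentioned, and Tx when the tumor
#' cannot be evaluated.
#'
#' @param tumor A [tumor_findings()] object.
#' @param config A [staging_config()].
#' @return List with elements `label` and `trace`.
#' @export
#' @examples
#' stage_t(tumor_findings(list(measurement(39, 1)), lobe = "LLL"))$label # T2a
stage_t <- function(tumor, config = staging_config()) {
  stopifnot(inherits(tumor, "tumor_findings"))
  trace <- character()
  note <- function(id) trace <<- c(trace, id)
  fire <- function(label, id) list(label = label, trace = c(trace, paste0("fired:", id)))

  if (!tumor$evaluable) return(fire("Tx", "t_not_evaluable"))
  note("t_not_evaluable=no")

  d <- select_current_diameter(tumor$measurements)
  tiers <- invasion_tier(tumor$invasion_sites)

  # T4 triggers
  if (!is.null(d) && d > 50 && d <= 70 && tumor$trans_lobar) {
    return(fire("T4", "t4_size50_70_translobar"))
  }
  if (any(tiers == "T4_SITE")) return(fire("T4", "t4_site_invasion"))
  if (tumor$nodule_other_ipsilateral_lobe) return(fire("T4", "t4_nodule_other_ipsilateral_lobe"))
  note("t4_triggers=no")

  # T3 triggers
  if (any(tiers == "T3_SITE")) return(fire("T3", "t3_site_invasion"))
  if (tumor$nodule_same_lobe) return(fire("T3", "t3_nodule_same_lobe"))
  if (!is.null(d) && d < 50 && tumor$trans_lobar) {
    return(fire("T3", "t3_size_lt50_translobar"))
  }
  note("t3_triggers=no")

  # T2 descriptor triggers
  descriptor <- tumor$atelectasis_to_hilum || any(tiers == "T2_SITE")
  if (descriptor) {
    desc_id <- if (tumor$atelectasis_to_hilum) "t2_atelectasis_to_hilum" else "t2_site_invasion"
    applies <- switch(config$t2_descriptor_mode,
                      literal_box3 = TRUE,
                      size_precedence = is.null(d) || d <= 50)
    if (applies) {
      if (!is.null(d) && d > 30 && d <= 40) {
        return(fire("T2a", paste0(desc_id, "+t_ladder_30_40")))
      }
      if (!is.null(d) && d > 40 && d <= 50) {
        return(fire("T2b", paste0(desc_id, "+t_ladder_40_50")))
      }
      if (config$t2_subdivision == "bare_T2") return(fire("T2", desc_id))
      note(paste0(desc_id, "=defer_to_ladder"))
    } else {
      note(paste0(desc_id, "=superseded_by_size"))
    }
  } else {
    note("t2_descriptor=no")
  }

  # size ladder
  if (!is.null(d)) {
    lad <- .t_ladder(d)
    return(fire(lad[1], lad[2]))
  }
  note("t_ladder=no_diameter")

  if (tumor$carcinoma_in_situ) return(fire("Tis", "tis_explicit_in_situ"))
  if (tumor$minimally_invasive_adeno) return(fire("T1a", "t1a_minimally_invasive"))
  if (!tumor$primary_tumor_mentioned) return(fire("T0", "t0_no_primary_mentioned"))
  fire("Tx", "tx_no_diameter_no_descriptor")
}

#' Stage regional lymph nodes (N)
#'
#' Without a PET-CT or contrast-CT assessment (modality `neither`), or on
#' an explicitly indeterminate report, nodal status is `Nx`.  Otherwise
#' the highest tier among explicitly evidenced stations wins (N3 > N2 >
#' N1); suggestive-only descriptions contribute no station and yield `N0`.
#'
#' @param nodal A [nodal_findings()] object.
#' @param config A [staging_config()].
#' @return List with elements `label` and `trace`.
#' @export
stage_n <- function(nodal, config = staging_config()) {
  stopifnot(inherits(nodal, "nodal_findings"))
  trace <- character()
  fire <- function(label, id) list(label = label, trace = c(trace, paste0("fired:", id)))
  if (nodal$modality == "neither") return(fire("Nx", "nx_no_adequate_modality"))
  if (nodal$explicitly_indeterminate) return(fire("Nx", "nx_explicitly_indeterminate"))
  trace <- c(trace, "nx_triggers=no")
  tiers <- station_tier(nodal$stations)
  if (any(tiers == "N3_STATION")) return(fire("N3", "n3_station"))
  if (any(tiers == "N2_STATION")) return(fire("N2", "n2_station"))
  if (any(tiers == "N1_STATION")) return(fire("N1", "n1_station"))
  if (nodal$suggestive_only) trace <- c(trace, "n_suggestive_only_ignored")
  fire("N0", "n0_no_explicit_station")
}

#' Stage distant metastasis (M)
#'
#' Two or more confirmatory extrathoracic lesions give `M1c`, exactly one
#' gives `M1b`; otherwise any intrathoracic spread flag gives `M1a`;
#' otherwise an explicitly indeterminate report or inadequate imaging
#' coverage gives `Mx`, else `M0`.  Under the `strict` strategy
#' nonspecific lesions never count; under `lenient` they count as
#' confirmatory.
#'
#' @param met A [metastasis_findings()] object.
#' @param config A [staging_config()]; its `m_strategy` selects the
#'   interpretation strategy.
#' @return List with elements `label` and `trace`.
#' @export
stage_m <- function(met, config = staging_config()) {
  stopifnot(inherits(met, "metastasis_findings"))
  trace <- character()
  fire <- function(label, id) list(label = label, trace = c(trace, paste0("fired:", id)))
  les <- met$extrathoracic_lesions
  counted <- if (config$m_strategy == "lenient") {
    nrow(les)
  } else {
    sum(les$evidence == "confirmatory")
  }
  trace <- c(trace, sprintf("m_strategy=%s;extrathoracic_counted=%d",
                            config$m_strategy, counted))
  if (counted >= 2L) return(fire("M1c", "m1c_multiple_extrathoracic"))
  if (counted == 1L) return(fire("M1b", "m1b_single_extrathoracic"))
  it <- met$intrathoracic
  if (it$pleural_or_pericardial_nodules) return(fire("M1a", "m1a_pleural_pericardial_nodules"))
  if (it$malignant_effusion) return(fire("M1a", "m1a_malignant_effusion"))
  if (it$contralateral_lung_nodule) return(fire("M1a", "m1a_contralateral_lung_nodule"))
  trace <- c(trace, "m1_triggers=no")
  if (met$explicitly_indeterminate) return(fire("Mx", "mx_explicitly_indeterminate"))
  if (!met$coverage_adequate) return(fire("Mx", "mx_inadequate_coverage"))
  fire("M0", "m0_no_distant_metastasis")
}

# AJCC 8th-edition M0 grouping table, T major rows x N columns
.m0_group_table <- local({
  tab <- rbind(
    T1a = c(N0 = "IA1", N1 = "IIB", N2 = "IIIA", N3 = "IIIB"),
    T1b = c("IA2", "IIB", "IIIA", "IIIB"),
    T1c = c("IA3", "IIB", "IIIA", "IIIB"),
    T2a = c("IB",  "IIB", "IIIA", "IIIB"),
    T2b = c("IIA", "IIB", "IIIA", "IIIB"),
    T3  = c("IIB", "IIIA", "IIIB", "IIIC"),
    T4  = c("IIIA", "IIIA", "IIIB", "IIIC")
  )
  colnames(tab) <- c("N0", "N1", "N2", "N3")
  tab
})

#' Derive the clinical stage group
#'
#' Maps a TNM triple to its AJCC 8th-edition clinical stage group.  Any
#' `Tx`/`Nx`/`Mx` component yields `indeterminate`, except the occult
#' carcinoma triple Tx N0 M0; `M1a`/`M1b` yield IVA and `M1c` IVB; Tis N0
#' M0 is stage 0; all remaining M0 combinations follow the AJCC grouping
#' table.  A bare `T2` is grouped per `config$t2_subdivision` (default: as
#' T2a).  Combinations the manual leaves undefined (T0 or Tis with nodal
#' disease at M0, T0 N0 M0) are reported as `indeterminate`.
#'
#' @param stage A [tnm_stage()] (or list with `t`, `n`, `m`).
#' @param config A [staging_config()].
#' @return A [clinical_stage()] object.
#' @export
#' @examples
#' group_stage(tnm_stage("T2a", "N0", "M0"))$group # "IB"
group_stage <- function(stage, config = staging_config()) {
  t <- .check_enum(stage$t, t_levels(), "t")
  n <- .check_enum(stage$n, n_levels(), "n")
  m <- .check_enum(stage$m, m_levels(), "m")
  if (t == "Tx" && n == "N0" && m == "M0") return(clinical_stage("occult"))
  if (t == "Tx" || n == "Nx" || m == "Mx") return(clinical_stage("indeterminate"))
  if (m == "M1c") return(clinical_stage("IVB"))
  if (m %in% c("M1a", "M1b")) return(clinical_stage("IVA"))
  # M0 table
  if (t == "Tis") {
    return(clinical_stage(if (n == "N0") "0" else "indeterminate"))
  }
  if (t == "T0") return(clinical_stage("indeterminate"))
  if (t == "T2") t <- "T2a"  # bare-T2 grouping convention
  clinical_stage(.m0_group_table[t, n])
}

#' Stage one case end to end
#'
#' Runs [stage_t()], [stage_n()], [stage_m()] and [group_stage()] on a
#' case.  When the case carries only report text (or `use_report_text =
#' TRUE`), the lexicon extractors run first; extraction notes are
#' preserved in the trace.  Deterministic for fixed inputs and config.
#'
#' @param case A [case_record()].
#' @param config A [staging_config()].
#' @param lexicon Lexicon used when extraction is needed.
#' @param use_report_text Stage from `report_text` even when structured
#'   findings are present.
#' @return List with elements `tnm` ([tnm_stage()]) and `clinical`
#'   ([clinical_stage()]).
#' @export
stage_case <- function(case, config = staging_config(),
                       lexicon = default_lexicon("zh"),
                       use_report_text = FALSE) {
  stopifnot(inherits(case, "case_record"))
  need_extract <- use_report_text || is.null(case$tumor) ||
    is.null(case$nodal) || is.null(case$metastasis)
  trace0 <- character()
  if (need_extract) {
    if (is.null(case$report_text)) {
      stop("case ", case$case_id, ": no report_text to extract from",
           call. = FALSE)
    }
    modality <- if (!is.null(case$nodal)) case$nodal$modality else "neither"
    fx <- extract_findings(case$report_text, lexicon, modality = modality,
                           strategy = config$m_strategy)
    tumor <- fx$tumor; nodal <- fx$nodal; met <- fx$metastasis
    trace0 <- "extracted_from_report_text"
  } else {
    tumor <- case$tumor; nodal <- case$nodal; met <- case$metastasis
  }
  rt <- stage_t(tumor, config)
  rn <- stage_n(nodal, config)
  rm_ <- stage_m(met, config)
  tnm <- tnm_stage(rt$label, rn$label, rm_$label,
                   trace = c(trace0,
                             paste0("T|", rt$trace),
                             paste0("N|", rn$trace),
                             paste0("M|", rm_$trace)))
  list(tnm = tnm, clinical = group_stage(tnm, config))
}

#' Stage a cohort
#'
#' @param cases List of [case_record()] objects.
#' @inheritParams stage_case
#' @return Data frame with columns `case_id`, `t`, `n`, `m`,
#'   `clinical_stage` (and gold columns when present).
#' @export
stage_cohort <- function(cases, config = staging_config(),
                         lexicon = default_lexicon("zh"),
                         use_report_text = FALSE) {
  rows <- lapply(cases, function(case) {
    st <- stage_case(case, config, lexicon, use_report_text)
    data.frame(case_id = case$case_id, t = st$tnm$t, n = st$tnm$n,
               m = st$tnm$m, clinical_stage = st$clinical$group,
               gold_t = if (!is.null(case$gold)) case$gold$t else NA_character_,
               gold_n = if (!is.null(case$gold)) case$gold$n else NA_character_,
               gold_m = if (!is.null(case$gold)) case$gold$m else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
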