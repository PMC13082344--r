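# Deterministic lexicon-based extraction of structured findings from report
# text.  Matching is longest-match literal substring on normalized text; no
# stemming.  All evidence must be non-negated (clause-scoped cue window).

# non-negated matches of a lexicon category within one sentence
.hits <- function(sentence, lex, category, window = 6L) {
  m <- match_terms(sentence, lex, category, negation_window = window)
  m[!m$negated, , drop = FALSE]
}

# non-negated occurrences of arbitrary literal surfaces within one sentence
.plain_hits <- function(sentence, surfaces, lex, window = 6L) {
  m <- scan_terms(sentence, surfaces)
  if (!nrow(m)) return(m)
  neg <- vapply(seq_len(nrow(m)), function(i) {
    is_negated(sentence, m$start[i], lex, window)
  }, logical(1))
  m[!neg, , drop = FALSE]
}

# map gazetteer surfaces found in a sentence to their codes (longest match)
.gaz_codes <- function(sentence, gaz, lex, window = 6L) {
  m <- .plain_hits(sentence, gaz$surface, lex, window)
  unique(gaz$code[match(m$term, gaz$surface)])
}

# size phrases: "a x b unit" or "a unit", mm/cm dialects; returns mm values
.parse_sizes <- function(sentence) {
  rx <- "([0-9]+(?:\\.[0-9]+)?)(?:\\s*[x×*]\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*(mm|cm|毫米|厘米)"
  m <- gregexpr(rx, sentence, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(numeric())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  vapply(seq_along(starts), function(i) {
    frag <- substr(sentence, starts[i], starts[i] + lens[i] - 1L)
    nums <- as.numeric(regmatches(frag, gregexpr("[0-9]+(?:\\.[0-9]+)?", frag))[[1]])
    unit <- if (grepl("cm|厘米", frag, ignore.case = TRUE)) "cm" else "mm"
    canonical_mm(max(nums), unit)  # the larger axis is the diameter
  }, numeric(1))
}

.sentence_has <- function(sentence, patterns) {
  any(vapply(patterns, function(p) {
    grepl(p, sentence, perl = TRUE, ignore.case = TRUE)
  }, logical(1)))
}

# default negation window: 6 characters for CJK text, 30 for English (cues
# like "no evidence of" sit further from their target word)
.default_window <- function(lexicon, window) {
  if (!is.null(window)) return(as.integer(window))
  if (lexicon$language == "en") 30L else 6L
}

#' Extract primary-tumor findings from report text
#'
#' Parses tumor measurements (mm and cm dialects; for `a x b` sizes the
#' larger axis is the diameter), the lung lobe, trans-lobar growth,
#' confirmed invasion sites, cancer-nodule flags, atelectasis extending to
#' the hilum, and explicit in-situ / minimally-invasive diagnoses.  Sizes
#' are only taken from sentences that mention the tumor itself and carry no
#' nonspecific-nodule wording, so that e.g. the size of a "solid nodule"
#' never becomes the tumor diameter.
#'
#' @param text Report text (raw; normalized internally).
#' @param lexicon A [lexicon()]; its language selects the gazetteers.
#' @param negation_window Negation cue window passed to [match_terms()];
#'   defaults to 6 characters for Chinese and 30 for English text.
#' @return A [tumor_findings()] object.
#' @export
extract_tumor_findings <- function(text, lexicon = default_lexicon("zh"),
                                   negation_window = NULL) {
  negation_window <- .default_window(lexicon, negation_window)
  text <- normalize_text(text)
  if (!nzchar(text)) return(tumor_findings(evaluable = FALSE))
  lang <- lexicon$language
  sents <- split_sentences(text)
  sites <- site_gazetteer(lang)

  not_eval_rx <- if (lang == "zh") {
    c("原发[^。]*无法评估",
      "无法评估[^。]*原发")
  } else {
    c("primary (tumor|lesion) cannot be (evaluated|assessed)")
  }
  size_guard <- c(lexicon$term_lists$metastasis_nonspecific,
                  if (lang == "zh") c("实性结节", "淋巴结")
                  else c("solid nodule", "lymph node"),
                  lexicon$term_lists$malignant_nodule)
  trans_rx <- if (lang == "zh") "跨叶" else "trans-?lobar|across (the )?lobes"
  atel_rx <- if (lang == "zh") "肺不张|阻塞性肺炎" else "atelectasis|obstructive pneumonia"
  hilum_rx <- if (lang == "zh") "肺门" else "hil(um|ar)"
  cis_rx <- if (lang == "zh") "原位癌" else "carcinoma in situ"
  mia_rx <- if (lang == "zh") "微浸润腺癌" else "minimally invasive adenocarcinoma"
  same_lobe_rx <- if (lang == "zh") "同一肺叶|同叶" else "same lobe"
  diff_lobe_rx <- if (lang == "zh") "不同肺叶|不同叶" else "different (ipsilateral )?lobe"
  mets_like <- if (lang == "zh") "转移" else "metasta"

  measurements <- list()
  invasion <- character()
  nodule_same <- FALSE
  nodule_other <- FALSE
  atelectasis <- FALSE
  cis <- FALSE
  mia <- FALSE
  trans_lobar <- FALSE
  tumor_mentioned <- FALSE
  evaluable <- TRUE
  seq_idx <- 0L

  for (s in sents) {
    if (.sentence_has(s, not_eval_rx)) evaluable <- FALSE
    tw <- .plain_hits(s, tumor_words(lang), lexicon, negation_window)
    has_tumor_word <- nrow(tw) > 0L
    if (has_tumor_word) tumor_mentioned <- TRUE

    guard_hit <- nrow(scan_terms(s, size_guard)) > 0L
    if (has_tumor_word && !guard_hit) {
      for (d in .parse_sizes(s)) {
        seq_idx <- seq_idx + 1L
        post <- if (lang == "zh") grepl("治疗后|术后", s)
                else grepl("post-?treatment|after (the )?current treatment", s)
        measurements[[length(measurements) + 1L]] <-
          measurement(d, seq_idx, post_current_treatment = post)
      }
    }

    inv_hit <- nrow(.hits(s, lexicon, "invasion_confirmatory", negation_window)) > 0L
    if (inv_hit) {
      invasion <- c(invasion, .gaz_codes(s, sites, lexicon, negation_window))
    }
    # vertebral metastasis wording counts as explicit invasion evidence
    vert_surface <- if (lang == "zh") "椎体" else "vertebra"
    if (!inv_hit && nrow(.plain_hits(s, vert_surface, lexicon, negation_window)) &&
        .sentence_has(s, mets_like)) {
      invasion <- c(invasion, "vertebral_body")
    }

    mn <- .hits(s, lexicon, "malignant_nodule", negation_window)
    if (nrow(mn)) {
      if (.sentence_has(s, diff_lobe_rx)) nodule_other <- TRUE
      else if (.sentence_has(s, same_lobe_rx)) nodule_same <- TRUE
    }
    if (.sentence_has(s, atel_rx) && .sentence_has(s, hilum_rx)) {
      atel_start <- regexpr(atel_rx, s, perl = TRUE)
      if (!is_negated(s, as.integer(atel_start), lexicon, negation_window)) {
        atelectasis <- TRUE
      }
    }
    if (.sentence_has(s, cis_rx)) {
      p <- as.integer(regexpr(cis_rx, s, perl = TRUE))
      if (!is_negated(s, p, lexicon, negation_window)) cis <- TRUE
    }
    if (.sentence_has(s, mia_rx)) mia <- TRUE
    if (.sentence_has(s, trans_rx)) {
      p <- as.integer(regexpr(trans_rx, s, perl = TRUE))
      if (!is_negated(s, p, lexicon, negation_window)) trans_lobar <- TRUE
    }
  }

  lobe_hit <- scan_terms(text, lobe_gazetteer(lang)$surface)
  lobe <- if (nrow(lobe_hit)) {
    gaz <- lobe_gazetteer(lang)
    gaz$code[match(lobe_hit$term[1], gaz$surface)]
  } else "unknown"

  mentioned <- tumor_mentioned || length(measurements) > 0L ||
    length(invasion) > 0L || nodule_same || nodule_other || cis || mia ||
    trans_lobar
  tumor_findings(
    measurements = measurements, lobe = lobe, trans_lobar = trans_lobar,
    invasion_sites = unique(invasion), nodule_same_lobe = nodule_same,
    nodule_other_ipsilateral_lobe = nodule_other,
    atelectasis_to_hilum = atelectasis, carcinoma_in_situ = cis,
    minimally_invasive_adeno = mia, primary_tumor_mentioned = mentioned,
    evaluable = evaluable
  )
}

#' Extract nodal findings from report text
#'
#' A station is recorded only when its name co-occurs, in the same
#' sentence, with explicit nodal-metastasis wording; nonspecific wording
#' (e.g. mild FDG uptake) sets `suggestive_only` and contributes no
#' station.  Unresolved laterality for mediastinal/hilar mentions is
#' treated as ipsilateral (the conservative, lower N tier).
#'
#' @inheritParams extract_tumor_findings
#' @param modality Imaging modality backing the nodal assessment
#'   (`pet_ct`, `contrast_ct` or `neither`); with `neither` the findings
#'   force `Nx` downstream.
#' @return A [nodal_findings()] object.
#' @export
extract_nodal_findings <- function(text, lexicon = default_lexicon("zh"),
                                   modality = "neither",
                                   negation_window = NULL) {
  negation_window <- .default_window(lexicon, negation_window)
  text <- normalize_text(text)
  lang <- lexicon$language
  gaz <- station_gazetteer(lang)
  stations <- character()
  suggestive <- FALSE
  indet_rx <- if (lang == "zh") {
    "淋巴结[^。]*(无法|不能)(评估|确定)"
  } else {
    "(nodal status|lymph node[s]?) cannot be (evaluated|determined|assessed)"
  }
  indeterminate <- FALSE
  for (s in split_sentences(text)) {
    if (.sentence_has(s, indet_rx)) indeterminate <- TRUE
    conf <- .hits(s, lexicon, "nodal_confirmatory", negation_window)
    if (nrow(conf)) {
      stations <- c(stations, .gaz_codes(s, gaz, lexicon, negation_window))
    }
    if (nrow(.hits(s, lexicon, "nodal_nonspecific", negation_window))) {
      suggestive <- TRUE
    }
  }
  stations <- unique(stations)
  nodal_findings(
    stations = stations,
    suggestive_only = suggestive && !length(stations),
    modality = modality,
    explicitly_indeterminate = indeterminate
  )
}

#' Extract distant-metastasis findings from report text
#'
#' Under the `strict` strategy a distant lesion is recorded as
#' confirmatory only via high-specificity metastasis wording; under
#' `lenient`, nonspecific findings in distant organs are also upgraded to
#' confirmatory evidence.  Intrathoracic spread (pleural/pericardial
#' metastatic nodules, malignant effusions, contralateral lung nodules) is
#' detected separately.
#'
#' @inheritParams extract_tumor_findings
#' @param strategy [interpretation_strategy()]: `"strict"` or `"lenient"`.
#' @return A [metastasis_findings()] object.
#' @export
extract_metastasis_findings <- function(text, lexicon = default_lexicon("zh"),
                                        strategy = interpretation_strategy("strict"),
                                        negation_window = NULL) {
  negation_window <- .default_window(lexicon, negation_window)
  strategy <- interpretation_strategy(strategy)
  text <- normalize_text(text)
  if (!nzchar(text)) {
    return(metastasis_findings(coverage_adequate = FALSE))
  }
  lang <- lexicon$language
  organs <- organ_gazetteer(lang)
  effusion_rx <- if (lang == "zh") {
    "恶性(胸腔|心包)积液"
  } else "malignant (pleural|pericardial) effusion"
  pleura_rx <- if (lang == "zh") "胸膜|心包" else "pleura|pericardi"
  met_nodule_rx <- if (lang == "zh") "转移性?结节" else "metastatic nodule"
  contra_rx <- if (lang == "zh") "对侧肺" else "contralateral lung"
  nodule_rx <- if (lang == "zh") "结节" else "nodule"
  indet_rx <- if (lang == "zh") {
    "远处转移[^。]*(无法|不能)(评估|确定)"
  } else "distant metastas[ie]s cannot be (evaluated|determined|assessed)"

  eff <- FALSE; pnod <- FALSE; contra <- FALSE; indet <- FALSE
  lesions <- list()
  for (s in split_sentences(text)) {
    if (.sentence_has(s, indet_rx)) indet <- TRUE
    if (.sentence_has(s, effusion_rx)) {
      p <- as.integer(regexpr(effusion_rx, s, perl = TRUE))
      if (!is_negated(s, p, lexicon, negation_window)) eff <- TRUE
    }
    if (.sentence_has(s, pleura_rx) && .sentence_has(s, met_nodule_rx)) {
      p <- as.integer(regexpr(met_nodule_rx, s, perl = TRUE))
      if (!is_negated(s, p, lexicon, negation_window)) pnod <- TRUE
    }
    if (.sentence_has(s, contra_rx) && .sentence_has(s, nodule_rx)) {
      p <- as.integer(regexpr(nodule_rx, s, perl = TRUE))
      if (!is_negated(s, p, lexicon, negation_window)) contra <- TRUE
    }
    found <- .gaz_codes(s, organs, lexicon, negation_window)
    if (length(found)) {
      conf <- nrow(.hits(s, lexicon, "metastasis_confirmatory", negation_window)) > 0L
      nonspec <- nrow(.hits(s, lexicon, "metastasis_nonspecific", negation_window)) > 0L
      for (org in found) {
        if (conf) {
          lesions[[length(lesions) + 1L]] <- c(org, "confirmatory")
        } else if (nonspec) {
          ev <- if (strategy == "lenient") "confirmatory" else "nonspecific"
          lesions[[length(lesions) + 1L]] <- c(org, ev)
        }
      }
    }
  }
  les_df <- if (length(lesions)) {
    df <- data.frame(organ = vapply(lesions, `[`, character(1), 1),
                     evidence = vapply(lesions, `[`, character(1), 2),
                     stringsAsFactors = FALSE)
    # one lesion per organ; confirmatory evidence dominates
    df <- df[order(df$organ, df$evidence != "confirmatory"), ]
    df <- df[!duplicated(df$organ), , drop = FALSE]
    rownames(df) <- NULL
    df
  } else NULL
  metastasis_findings(
    pleural_or_pericardial_nodules = pnod,
    malignant_effusion = eff,
    contralateral_lung_nodule = contra,
    extrathoracic_lesions = les_df,
    explicitly_indeterminate = indet,
    coverage_adequate = TRUE
  )
}

#' Select the staging-relevant tumor diameter
#'
#' Returns the diameter of the highest-sequence measurement flagged as
#' obtained after the current treatment cycle; if none is flagged, the
#' highest-sequence measurement overall.  Empty input yields `NULL`.
#'
#' @param measurements List of [measurement()] objects.
#' @return Diameter in millimetres, or `NULL`.
#' @export
#' @examples
#' select_current_diameter(list(
#'   measurement(45, 1, FALSE), measurement(39, 2, TRUE)
#' )) # 39
select_current_diameter <- function(measurements) {
  if (!length(measurements)) return(NULL)
  idx <- vapply(measurements, `[[`, integer(1), "sequence_index")
  post <- vapply(measurements, `[[`, logical(1), "post_current_treatment")
  pool <- if (any(post)) which(post) else seq_along(measurements)
  pick <- pool[which.max(idx[pool])]
  measurements[[pick]]$diameter_mm
}

#' Extract all structured findings from one report
#'
#' Convenience wrapper running the three extractors on one text.
#'
#' @inheritParams extract_metastasis_findings
#' @inheritParams extract_nodal_findings
#' @return List with elements `tumor`, `nodal`, `metastasis`.
#' @export
extract_findings <- function(text, lexicon = default_lexicon("zh"),
                             modality = "neither",
                             strategy = interpretation_strategy("strict"),
                             negation_window = NULL) {
  list(
    tumor = extract_tumor_findings(text, lexicon, negation_window),
    nodal = extract_nodal_findings(text, lexicon, modality, negation_window),
    metastasis = extract_metastasis_findings(text, lexicon, strategy,
                                             negation_window)
  )
}
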