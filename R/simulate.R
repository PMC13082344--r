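# Label-first synthetic cohort generator.  A target (T, N, M) triple is
# drawn first; structured findings are then sampled from the preimage of
# that triple under the staging rules, so gold labels are exact by
# construction.  Pseudo-reports are rendered from the same findings, salted
# with nonspecific distractor wording that must not change strict-mode
# staging.

#' Simulation configuration
#'
#' Defaults emulate the study design this generator stands in for: test
#' cohorts of 100 cases, a relatively balanced coverage of all reachable
#' T/N/M subcategories, a CT-dominated modality mix with a PET-CT minority
#' and a small remainder without an adequate nodal modality, and report
#' text salted with nonspecific distractor terminology.
#'
#' @param n_cases Number of cases.
#' @param seed Integer seed fixing the entire cohort (structure and text).
#' @param label_distribution Data frame with columns `t`, `n`, `m`, `prob`;
#'   default uniform over the default-reachable triples (bare `T2` and the
#'   minimally-invasive T1a path excluded; they arise only from descriptor
#'   or explicit-diagnosis wording).
#' @param distractor_rate Probability that a rendered report receives
#'   nonspecific distractor sentences.
#' @param modality_mix Probabilities over `pet_ct`, `contrast_ct`,
#'   `neither` for nodal assessments (targets other than `Nx` draw from
#'   the first two, renormalized).
#' @param corruption_rate Per-component probability that a companion
#'   prediction label is resampled away from gold (for evaluation tests).
#' @param language `"zh"` or `"en"` report templates.
#' @param render_text Render a pseudo-report per case.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cases = 100L, seed = 1102L,
                       label_distribution = NULL,
                       distractor_rate = 0.3,
                       modality_mix = c(pet_ct = 0.13, contrast_ct = 0.85,
                                        neither = 0.02),
                       corruption_rate = 0,
                       language = c("zh", "en"),
                       render_text = TRUE) {
  language <- match.arg(language)
  if (!is.numeric(n_cases) || n_cases < 1) {
    abort_field("n_cases", "must be a positive integer")
  }
  if (is.null(label_distribution)) {
    label_distribution <- default_label_distribution()
  }
  stopifnot(all(c("t", "n", "m", "prob") %in% names(label_distribution)))
  if (abs(sum(label_distribution$prob) - 1) > 1e-9) {
    abort_field("label_distribution", "probabilities must sum to 1")
  }
  if (any(label_distribution$prob < 0)) {
    abort_field("label_distribution", "probabilities must be non-negative")
  }
  stopifnot(setequal(names(modality_mix), modality_levels()))
  if (abs(sum(modality_mix) - 1) > 1e-9) {
    abort_field("modality_mix", "probabilities must sum to 1")
  }
  if (distractor_rate < 0 || distractor_rate > 1) {
    abort_field("distractor_rate", "must be in [0, 1]")
  }
  if (corruption_rate < 0 || corruption_rate > 1) {
    abort_field("corruption_rate", "must be in [0, 1]")
  }
  structure(
    list(n_cases = as.integer(n_cases), seed = as.integer(seed),
         label_distribution = label_distribution,
         distractor_rate = distractor_rate,
         modality_mix = modality_mix[modality_levels()],
         corruption_rate = corruption_rate, language = language,
         render_text = isTRUE(render_text)),
    class = "sim_config"
  )
}

#' Default label distribution
#'
#' Uniform over the default-reachable (T, N, M) triples: all T labels
#' except bare `T2`, crossed with all N and M labels (250 triples).
#'
#' @return Data frame with columns `t`, `n`, `m`, `prob`.
#' @export
default_label_distribution <- function() {
  grid <- expand.grid(t = setdiff(t_levels(), "T2"), n = n_levels(),
                      m = m_levels(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$prob <- 1 / nrow(grid)
  grid
}

# largest-remainder (Hamilton) allocation of n among probabilities p
largest_remainder <- function(n, p) {
  exact <- n * p / sum(p)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.diameter_range <- c(T1a = "3:10", T1b = "11:20", T1c = "21:30",
                     T2a = "31:40", T2b = "41:50")

#' Sample one case from the preimage of a target triple
#'
#' Findings are drawn so that noiseless staging recovers the target
#' exactly: e.g. T2b yields a diameter in (40, 50] with no higher-tier
#' triggers; T4 picks one of its triggers (diameter over 70 mm, a T4-site
#' invasion, 50-70 mm with trans-lobar growth, or a nodule in a different
#' ipsilateral lobe) at random; N3 places at least one explicit N3
#' station; Mx marks metastasis status not assessable.  Uses the current
#' RNG state.
#'
#' @param target Named list or character vector with `t`, `n`, `m` labels.
#' @param config A [sim_config()].
#' @param case_id Case identifier.
#' @return A [case_record()] with gold labels (no report text; see
#'   [render_report()]).
#' @export
sample_case <- function(target, config = sim_config(), case_id = "case_0001") {
  t_lab <- .check_enum(target[["t"]], t_levels(), "t")
  n_lab <- .check_enum(target[["n"]], n_levels(), "n")
  m_lab <- .check_enum(target[["m"]], m_levels(), "m")

  pick <- function(x, k = 1L) x[sample.int(length(x), k)]
  rng_d <- function(spec) sample(eval(parse(text = spec)), 1L)

  # --- tumor ---------------------------------------------------------------
  lobe <- pick(setdiff(lobe_levels(), "unknown"))
  tumor <- switch(
    t_lab,
    T0 = tumor_findings(lobe = "unknown", primary_tumor_mentioned = FALSE),
    Tis = tumor_findings(lobe = lobe, carcinoma_in_situ = TRUE),
    Tx = tumor_findings(lobe = "unknown", evaluable = FALSE),
    T1a = , T1b = , T1c = , T2a = , T2b = tumor_findings(
      measurements = list(measurement(rng_d(.diameter_range[[t_lab]]), 1L)),
      lobe = lobe),
    T2 = tumor_findings(atelectasis_to_hilum = TRUE, lobe = lobe,
                        primary_tumor_mentioned = TRUE),
    T3 = {
      mode <- pick(c("ladder", "invasion", "nodule_same_lobe", "translobar"))
      switch(mode,
        ladder = tumor_findings(
          measurements = list(measurement(sample(51:70, 1L), 1L)), lobe = lobe),
        invasion = tumor_findings(
          measurements = list(measurement(sample(15:45, 1L), 1L)), lobe = lobe,
          invasion_sites = pick(.t3_sites)),
        nodule_same_lobe = tumor_findings(
          measurements = list(measurement(sample(15:45, 1L), 1L)), lobe = lobe,
          nodule_same_lobe = TRUE),
        translobar = tumor_findings(
          measurements = list(measurement(sample(15:45, 1L), 1L)), lobe = lobe,
          trans_lobar = TRUE))
    },
    T4 = {
      mode <- pick(c("ladder", "invasion", "translobar", "nodule_other_lobe"))
      switch(mode,
        ladder = tumor_findings(
          measurements = list(measurement(sample(71:95, 1L), 1L)), lobe = lobe),
        invasion = tumor_findings(
          measurements = list(measurement(sample(15:45, 1L), 1L)), lobe = lobe,
          invasion_sites = pick(.t4_sites)),
        translobar = tumor_findings(
          measurements = list(measurement(sample(51:70, 1L), 1L)), lobe = lobe,
          trans_lobar = TRUE),
        nodule_other_lobe = tumor_findings(
          measurements = list(measurement(sample(15:45, 1L), 1L)), lobe = lobe,
          nodule_other_ipsilateral_lobe = TRUE))
    }
  )

  # --- nodal ---------------------------------------------------------------
  if (n_lab == "Nx") {
    if (config$modality_mix[["neither"]] <= 0) {
      stop("target Nx unreachable: modality_mix gives no weight to 'neither'",
           call. = FALSE)
    }
    modality <- "neither"
  } else {
    w <- config$modality_mix[c("pet_ct", "contrast_ct")]
    if (sum(w) <= 0) {
      stop("target ", n_lab, " unreachable: modality_mix gives no weight ",
           "to pet_ct or contrast_ct", call. = FALSE)
    }
    modality <- sample(names(w), 1L, prob = w)
  }
  stations <- switch(n_lab,
    N0 = , Nx = character(),
    N1 = pick(.n1_stations, sample(1:2, 1L)),
    N2 = c(pick(.n2_stations), if (stats::runif(1) < 0.5) pick(.n1_stations)),
    N3 = c(pick(.n3_stations),
           if (stats::runif(1) < 0.5) pick(c(.n1_stations, .n2_stations))))
  nodal <- nodal_findings(stations = stations, modality = modality)

  # --- metastasis ----------------------------------------------------------
  organs <- unique(organ_gazetteer(config$language)$code)
  metastasis <- switch(m_lab,
    M0 = metastasis_findings(),
    Mx = metastasis_findings(explicitly_indeterminate = TRUE,
                             coverage_adequate = FALSE),
    M1a = {
      flag <- pick(c("effusion", "pleural_nodules", "contralateral_nodule"))
      metastasis_findings(
        malignant_effusion = flag == "effusion",
        pleural_or_pericardial_nodules = flag == "pleural_nodules",
        contralateral_lung_nodule = flag == "contralateral_nodule")
    },
    M1b = metastasis_findings(
      extrathoracic_lesions = data.frame(organ = pick(organs),
                                         evidence = "confirmatory")),
    M1c = metastasis_findings(
      extrathoracic_lesions = data.frame(organ = pick(organs, sample(2:3, 1L)),
                                         evidence = "confirmatory"))
  )

  case_record(case_id, tumor = tumor, nodal = nodal, metastasis = metastasis,
              gold = tnm_stage(t_lab, n_lab, m_lab))
}

# renderer surface tables: one canonical surface per code
.render_site <- function(language) {
  if (language == "zh") {
    c(diaphragm = "膈肌", mediastinum = "纵隔", heart = "心脏",
      major_vessel = "大血管", trachea = "气管",
      recurrent_laryngeal_nerve = "喉返神经", esophagus = "食管",
      vertebral_body = "椎体", carina = "隆突",
      parietal_pleura = "壁层胸膜", chest_wall = "胸壁",
      phrenic_nerve = "膈神经", pericardium = "心包",
      distal_vessel_main_stem = "远端血管主干",
      main_bronchus = "主支气管", visceral_pleura = "脏层胸膜")
  } else {
    c(diaphragm = "diaphragm", mediastinum = "mediastinum", heart = "heart",
      major_vessel = "major vessel", trachea = "trachea",
      recurrent_laryngeal_nerve = "recurrent laryngeal nerve",
      esophagus = "esophagus", vertebral_body = "vertebral body",
      carina = "carina", parietal_pleura = "parietal pleura",
      chest_wall = "chest wall", phrenic_nerve = "phrenic nerve",
      pericardium = "pericardium",
      distal_vessel_main_stem = "distal vessel main stem",
      main_bronchus = "main bronchus", visceral_pleura = "visceral pleura")
  }
}

.render_station <- function(language) {
  if (language == "zh") {
    c(ipsilateral_peribronchial = "同侧支气管旁",
      ipsilateral_hilar = "同侧肺门",
      ipsilateral_intrapulmonary = "同侧肺内",
      ipsilateral_mediastinal = "同侧纵隔", subcarinal = "隆突下",
      contralateral_mediastinal = "对侧纵隔",
      contralateral_hilar = "对侧肺门",
      scalene_either_side = "斜角肌",
      supraclavicular_either_side = "锁骨上")
  } else {
    c(ipsilateral_peribronchial = "peribronchial",
      ipsilateral_hilar = "ipsilateral hilar",
      ipsilateral_intrapulmonary = "intrapulmonary",
      ipsilateral_mediastinal = "ipsilateral mediastinal",
      subcarinal = "subcarinal",
      contralateral_mediastinal = "contralateral mediastinal",
      contralateral_hilar = "contralateral hilar",
      scalene_either_side = "scalene",
      supraclavicular_either_side = "supraclavicular")
  }
}

.render_organ <- function(language) {
  if (language == "zh") {
    c(liver = "肝脏", adrenal = "肾上腺", brain = "脑", bone = "骨",
      kidney = "肾", spleen = "脾", pancreas = "胰腺")
  } else {
    c(liver = "liver", adrenal = "adrenal", brain = "brain", bone = "bone",
      kidney = "kidney", spleen = "spleen", pancreas = "pancreas")
  }
}

.render_lobe <- function(language) {
  if (language == "zh") {
    c(RUL = "右肺上叶", RML = "右肺中叶", RLL = "右肺下叶",
      LUL = "左肺上叶", LLL = "左肺下叶", unknown = "两肺")
  } else {
    c(RUL = "right upper lobe", RML = "right middle lobe",
      RLL = "right lower lobe", LUL = "left upper lobe",
      LLL = "left lower lobe", unknown = "both lungs")
  }
}

.distractor_pool <- function(language) {
  if (language == "zh") {
    c("肝内见小结节。", "双肾见低密度结节影。", "肝脏小囊肿。",
      "颅内见软化灶。", "骨见条状强化影。", "纵隔见小淋巴结。",
      "脾见致密影。")
  } else {
    c("A small nodule in the liver.", "A low-density nodule in the kidney.",
      "A hepatic cyst.", "A softening focus in the brain.",
      "Linear enhancement in the bone.",
      "A small lymph node in the mediastinum.",
      "A dense shadow in the spleen.")
  }
}

#' Render a pseudo-report from structured findings
#'
#' Fills language-specific sentence templates with confirmatory phrases
#' realizing each finding; with probability `config$distractor_rate` the
#' report is salted with nonspecific distractor sentences (small nodules,
#' low-density shadows, cysts) in distant organs that must not change
#' strict-mode staging.  Deterministic given the RNG state.
#'
#' @param case A [case_record()] with structured findings.
#' @param config A [sim_config()] (language and distractor rate).
#' @return Report text (single string).
#' @export
render_report <- function(case, config = sim_config()) {
  lang <- config$language
  zh <- lang == "zh"
  lobe_s <- .render_lobe(lang)[[case$tumor$lobe]]
  sents <- character()
  add <- function(s) sents <<- c(sents, s)

  add(switch(case$nodal$modality,
             pet_ct = if (zh) "PET-CT检查所见。" else "PET-CT findings.",
             contrast_ct = if (zh) "胸部增强CT检查所见。"
                           else "Contrast-enhanced chest CT findings.",
             neither = if (zh) "报告所见。" else "Report findings."))

  tm <- case$tumor
  if (!tm$evaluable) {
    add(if (zh) "原发灶显示不清，无法评估。"
        else "The primary lesion cannot be assessed.")
  } else if (!tm$primary_tumor_mentioned) {
    add(if (zh) "两肺未见原发肿瘤征象。"
        else "No evidence of a primary tumor.")
  } else {
    d <- select_current_diameter(tm$measurements)
    if (!is.null(d)) {
      add(if (zh) sprintf("%s见恶性肿块，最大径约%gmm。", lobe_s, d)
          else sprintf("A malignant mass in the %s, maximum diameter about %g mm.",
                       lobe_s, d))
    } else if (tm$carcinoma_in_situ || tm$minimally_invasive_adeno ||
               tm$atelectasis_to_hilum) {
      add(if (zh) sprintf("%s见占位。", lobe_s)
          else sprintf("A mass lesion in the %s.", lobe_s))
    }
    if (tm$carcinoma_in_situ) {
      add(if (zh) "病理提示原位癌。" else "Pathology indicates carcinoma in situ.")
    }
    if (tm$minimally_invasive_adeno) {
      add(if (zh) "病理提示微浸润腺癌。"
          else "Pathology indicates minimally invasive adenocarcinoma.")
    }
    if (tm$trans_lobar) {
      add(if (zh) "病灶呈跨叶生长。" else "The lesion shows trans-lobar growth.")
    }
    for (site in tm$invasion_sites) {
      verb <- if (zh) sample(c("侵犯", "侵及", "累及"), 1L)
              else sample(c("invades", "invading"), 1L)
      add(if (zh) sprintf("肿块%s%s。", verb, .render_site(lang)[[site]])
          else sprintf("The mass %s the %s.", verb, .render_site(lang)[[site]]))
    }
    if (tm$nodule_same_lobe) {
      add(if (zh) "同一肺叶内见孤立癌结节。"
          else "A solitary cancer nodule in the same lobe.")
    }
    if (tm$nodule_other_ipsilateral_lobe) {
      add(if (zh) "同侧不同肺叶见癌结节。"
          else "A cancer nodule in a different ipsilateral lobe.")
    }
    if (tm$atelectasis_to_hilum) {
      add(if (zh) "伴阻塞性肺炎，肺不张延伸至肺门。"
          else "Atelectasis and obstructive pneumonia extending to the hilum.")
    }
  }

  nd <- case$nodal
  for (st in nd$stations) {
    conf <- if (zh) sample(c("淋巴结转移", "淋巴结肿大"), 1L)
            else sample(c("lymph node metastasis", "enlarged lymph node"), 1L)
    add(if (zh) sprintf("见%s%s。", .render_station(lang)[[st]], conf)
        else sprintf("There is %s %s.", .render_station(lang)[[st]], conf))
  }

  mt <- case$metastasis
  if (mt$intrathoracic$malignant_effusion) {
    add(if (zh) "可见恶性胸腔积液。" else "Malignant pleural effusion is present.")
  }
  if (mt$intrathoracic$pleural_or_pericardial_nodules) {
    add(if (zh) "胸膜见多发转移性结节。"
        else "Multiple metastatic nodules along the pleura.")
  }
  if (mt$intrathoracic$contralateral_lung_nodule) {
    add(if (zh) "对侧肺见转移结节。"
        else "A metastatic nodule in the contralateral lung.")
  }
  les <- mt$extrathoracic_lesions
  if (nrow(les)) {
    for (i in seq_len(nrow(les))) {
      org <- .render_organ(lang)[[les$organ[i]]]
      if (les$evidence[i] == "confirmatory") {
        phr <- if (zh) sample(c("考虑转移", "疑似转移", "见转移性病变"), 1L)
               else "shows metastatic involvement"
        add(if (zh) sprintf("%s%s。", org, phr)
            else sprintf("The %s %s.", org, phr))
      } else {
        add(if (zh) sprintf("%s见小结节。", org)
            else sprintf("A small nodule in the %s.", org))
      }
    }
  }
  if (mt$explicitly_indeterminate || !mt$coverage_adequate) {
    add(if (zh) "远处转移情况无法评估。"
        else "Distant metastasis cannot be evaluated.")
  }

  if (stats::runif(1) < config$distractor_rate) {
    pool <- .distractor_pool(lang)
    add(pool[sample.int(length(pool), sample(1:2, 1L))])
  }
  paste(sents, collapse = if (zh) "" else " ")
}

#' Generate a synthetic cohort
#'
#' Draws `n_cases` gold label triples from the label distribution by
#' stratified allocation (largest-remainder rounding), shuffles them with
#' the seeded generator, samples findings from each triple's preimage, and
#' optionally renders pseudo-reports and a corrupted companion prediction
#' set.  The same configuration always yields a byte-identical cohort.
#'
#' @param config A [sim_config()].
#' @return List with `cases` (list of [case_record()]), `manifest`
#'   (config echo plus realized per-category counts), and `predictions`
#'   (label data frame, only when `corruption_rate > 0`).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_cases = 10, seed = 1))
#' cohort$manifest$counts$t
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dist <- config$label_distribution
  counts <- largest_remainder(config$n_cases, dist$prob)
  idx <- rep(seq_len(nrow(dist)), counts)
  idx <- idx[sample.int(length(idx))]
  targets <- dist[idx, c("t", "n", "m")]

  cases <- lapply(seq_len(nrow(targets)), function(i) {
    sample_case(as.list(targets[i, ]), config,
                case_id = sprintf("case_%04d", i))
  })
  # text is rendered in a second pass so the structured findings stream is
  # identical across distractor rates at the same seed
  if (config$render_text) {
    for (i in seq_along(cases)) {
      cases[[i]]$report_text <- render_report(cases[[i]], config)
    }
  }
  predictions <- NULL
  if (config$corruption_rate > 0) {
    vocab <- list(t = t_levels(), n = n_levels(), m = m_levels())
    predictions <- data.frame(
      case_id = vapply(cases, `[[`, character(1), "case_id"),
      t = NA_character_, n = NA_character_, m = NA_character_,
      stringsAsFactors = FALSE
    )
    for (i in seq_along(cases)) {
      for (comp in c("t", "n", "m")) {
        gold <- cases[[i]]$gold[[comp]]
        predictions[[comp]][i] <- if (stats::runif(1) < config$corruption_rate) {
          sample(setdiff(vocab[[comp]], gold), 1L)
        } else gold
      }
    }
  }
  gold_t <- vapply(cases, function(x) x$gold$t, character(1))
  gold_n <- vapply(cases, function(x) x$gold$n, character(1))
  gold_m <- vapply(cases, function(x) x$gold$m, character(1))
  manifest <- list(
    config = list(n_cases = config$n_cases, seed = config$seed,
                  distractor_rate = config$distractor_rate,
                  modality_mix = as.list(config$modality_mix),
                  corruption_rate = config$corruption_rate,
                  language = config$language,
                  render_text = config$render_text),
    counts = list(t = as.list(table(factor(gold_t, t_levels()))),
                  n = as.list(table(factor(gold_n, n_levels()))),
                  m = as.list(table(factor(gold_m, m_levels())))),
    generator_version = as.character(utils::packageVersion("tnmstager"))
  )
  list(cases = cases, manifest = manifest, predictions = predictions)
}
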