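lex_zh <- default_lexicon("zh")
lex_en <- default_lexicon("en")

test_that("shipped lexicons are complete and category-disjoint", {
  for (lx in list(lex_zh, lex_en)) {
    expect_setequal(names(lx$term_lists), lexicon_categories())
    expect_true(all(lengths(lx$term_lists) > 0))
  }
  expect_error(
    lexicon("dup", "zh", modifyList(lex_zh$term_lists,
                                    list(nodal_nonspecific = c("小结节")))),
    "two categories"
  )
})

test_that("normalize_text collapses CJK noise and is idempotent", {
  expect_identical(normalize_text("左 下 叶"), "左下叶")
  expect_identical(normalize_text("左肺下叶恶性肿块"), "左肺下叶恶性肿块")
  clean <- c("左肺下叶见恶性肿块，最大径约39mm。", "对侧纵隔淋巴结转移。",
             "肝脏考虑转移，骨见转移性病变。")
  set.seed(7)
  for (i in 1:40) {
    noised <- inject_noise(sample(clean, 1))
    once <- normalize_text(noised)
    expect_identical(normalize_text(once), once)
    # no residual spaces between CJK characters
    expect_false(grepl("(?<=\\p{Han}) (?=\\p{Han})", once, perl = TRUE))
  }
  # noise does not change extraction results
  set.seed(8)
  for (i in 1:10) {
    raw <- clean[3]
    mt_clean <- extract_metastasis_findings(raw, lex_zh)
    mt_noisy <- extract_metastasis_findings(inject_noise(raw), lex_zh)
    expect_identical(mt_noisy$extrathoracic_lesions,
                     mt_clean$extrathoracic_lesions)
  }
})

test_that("match_terms finds longest non-overlapping matches with negation", {
  m <- match_terms("考虑转移", lex_zh, "metastasis_confirmatory")
  expect_identical(m$term, "考虑转移")
  expect_false(m$negated)

  m <- match_terms("未见转移性病变", lex_zh, "metastasis_confirmatory")
  expect_identical(m$term, "转移性")
  expect_true(m$negated)

  expect_identical(nrow(match_terms("", lex_zh, "metastasis_confirmatory")), 0L)
  expect_error(match_terms("x", lex_zh, "nonexistent"), "unknown category")
})

test_that("match positions are strictly increasing and non-overlapping", {
  set.seed(11)
  terms <- lex_zh$term_lists$metastasis_nonspecific
  for (i in 1:50) {
    txt <- paste(sample(c(terms, "肝脏", "，", "可见"), 12, replace = TRUE),
                 collapse = "")
    m <- match_terms(txt, lex_zh, "metastasis_nonspecific")
    if (nrow(m) > 1) {
      expect_true(all(diff(m$start) > 0))
      expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    }
  }
})

test_that("tumor extraction parses sizes, lobe, and invasion wording", {
  tf <- extract_tumor_findings("左肺下叶见恶性肿块，大小约3.9cm。", lex_zh)
  expect_length(tf$measurements, 1)
  expect_equal(tf$measurements[[1]]$diameter_mm, 39)
  expect_identical(tf$lobe, "LLL")
  expect_length(tf$invasion_sites, 0)
  expect_true(tf$primary_tumor_mentioned)

  tf <- extract_tumor_findings("右肺上叶肿块，椎体侵犯。", lex_zh)
  expect_identical(tf$invasion_sites, "vertebral_body")

  # vertebral metastasis wording also counts as invasion evidence
  tf <- extract_tumor_findings("椎体转移可能。", lex_zh)
  expect_identical(tf$invasion_sites, "vertebral_body")

  # "a x b" sizes: larger axis is the diameter
  tf <- extract_tumor_findings("左肺上叶肿块，大小约2.1×3.4cm。", lex_zh)
  expect_equal(tf$measurements[[1]]$diameter_mm, 34)

  # nonneoplastic nodule sizes are never the tumor diameter
  tf <- extract_tumor_findings("右肺中叶实性结节，大小约12mm。", lex_zh)
  expect_length(tf$measurements, 0)

  # negated tumor mention -> no primary
  tf <- extract_tumor_findings("两肺未见原发肿瘤征象。", lex_zh)
  expect_false(tf$primary_tumor_mentioned)
  expect_true(tf$evaluable)
})

test_that("nodal extraction needs confirmatory wording for a station", {
  nd <- extract_nodal_findings("见同侧纵隔淋巴结转移。", lex_zh, "pet_ct")
  expect_identical(nd$stations, "ipsilateral_mediastinal")
  expect_false(nd$suggestive_only)

  nd <- extract_nodal_findings("纵隔淋巴结FDG轻度摄取。", lex_zh, "pet_ct")
  expect_length(nd$stations, 0)
  expect_true(nd$suggestive_only)

  # unresolved laterality is treated as ipsilateral (lower tier)
  nd <- extract_nodal_findings("纵隔淋巴结肿大。", lex_zh, "contrast_ct")
  expect_identical(nd$stations, "ipsilateral_mediastinal")

  nd <- extract_nodal_findings("见对侧纵隔淋巴结转移。", lex_zh, "neither")
  expect_identical(nd$modality, "neither")
  expect_identical(stage_n(nd)$label, "Nx")
})

test_that("metastasis extraction applies strict vs lenient strategies", {
  strict <- extract_metastasis_findings("肝内见小结节。", lex_zh, "strict")
  expect_identical(strict$extrathoracic_lesions$organ, "liver")
  expect_identical(strict$extrathoracic_lesions$evidence, "nonspecific")

  lenient <- extract_metastasis_findings("肝内见小结节。", lex_zh, "lenient")
  expect_identical(lenient$extrathoracic_lesions$evidence, "confirmatory")

  conf <- extract_metastasis_findings("左肾上腺考虑转移。", lex_zh, "strict")
  expect_identical(conf$extrathoracic_lesions$organ, "adrenal")
  expect_identical(conf$extrathoracic_lesions$evidence, "confirmatory")

  neg <- extract_metastasis_findings("肝脏未见转移性病变。", lex_zh, "strict")
  expect_identical(nrow(neg$extrathoracic_lesions), 0L)

  empty <- extract_metastasis_findings("", lex_zh, "strict")
  expect_identical(nrow(empty$extrathoracic_lesions), 0L)
  expect_false(empty$coverage_adequate)

  eff <- extract_metastasis_findings("可见恶性胸腔积液。", lex_zh, "strict")
  expect_true(eff$intrathoracic$malignant_effusion)
})

test_that("strict lesions are a subset of lenient lesions on any report", {
  cfg <- sim_config(n_cases = 40, seed = 23, distractor_rate = 1)
  cohort <- generate_cohort(cfg)
  for (case in cohort$cases) {
    s <- extract_metastasis_findings(case$report_text, lex_zh, "strict")
    l <- extract_metastasis_findings(case$report_text, lex_zh, "lenient")
    s_conf <- s$extrathoracic_lesions$organ[
      s$extrathoracic_lesions$evidence == "confirmatory"]
    l_conf <- l$extrathoracic_lesions$organ[
      l$extrathoracic_lesions$evidence == "confirmatory"]
    expect_true(all(s_conf %in% l_conf))
  }
})

test_that("nonspecific terms never change the strict confirmatory set", {
  cfg <- sim_config(n_cases = 30, seed = 29, distractor_rate = 0)
  cohort <- generate_cohort(cfg)
  salt <- paste0("肝内见小结节。双肾见低密度结节影。脾见致密影。",
                 "颅内见软化灶。骨见条状强化影。")
  for (case in cohort$cases) {
    base <- extract_metastasis_findings(case$report_text, lex_zh, "strict")
    salted <- extract_metastasis_findings(paste0(case$report_text, salt),
                                          lex_zh, "strict")
    base_conf <- sort(base$extrathoracic_lesions$organ[
      base$extrathoracic_lesions$evidence == "confirmatory"])
    salt_conf <- sort(salted$extrathoracic_lesions$organ[
      salted$extrathoracic_lesions$evidence == "confirmatory"])
    expect_identical(salt_conf, base_conf)
  }
})

test_that("select_current_diameter prefers post-treatment measurements", {
  expect_equal(select_current_diameter(list(
    measurement(45, 1, FALSE), measurement(39, 2, TRUE))), 39)
  # post-treatment flag wins even when a later pre-treatment value exists
  expect_equal(select_current_diameter(list(
    measurement(39, 1, TRUE), measurement(45, 2, FALSE))), 39)
  expect_equal(select_current_diameter(list(measurement(12, 1))), 12)
  expect_null(select_current_diameter(list()))
})

test_that("the english lexicon mirrors the extraction behaviour", {
  tf <- extract_tumor_findings(
    "A malignant mass in the left lower lobe, maximum diameter about 39 mm.",
    lex_en)
  expect_equal(tf$measurements[[1]]$diameter_mm, 39)
  expect_identical(tf$lobe, "LLL")

  tf <- extract_tumor_findings("No evidence of a primary tumor.", lex_en)
  expect_false(tf$primary_tumor_mentioned)

  mt <- extract_metastasis_findings("A small nodule in the liver.", lex_en)
  expect_identical(mt$extrathoracic_lesions$evidence, "nonspecific")
})
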