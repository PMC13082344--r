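cfg <- staging_config()

t_of <- function(...) stage_t(tumor_findings(...), cfg)$label
meas <- function(d) list(measurement(d, 1L))

test_that("stage_t applies the prioritized rules and the size ladder", {
  expect_identical(t_of(meas(39), lobe = "LLL"), "T2a")
  expect_identical(t_of(meas(10)), "T1a")
  expect_identical(t_of(meas(10.5)), "T1b")
  expect_identical(t_of(meas(20)), "T1b")
  expect_identical(t_of(meas(30)), "T1c")
  expect_identical(t_of(meas(40)), "T2a")
  expect_identical(t_of(meas(50)), "T2b")
  expect_identical(t_of(meas(70)), "T3")
  expect_identical(t_of(meas(71)), "T4")
  expect_identical(t_of(meas(30), invasion_sites = "vertebral_body"), "T4")
  expect_identical(t_of(meas(30), invasion_sites = "chest_wall"), "T3")
  expect_identical(t_of(meas(45), trans_lobar = TRUE), "T3")
  expect_identical(t_of(meas(60), trans_lobar = TRUE), "T4")
  expect_identical(t_of(meas(25), nodule_same_lobe = TRUE), "T3")
  expect_identical(t_of(meas(25), nodule_other_ipsilateral_lobe = TRUE), "T4")
  expect_identical(t_of(primary_tumor_mentioned = FALSE), "T0")
  expect_identical(t_of(carcinoma_in_situ = TRUE), "Tis")
  expect_identical(t_of(minimally_invasive_adeno = TRUE), "T1a")
  expect_identical(t_of(evaluable = FALSE), "Tx")
  expect_identical(t_of(primary_tumor_mentioned = TRUE), "Tx")
})

test_that("T2 descriptors subdivide by size and respect the mode", {
  # descriptor with an in-range size takes the size subdivision
  expect_identical(t_of(meas(35), atelectasis_to_hilum = TRUE), "T2a")
  expect_identical(t_of(meas(45), atelectasis_to_hilum = TRUE), "T2b")
  expect_identical(t_of(meas(25), invasion_sites = "visceral_pleura"), "T2")
  expect_identical(t_of(atelectasis_to_hilum = TRUE,
                        primary_tumor_mentioned = TRUE), "T2")
  # size precedence: a 60 mm tumor with atelectasis is T3, not T2
  expect_identical(t_of(meas(60), atelectasis_to_hilum = TRUE), "T3")
  lit <- staging_config(t2_descriptor_mode = "literal_box3")
  expect_identical(
    stage_t(tumor_findings(meas(60), atelectasis_to_hilum = TRUE), lit)$label,
    "T2")
})

test_that("the T label is monotone in diameter absent other triggers", {
  order_t <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4")
  labels <- vapply(seq(1, 100, by = 0.5),
                   function(d) t_of(meas(d)), character(1))
  ranks <- match(labels, order_t)
  expect_true(all(diff(ranks) >= 0))
})

test_that("stage_n takes the maximum station tier and handles Nx", {
  n_of <- function(...) stage_n(nodal_findings(...), cfg)$label
  expect_identical(n_of(stations = "subcarinal", modality = "pet_ct"), "N2")
  expect_identical(n_of(stations = c("ipsilateral_hilar", "contralateral_mediastinal"),
                        modality = "pet_ct"), "N3")
  expect_identical(n_of(stations = "ipsilateral_intrapulmonary",
                        modality = "contrast_ct"), "N1")
  expect_identical(n_of(suggestive_only = TRUE, modality = "pet_ct"), "N0")
  expect_identical(n_of(modality = "neither"), "Nx")
  expect_identical(n_of(modality = "pet_ct", explicitly_indeterminate = TRUE), "Nx")
})

test_that("stage_m counts confirmatory lesions and applies the strategy", {
  les <- function(...) {
    orgs <- c(...)
    data.frame(organ = names(orgs), evidence = unname(orgs),
               stringsAsFactors = FALSE)
  }
  m_of <- function(f, strategy = "strict") {
    stage_m(f, staging_config(m_strategy = strategy))$label
  }
  expect_identical(m_of(metastasis_findings(malignant_effusion = TRUE)), "M1a")
  expect_identical(m_of(metastasis_findings(
    extrathoracic_lesions = les(adrenal = "confirmatory"))), "M1b")
  expect_identical(m_of(metastasis_findings(
    extrathoracic_lesions = les(liver = "confirmatory", bone = "confirmatory"))),
    "M1c")
  # nonspecific lesions count only under lenient
  nsp <- metastasis_findings(extrathoracic_lesions = les(liver = "nonspecific"))
  expect_identical(m_of(nsp, "strict"), "M0")
  expect_identical(m_of(nsp, "lenient"), "M1b")
  expect_identical(m_of(metastasis_findings(explicitly_indeterminate = TRUE)), "Mx")
  expect_identical(m_of(metastasis_findings(coverage_adequate = FALSE)), "Mx")
  expect_identical(m_of(metastasis_findings()), "M0")
})

test_that("lenient M staging never downstages relative to strict", {
  set.seed(31)
  organs <- unique(organ_gazetteer("zh")$code)
  for (i in 1:300) {
    k <- sample(0:3, 1)
    les <- if (k > 0) {
      data.frame(organ = sample(organs, k),
                 evidence = sample(c("confirmatory", "nonspecific"), k,
                                   replace = TRUE),
                 stringsAsFactors = FALSE)
    } else NULL
    f <- metastasis_findings(
      malignant_effusion = stats::runif(1) < 0.15,
      pleural_or_pericardial_nodules = stats::runif(1) < 0.1,
      contralateral_lung_nodule = stats::runif(1) < 0.1,
      extrathoracic_lesions = les,
      explicitly_indeterminate = stats::runif(1) < 0.1,
      coverage_adequate = stats::runif(1) > 0.1)
    s <- stage_m(f, staging_config(m_strategy = "strict"))$label
    l <- stage_m(f, staging_config(m_strategy = "lenient"))$label
    expect_gte(m_rank(l), m_rank(s))
  }
})

test_that("stage grouping matches the AJCC table on reference triples", {
  g <- function(t, n, m) group_stage(tnm_stage(t, n, m), cfg)$group
  expect_identical(g("T2a", "N0", "M0"), "IB")
  expect_identical(g("T1c", "N2", "M0"), "IIIA")
  expect_identical(g("T1a", "N0", "M0"), "IA1")
  expect_identical(g("T1b", "N0", "M0"), "IA2")
  expect_identical(g("T1c", "N0", "M0"), "IA3")
  expect_identical(g("T2b", "N0", "M0"), "IIA")
  expect_identical(g("T3", "N0", "M0"), "IIB")
  expect_identical(g("T4", "N0", "M0"), "IIIA")
  expect_identical(g("T2b", "N1", "M0"), "IIB")
  expect_identical(g("T4", "N1", "M0"), "IIIA")
  expect_identical(g("T3", "N2", "M0"), "IIIB")
  expect_identical(g("T2a", "N3", "M0"), "IIIB")
  expect_identical(g("T4", "N3", "M0"), "IIIC")
  expect_identical(g("T2", "N0", "M0"), "IB")  # bare T2 grouped as T2a
  expect_identical(g("T3", "N1", "M1c"), "IVB")
  expect_identical(g("T1a", "N0", "M1a"), "IVA")
  expect_identical(g("T1a", "N0", "M1b"), "IVA")
  expect_identical(g("Tis", "N0", "M0"), "0")
  expect_identical(g("Tx", "N0", "M0"), "occult")
  expect_identical(g("Tx", "N1", "M0"), "indeterminate")
  expect_identical(g("T1a", "Nx", "M0"), "indeterminate")
  expect_identical(g("T1a", "N0", "Mx"), "indeterminate")
})

test_that("every T x N x M triple maps to exactly one clinical stage", {
  grid <- expand.grid(t = t_levels(), n = n_levels(), m = m_levels(),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(grid), 275L)
  groups <- vapply(seq_len(nrow(grid)), function(i) {
    group_stage(list(t = grid$t[i], n = grid$n[i], m = grid$m[i]), cfg)$group
  }, character(1))
  expect_true(all(groups %in% stage_levels()))
})

test_that("staging is deterministic and every label is justified in the trace", {
  cohort <- make_cohort(n = 20, seed = 77)
  for (case in cohort$cases) {
    a <- stage_case(case, cfg)
    b <- stage_case(case, cfg)
    expect_identical(a, b)
    expect_gt(length(a$tnm$trace), 0)
    expect_identical(sum(grepl("^T\\|fired:", a$tnm$trace)), 1L)
    expect_identical(sum(grepl("^N\\|fired:", a$tnm$trace)), 1L)
    expect_identical(sum(grepl("^M\\|fired:", a$tnm$trace)), 1L)
  }
})
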