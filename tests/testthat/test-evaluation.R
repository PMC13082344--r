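test_that("confusion cross-tabulates truth against predictions", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"))
  expect_identical(cm["A", "A"], 1L)
  expect_identical(cm["A", "B"], 1L)
  expect_identical(cm["B", "B"], 1L)
  expect_identical(attr(cm, "n"), 3L)

  perfect <- confusion(c("A", "B", "C"), c("A", "B", "C"))
  expect_identical(sum(diag(perfect)), 3L)
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)

  expect_error(confusion("A", "Z", classes = c("A", "B")), "vocabulary")
  expect_error(confusion(c("A", "B"), "A"), "equal length")

  set.seed(17)
  for (i in 1:20) {
    tt <- sample(letters[1:4], 60, replace = TRUE)
    pp <- sample(letters[1:4], 60, replace = TRUE)
    cm <- confusion(tt, pp, classes = letters[1:4])
    expect_identical(as.integer(rowSums(cm)),
                     as.integer(table(factor(tt, letters[1:4]))))
    expect_identical(as.integer(colSums(cm)),
                     as.integer(table(factor(pp, letters[1:4]))))
  }
})

test_that("prf matches hand values and the zero-division convention", {
  expect_equal(round(f1_score(1, 0.5), 3), 0.667)
  expect_equal(round(f1_score(0.941, 0.970), 3), 0.955)
  expect_identical(f1_score(0, 0), 0)

  # a padded class never true and never predicted scores 0/0/0
  cm <- confusion(c("N0", "N0", "N2"), c("N0", "N2", "N2"),
                  classes = n_levels())
  tab <- prf(cm)$per_class
  nx <- tab[tab$class == "Nx", ]
  expect_identical(c(nx$precision, nx$recall, nx$f1), c(0, 0, 0))
  # macro averages include the zero-score classes
  expect_equal(prf(cm)$macro[["precision"]], mean(tab$precision))
})

test_that("prf agrees with an independent reference on random inputs", {
  set.seed(19)
  classes <- letters[1:5]
  for (i in 1:200) {
    tt <- sample(classes, 40, replace = TRUE)
    pp <- sample(classes, 40, replace = TRUE)
    got <- prf(confusion(tt, pp, classes))$per_class
    ref <- naive_prf(tt, pp, classes)
    expect_equal(got$precision, unname(ref[, "precision"]))
    expect_equal(got$recall, unname(ref[, "recall"]))
    expect_equal(got$f1, unname(ref[, "f1"]))
  }
})

test_that("accuracy_ci computes Wilson intervals", {
  r <- accuracy_ci(92, 100)
  expect_equal(r$accuracy, 0.92)
  expect_equal(r$ci_low_3, 0.850)
  expect_equal(r$ci_high_3, 0.959)
  expect_equal(accuracy_ci(100, 100)$ci_high_3, 1.000)
  expect_equal(accuracy_ci(0, 100)$ci_low_3, 0.000)
  expect_error(accuracy_ci(1, 0), "positive")
  expect_error(accuracy_ci(5, 4), "correct")

  # interval contains the point estimate; width shrinks with n
  set.seed(23)
  for (i in 1:50) {
    n <- sample(10:500, 1)
    x <- sample(0:n, 1)
    r <- accuracy_ci(x, n)
    expect_lte(r$ci_low, r$accuracy)
    expect_gte(r$ci_high, r$accuracy)
    r4 <- accuracy_ci(4 * x, 4 * n)
    expect_lt(r4$ci_high - r4$ci_low, r$ci_high - r$ci_low)
  }
})

test_that("exact_match_ratio counts fully correct triples", {
  tt <- data.frame(t = c("T1a", "T2a", "T3", "T4"), n = rep("N0", 4),
                   m = rep("M0", 4))
  pp <- tt
  expect_equal(exact_match_ratio(tt, pp), 1)
  pp$n[2] <- "N1"
  expect_equal(exact_match_ratio(tt, pp), 0.75)
  expect_error(exact_match_ratio(tt, pp[1:2, ]), "mismatch")
})

test_that("cohen_kappa matches hand computation and is relabel-invariant", {
  expect_equal(cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y")), 0.5)
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  set.seed(29)
  for (i in 1:100) {
    a <- sample(letters[1:4], 50, replace = TRUE)
    b <- sample(letters[1:4], 50, replace = TRUE)
    k <- cohen_kappa(a, b)
    expect_equal(k, naive_kappa(a, b))
    relabel <- c(a = "w", b = "x", c = "y", d = "z")
    expect_equal(cohen_kappa(relabel[a], relabel[b]), k)
  }
  # independent labels at large n: kappa near 0
  a <- sample(letters[1:3], 4000, replace = TRUE)
  b <- sample(letters[1:3], 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  expect_error(cohen_kappa(character(), character()), "empty")
})

test_that("bowker_symmetry reduces to McNemar at k = 2", {
  # off-diagonal counts (3, 1): chi-square (3-1)^2/4 = 1, df 1
  a <- c(rep("p", 3), rep("q", 1), rep("p", 6))
  b <- c(rep("q", 3), rep("p", 1), rep("p", 6))
  r <- bowker_symmetry(a, b, classes = c("p", "q"))
  expect_equal(r$chi_square, 1)
  expect_identical(r$df, 1)

  set.seed(31)
  for (i in 1:100) {
    a <- sample(c("p", "q"), 40, replace = TRUE)
    b <- sample(c("p", "q"), 40, replace = TRUE)
    got <- bowker_symmetry(a, b, classes = c("p", "q"))
    ref <- stats::mcnemar.test(table(factor(a, c("p", "q")),
                                     factor(b, c("p", "q"))),
                               correct = FALSE)
    if (!is.nan(ref$statistic)) {
      expect_equal(got$chi_square, unname(ref$statistic))
      expect_equal(got$p_value, unname(ref$p.value))
    }
  }
})

test_that("bowker df follows the full-pair convention", {
  preds10 <- sample(letters[1:10], 100, replace = TRUE)
  expect_identical(bowker_symmetry(preds10, rev(preds10),
                                   classes = letters[1:10])$df, 45)
  preds5 <- sample(letters[1:5], 100, replace = TRUE)
  expect_identical(bowker_symmetry(preds5, rev(preds5),
                                   classes = letters[1:5])$df, 10)
  expect_error(bowker_symmetry("a", "a", classes = "a"), "2 classes")
})

test_that("a symmetric disagreement table gives chi-square 0", {
  a <- c("p", "q", "p", "q", "r", "r")
  b <- c("q", "p", "p", "q", "r", "r")
  r <- bowker_symmetry(a, b, classes = c("p", "q", "r"))
  expect_equal(r$chi_square, 0)
  expect_equal(r$omega$omega, 0)
})

test_that("cohen_omega applies the effect-size formula and benchmarks", {
  expect_equal(round(cohen_omega(14, 100)$omega, 3), 0.374)
  expect_equal(round(cohen_omega(15.9, 100)$omega, 3), 0.399)
  expect_equal(cohen_omega(0, 100)$omega, 0)
  expect_identical(cohen_omega(2, 100)$interpretation, "small")
  expect_identical(cohen_omega(10, 100)$interpretation, "medium")
  expect_identical(cohen_omega(26, 100)$interpretation, "large")
  expect_error(cohen_omega(1, 0), "positive")
})

test_that("evaluate_run of truth against itself is perfect", {
  cohort <- make_cohort(n = 30, seed = 41)
  truth <- gold_df(cohort$cases)
  rep_ <- evaluate_run(truth, truth, pred_b = truth)
  for (comp in c("T", "N", "M")) {
    cc <- rep_$components[[comp]]
    expect_equal(cc$accuracy$accuracy, 1)
    expect_equal(cc$kappa, 1)
    expect_identical(unname(cc$severity[["total"]]), 0L)
    expect_equal(cc$comparison$chi_square, 0)
  }
  expect_equal(rep_$exact_match, 1)
  expect_equal(rep_$clinical$accuracy$accuracy, 1)
})

test_that("evaluate_run recovers an injected corruption rate", {
  cohort <- make_cohort(n = 1000, seed = 43, corruption_rate = 0.1)
  truth <- gold_df(cohort$cases)
  rep_ <- evaluate_run(truth, cohort$predictions)
  for (comp in c("T", "N", "M")) {
    acc <- rep_$components[[comp]]$accuracy$accuracy
    expect_gt(acc, 0.87)  # 0.9 within ~3 binomial SDs
    expect_lt(acc, 0.93)
  }
  expect_error(evaluate_run(truth[-1, ], cohort$predictions),
               "case_id mismatch")
})
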