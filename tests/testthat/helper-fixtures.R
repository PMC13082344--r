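# Shared fixtures: all tests build their inputs in code.

# small cohort with text and gold labels
make_cohort <- function(n = 30, seed = 101, distractor_rate = 0.3,
                        language = "zh", corruption_rate = 0) {
  generate_cohort(sim_config(n_cases = n, seed = seed,
                             distractor_rate = distractor_rate,
                             language = language,
                             corruption_rate = corruption_rate))
}

gold_df <- function(cases) {
  data.frame(case_id = vapply(cases, `[[`, character(1), "case_id"),
             t = vapply(cases, function(x) x$gold$t, character(1)),
             n = vapply(cases, function(x) x$gold$n, character(1)),
             m = vapply(cases, function(x) x$gold$m, character(1)),
             stringsAsFactors = FALSE)
}

# independent naive per-class precision/recall/F1 (counting loops, no
# matrix algebra shared with the implementation)
naive_prf <- function(truth, pred, classes) {
  rows <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  })
  do.call(rbind, rows)
}

# independent naive Cohen kappa from first principles
naive_kappa <- function(a, b) {
  classes <- unique(c(a, b))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (cl in classes) pe <- pe + (sum(a == cl) / n) * (sum(b == cl) / n)
  (po - pe) / (1 - pe)
}

# inject OCR-style noise: spurious spaces and line breaks between CJK chars
inject_noise <- function(x) {
  chars <- strsplit(x, "")[[1]]
  out <- character(0)
  for (ch in chars) {
    out <- c(out, ch)
    if (grepl("\\p{Han}", ch, perl = TRUE) && stats::runif(1) < 0.3) {
      out <- c(out, sample(c(" ", "\n", " \n "), 1))
    }
  }
  paste(out, collapse = "")
}

m_rank <- function(m) c(M0 = 0, Mx = 1, M1a = 2, M1b = 3, M1c = 4)[[m]]
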