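# Evaluation statistics: confusion matrices, per-class and macro
# precision/recall/F1, Wilson confidence intervals, exact-match ratio,
# Cohen kappa, the McNemar-Bowker symmetry test, and the Cohen omega
# effect size.

#' Cross-tabulate truth against predictions
#'
#' @param truth,pred Equal-length aligned label vectors.
#' @param classes Ordered label vocabulary; both vectors must draw from it.
#' @return A `confusion_matrix`: square integer matrix indexed
#'   (truth, predicted) with attribute `n`.
#' @export
confusion <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, pred)), classes)
  if (length(bad)) {
    stop("label outside vocabulary: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(truth, levels = classes),
                  factor(pred, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, n = length(truth), class = c("confusion_matrix", "matrix", "array"))
}

#' Per-class and macro precision, recall and F1
#'
#' Precision is TP/(TP+FP) and recall TP/(TP+FN), both 0 when their
#' denominator is 0; F1 is their harmonic mean (0 when precision + recall
#' is 0).  Macro averages are unweighted arithmetic means over all classes
#' of the matrix vocabulary, zero-score classes included.
#'
#' @param matrix A [confusion()] matrix.
#' @return List with `per_class` (data frame: class, precision, recall,
#'   f1, support) and `macro` (named numeric: precision, recall, f1).
#' @export
#' @examples
#' cm <- confusion(c("A", "A", "B"), c("A", "B", "B"))
#' prf(cm)$per_class
prf <- function(matrix) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  tp <- diag(matrix)
  fp <- colSums(matrix) - tp
  fn <- rowSums(matrix) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- f1_score(precision, recall)
  per_class <- data.frame(class = rownames(matrix), precision = precision,
                          recall = recall, f1 = f1,
                          support = as.integer(rowSums(matrix)),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(per_class = per_class,
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)))
}

#' Harmonic-mean F1 score
#'
#' @param precision,recall Proportions in `[0, 1]` (vectorized).
#' @return `2 * precision * recall / (precision + recall)`, 0 when the
#'   denominator is 0.
#' @export
#' @examples
#' f1_score(1, 0.5) # 0.6667
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Accuracy with a Wilson score confidence interval
#'
#' @param correct Number of correct predictions.
#' @param n Total predictions (> 0).
#' @param level Confidence level (default 0.95).
#' @return List with `accuracy`, `ci_low`, `ci_high` (full precision),
#'   `ci_low_3`, `ci_high_3` (reporting precision, 3 decimals) and `n`.
#' @export
#' @examples
#' accuracy_ci(92, 100) # CI 0.850-0.959
accuracy_ci <- function(correct, n, level = 0.95) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (correct < 0 || correct > n) stop("correct must be in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- correct / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lo <- (centre - half) / denom
  hi <- (centre + half) / denom
  list(accuracy = p, ci_low = lo, ci_high = hi,
       ci_low_3 = round(lo, 3), ci_high_3 = round(hi, 3), n = n)
}

#' Exact match ratio over TNM triples
#'
#' Fraction of cases where T, N and M are all predicted correctly.
#'
#' @param truth,pred Data frames (or lists of [tnm_stage()]) with aligned
#'   `t`, `n`, `m` labels.
#' @return Proportion in `[0, 1]`.
#' @export
exact_match_ratio <- function(truth, pred) {
  tt <- .as_label_df(truth); pp <- .as_label_df(pred)
  if (nrow(tt) != nrow(pp)) stop("length mismatch", call. = FALSE)
  if (!nrow(tt)) stop("empty input", call. = FALSE)
  mean(tt$t == pp$t & tt$n == pp$n & tt$m == pp$m)
}

.as_label_df <- function(x) {
  if (is.data.frame(x)) return(x[, c("t", "n", "m")])
  data.frame(t = vapply(x, `[[`, character(1), "t"),
             n = vapply(x, `[[`, character(1), "n"),
             m = vapply(x, `[[`, character(1), "m"),
             stringsAsFactors = FALSE)
}

#' Cohen kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement; 1 when both observed and chance
#' agreement are perfect.
#'
#' @param labels_a,labels_b Equal-length aligned categorical vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y")) # 0.5
cohen_kappa <- function(labels_a, labels_b) {
  if (!length(labels_a)) stop("empty input", call. = FALSE)
  if (length(labels_a) != length(labels_b)) {
    stop("length mismatch", call. = FALSE)
  }
  classes <- sort(unique(c(labels_a, labels_b)))
  n <- length(labels_a)
  po <- mean(labels_a == labels_b)
  pa <- table(factor(labels_a, classes)) / n
  pb <- table(factor(labels_b, classes)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (pe == 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' McNemar-Bowker test of symmetry for paired multi-class predictions
#'
#' Cross-tabulates the two models' predictions and tests symmetry of the
#' off-diagonal disagreements: chi-square is the sum over unordered class
#' pairs (i, j) with `n_ij + n_ji > 0` of `(n_ij - n_ji)^2 / (n_ij +
#' n_ji)`; empty pairs contribute 0.  Degrees of freedom follow the
#' full-pair convention `k (k - 1) / 2` over the declared vocabulary.  For
#' k = 2 the statistic reduces to the classical McNemar test without
#' continuity correction.  The Cohen omega effect size `sqrt(chi^2 / n)`
#' is attached.
#'
#' @param pred_a,pred_b Aligned prediction vectors of the two models.
#' @param classes Declared label vocabulary (k >= 2).
#' @return List with `chi_square`, `df`, `p_value`, `n`, `omega` and the
#'   paired `table`.
#' @export
bowker_symmetry <- function(pred_a, pred_b,
                            classes = sort(unique(c(pred_a, pred_b)))) {
  if (length(pred_a) != length(pred_b)) stop("length mismatch", call. = FALSE)
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  bad <- setdiff(unique(c(pred_a, pred_b)), classes)
  if (length(bad)) {
    stop("label outside vocabulary: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  k <- length(classes)
  tab <- table(factor(pred_a, classes), factor(pred_b, classes))
  chi <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- tab[i, j] + tab[j, i]
      if (s > 0) chi <- chi + (tab[i, j] - tab[j, i])^2 / s
    }
  }
  df <- k * (k - 1) / 2
  n <- length(pred_a)
  list(chi_square = as.numeric(chi), df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE), n = n,
       omega = cohen_omega(chi, n), table = tab)
}

#' Cohen omega effect size
#'
#' `omega = sqrt(chi_square / n)`; by conventional benchmarks 0.1 is a
#' small, 0.3 a medium and 0.5 a large effect.
#'
#' @param chi_square Chi-square statistic (>= 0).
#' @param n Sample size (> 0).
#' @return List with `omega` and its benchmark `interpretation`.
#' @export
#' @examples
#' cohen_omega(15.9, 100)$omega # 0.399
cohen_omega <- function(chi_square, n) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (chi_square < 0) stop("chi_square must be non-negative", call. = FALSE)
  omega <- sqrt(chi_square / n)
  interpretation <- if (omega >= 0.5) "large" else if (omega >= 0.3) "medium"
                    else if (omega >= 0.1) "small" else "negligible"
  list(omega = omega, interpretation = interpretation)
}

#' Evaluate one (or two) prediction sets against truth
#'
#' Assembles, per component (T, N, M): the confusion matrix over the full
#' component vocabulary, per-class and macro precision/recall/F1, accuracy
#' with a Wilson CI, severity-category tallies, and Cohen kappa; plus the
#' exact-match ratio and the derived clinical-stage accuracy (stage groups
#' computed from both truth and predicted triples).  When a second
#' prediction set is supplied, a paired McNemar-Bowker comparison with
#' Cohen omega is added per component.
#'
#' @param truth,pred Label data frames with columns `case_id`, `t`, `n`,
#'   `m` (see [read_labels()]).
#' @param pred_b Optional second prediction set for paired comparison.
#' @param config A [staging_config()] used for stage grouping.
#' @param level Confidence level for accuracy CIs.
#' @return An `eval_report` list.
#' @export
evaluate_run <- function(truth, pred, pred_b = NULL,
                         config = staging_config(), level = 0.95) {
  .align <- function(a, b, who) {
    if (!setequal(a$case_id, b$case_id)) {
      off <- c(setdiff(a$case_id, b$case_id), setdiff(b$case_id, a$case_id))
      stop("case_id mismatch with ", who, ": ", paste(off, collapse = ", "),
           call. = FALSE)
    }
    b[match(a$case_id, b$case_id), ]
  }
  pred <- .align(truth, pred, "pred")
  if (!is.null(pred_b)) pred_b <- .align(truth, pred_b, "pred_b")
  n <- nrow(truth)
  vocab <- list(T = t_levels(), N = n_levels(), M = m_levels())
  cols <- c(T = "t", N = "n", M = "m")
  components <- lapply(names(vocab), function(comp) {
    col <- cols[[comp]]
    tt <- truth[[col]]; pp <- pred[[col]]
    cm <- confusion(tt, pp, classes = vocab[[comp]])
    out <- list(
      component = comp,
      confusion = cm,
      prf = prf(cm),
      accuracy = accuracy_ci(sum(tt == pp), n, level),
      kappa = cohen_kappa(tt, pp),
      severity = tally_errors(tt, pp, comp)
    )
    if (!is.null(pred_b)) {
      out$comparison <- bowker_symmetry(pp, pred_b[[col]], classes = vocab[[comp]])
      out$severity_b <- tally_errors(tt, pred_b[[col]], comp)
    }
    out
  })
  names(components) <- names(vocab)

  grp <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      group_stage(list(t = df$t[i], n = df$n[i], m = df$m[i]), config)$group
    }, character(1))
  }
  truth_grp <- grp(truth)
  pred_grp <- grp(pred)
  list_out <- list(
    n = n,
    components = components,
    exact_match = exact_match_ratio(truth, pred),
    clinical = list(
      accuracy = accuracy_ci(sum(truth_grp == pred_grp), n, level),
      confusion = confusion(truth_grp, pred_grp, classes = stage_levels())
    )
  )
  structure(list_out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d cases\n", x$n))
  for (comp in names(x$components)) {
    cc <- x$components[[comp]]
    acc <- cc$accuracy
    cat(sprintf("  %s: accuracy %.1f%% (95%% CI %.3f-%.3f), macro-F1 %.3f, kappa %.3f, errors I/II/III = %d/%d/%d\n",
                comp, 100 * acc$accuracy, acc$ci_low_3, acc$ci_high_3,
                cc$prf$macro[["f1"]], cc$kappa,
                cc$severity[["I"]], cc$severity[["II"]], cc$severity[["III"]]))
    if (!is.null(cc$comparison)) {
      cmp <- cc$comparison
      cat(sprintf("     paired Bowker: chi-square %.3f (df %d), p = %.3g, omega = %.3f\n",
                  cmp$chi_square, cmp$df, cmp$p_value, cmp$omega$omega))
    }
  }
  cat(sprintf("  exact match %.1f%%; clinical staging accuracy %.1f%% (95%% CI %.3f-%.3f)\n",
              100 * x$exact_match, 100 * x$clinical$accuracy$accuracy,
              x$clinical$accuracy$ci_low_3, x$clinical$accuracy$ci_high_3))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes `confusion_<C>.csv` and `prf_<C>.csv` per component plus
#' `summary.json` into a directory.
#'
#' @param report An [evaluate_run()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(n = report$n, exact_match = report$exact_match,
                  clinical_accuracy = report$clinical$accuracy)
  for (comp in names(report$components)) {
    cc <- report$components[[comp]]
    utils::write.csv(as.data.frame.matrix(unclass(cc$confusion)),
                     file.path(dir, sprintf("confusion_%s.csv", comp)))
    utils::write.csv(cc$prf$per_class,
                     file.path(dir, sprintf("prf_%s.csv", comp)),
                     row.names = FALSE)
    summary[[comp]] <- list(
      accuracy = cc$accuracy, kappa = cc$kappa,
      macro = as.list(cc$prf$macro),
      severity = as.list(cc$severity)
    )
    if (!is.null(cc$comparison)) {
      summary[[comp]]$comparison <- cc$comparison[c("chi_square", "df",
                                                    "p_value", "n")]
      summary[[comp]]$comparison$omega <- cc$comparison$omega$omega
    }
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
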