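# Clinical-impact severity taxonomy for staging errors.
#
# Disagreements are graded into three tiers by their potential effect on
# clinical decision-making: I (major: changes the treatment goal, e.g.
# M0 vs M1), II (moderate: may change the stage group or adjuvant choice),
# III (minor: substage distinctions, or any indeterminate label).
# Classification is pair-based and undirected.

.major_t <- function(label) {
  if (label %in% c("T1a", "T1b", "T1c")) "T1"
  else if (label %in% c("T2a", "T2b")) "T2"
  else label
}

#' Classify one staging disagreement by clinical severity
#'
#' Exact agreement is `none`.  Any pair involving an indeterminate label
#' (`Tx`, `Nx`, `Mx`) is category III (the clinical stage cannot be
#' determined and needs further evaluation) — this rule precedes all pair
#' rules.  For T, labels collapse to major categories
#' (T0/Tis/T1/T2/T3/T4): T0 versus any tumor-present label is I; T1 or T2
#' versus T4 is I; adjacent-major confusions (T1/T2, T1/T3, T2/T3, T3/T4)
#' are II; within-T1 substage confusions are III; within-T2 substage
#' confusions (and pairs with Tis not covered above) default to II.  For
#' N: N0/N2 and N0/N3 are I; N0/N1, N1/N2, N1/N3 are II; N2/N3 is III.
#' For M: M0 versus any M1 is I; confusions among M1a/M1b/M1c are III.
#'
#' @param component `"T"`, `"N"` or `"M"`.
#' @param truth,predicted Labels from the component's vocabulary.
#' @return One of `"I"`, `"II"`, `"III"`, `"none"`.
#' @export
#' @examples
#' classify_error("M", "M0", "M1b") # "I"
#' classify_error("T", "T1b", "T1c") # "III"
classify_error <- function(component, truth, predicted) {
  component <- match.arg(component, c("T", "N", "M"))
  vocab <- switch(component, T = t_levels(), N = n_levels(), M = m_levels())
  if (!(truth %in% vocab)) abort_field("truth", paste("not a", component, "label:", truth))
  if (!(predicted %in% vocab)) {
    abort_field("predicted", paste("not a", component, "label:", predicted))
  }
  if (truth == predicted) return("none")
  x_label <- switch(component, T = "Tx", N = "Nx", M = "Mx")
  if (truth == x_label || predicted == x_label) return("III")

  if (component == "M") {
    if (truth == "M0" || predicted == "M0") return("I")
    return("III")  # among M1a/M1b/M1c
  }
  if (component == "N") {
    pair <- paste(sort(c(truth, predicted)), collapse = "/")
    return(switch(pair,
                  "N0/N2" = , "N0/N3" = "I",
                  "N0/N1" = , "N1/N2" = , "N1/N3" = "II",
                  "N2/N3" = "III"))
  }
  # T component
  a <- .major_t(truth); b <- .major_t(predicted)
  if (a == b) {
    # substage confusion within one major category
    return(if (a == "T1") "III" else "II")
  }
  pair <- paste(sort(c(a, b)), collapse = "/")
  if (a == "T0" || b == "T0") return("I")
  if (pair %in% c("T1/T4", "T2/T4")) return("I")
  if (pair %in% c("T1/T2", "T1/T3", "T2/T3", "T3/T4")) return("II")
  "II"  # pairs with Tis: stage-group change exceeds a minor impact
}

#' Tally staging errors by severity category
#'
#' @param truth,predicted Equal-length aligned label vectors.
#' @param component `"T"`, `"N"` or `"M"`.
#' @return Named integer vector with counts `I`, `II`, `III` and `total`
#'   (`total` equals the number of disagreements).
#' @export
tally_errors <- function(truth, predicted, component) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  cats <- vapply(seq_along(truth), function(i) {
    classify_error(component, truth[i], predicted[i])
  }, character(1))
  out <- c(I = sum(cats == "I"), II = sum(cats == "II"),
           III = sum(cats == "III"))
  c(out, total = sum(out))
}
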