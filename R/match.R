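# Longest-match term scanning with clause-scoped negation.

# Locate all occurrences of literal surface forms in `text`, resolved to
# longest-match, non-overlapping spans in reading order.  Case-insensitive
# (relevant for the English lexicon).  Returns data.frame(term, start, end).
scan_terms <- function(text, terms) {
  if (!nzchar(text) || !length(terms)) {
    return(data.frame(term = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  ltext <- tolower(text)
  hits <- lapply(unique(terms), function(tm) {
    pos <- gregexpr(tolower(tm), ltext, fixed = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    data.frame(term = tm, start = as.integer(pos),
               end = as.integer(pos) + nchar(tm) - 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(term = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  # reading order; on ties the longest surface wins
  hits <- hits[order(hits$start, -nchar(hits$term)), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match lexicon terms in normalized text
#'
#' Finds longest-match, non-overlapping occurrences of a category's surface
#' forms in reading order.  A match is negated when a negation cue occurs
#' within the preceding `negation_window` characters of the same clause
#' (clauses are comma- and sentence-delimited).
#'
#' @param text Normalized report text (see [normalize_text()]).
#' @param lexicon A [lexicon()].
#' @param category One of `lexicon_categories()`.
#' @param negation_window Number of characters before a match within which a
#'   negation cue negates it (default 6).
#' @return Data frame with columns `term`, `start`, `end`, `negated`;
#'   `start` positions are strictly increasing and spans never overlap.
#' @export
#' @examples
#' lex <- default_lexicon("zh")
#' match_terms("考虑转移", lex, "metastasis_confirmatory")
match_terms <- function(text, lexicon, category, negation_window = 6L) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (!category %in% names(lexicon$term_lists)) {
    stop("unknown category: ", category, call. = FALSE)
  }
  hits <- scan_terms(text, lexicon$term_lists[[category]])
  hits$negated <- vapply(seq_len(nrow(hits)), function(i) {
    is_negated(text, hits$start[i], lexicon, negation_window)
  }, logical(1))
  hits
}

# Is the span starting at `start` preceded, within the same clause and
# within `window` characters, by a negation cue?
is_negated <- function(text, start, lexicon, window = 6L) {
  if (start <= 1L) return(FALSE)
  cs <- clause_starts(text)
  clause_start <- max(cs[cs <= start])
  win_start <- max(clause_start, start - window)
  if (win_start >= start) return(FALSE)
  window_text <- substr(text, win_start, start - 1L)
  cues <- lexicon$term_lists$negation_cues
  any(vapply(cues, function(cue) {
    grepl(tolower(cue), tolower(window_text), fixed = TRUE)
  }, logical(1)))
}
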