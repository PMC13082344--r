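# Text normalization tolerant of OCR-style noise: erroneous line breaks and
# spurious spaces between CJK characters.

#' Normalize report text
#'
#' Collapses runs of whitespace, removes spurious single spaces between CJK
#' characters, and joins lines broken mid-sentence.  Idempotent:
#' `normalize_text(normalize_text(x))` equals `normalize_text(x)`.
#'
#' @param raw Character vector of raw report text.
#' @return Normalized text, same length as `raw`.
#' @export
#' @examples
#' normalize_text("左 下 叶") # spaces between CJK removed
normalize_text <- function(raw) {
  if (!length(raw)) return(character())
  vapply(raw, function(x) {
    if (is.na(x)) return(NA_character_)
    x <- gsub("\r\n?", "\n", x)
    x <- gsub("[ \t]+", " ", x)
    # line break splitting a CJK sentence: join without a space
    x <- gsub("(?<=[\\p{Han}、。，；：]) ?\n ?(?=[\\p{Han}])",
              "", x, perl = TRUE)
    x <- gsub(" ?\n+ ?", " ", x)
    # spurious single spaces inside CJK runs
    repeat {
      y <- gsub("(?<=[\\p{Han}、。，；：]) (?=[\\p{Han}、。，；：])",
                "", x, perl = TRUE)
      if (identical(y, x)) break
      x <- y
    }
    trimws(x)
  }, character(1), USE.NAMES = FALSE)
}

# Sentence and clause splitting used by the extractor.  Sentences split on
# terminal punctuation; clauses additionally on commas (negation scope).
split_sentences <- function(text) {
  parts <- strsplit(text, "[。；！？;!?\n]|\\.\\s", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

clause_starts <- function(text) {
  # positions (1-based) where a new clause begins
  brk <- gregexpr("[。；！？，、;!?,\n.]", text, perl = TRUE)[[1]]
  if (brk[1] == -1) return(1L)
  sort(unique(c(1L, brk + 1L)))
}
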