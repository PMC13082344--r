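# Lexicon objects: named term lists per evidence category, per language.

lexicon_categories <- function() {
  c("metastasis_confirmatory", "metastasis_nonspecific",
    "invasion_confirmatory", "nodal_confirmatory", "nodal_nonspecific",
    "malignant_nodule", "negation_cues")
}

#' Create a lexicon
#'
#' A lexicon maps evidence categories to lists of literal surface forms.
#' The shipped defaults (see [default_lexicon()]) encode the supplementary
#' staging rules' term lists: high-specificity metastasis wording versus
#' nonspecific findings, explicit invasion and nodal wording, cancer-nodule
#' wording, and negation cues.
#'
#' @param name Lexicon name.
#' @param language `"zh"` or `"en"`.
#' @param term_lists Named list mapping each category in
#'   `lexicon_categories()` to a character vector of surface forms.
#' @return A `lexicon` object.
#' @export
lexicon <- function(name, language = c("zh", "en"), term_lists) {
  language <- match.arg(language)
  if (!is.list(term_lists) || !all(lexicon_categories() %in% names(term_lists))) {
    abort_field("term_lists",
                paste("must name every category:",
                      paste(lexicon_categories(), collapse = ", ")))
  }
  term_lists <- lapply(term_lists[lexicon_categories()], as.character)
  if (any(!vapply(term_lists, length, integer(1)))) {
    abort_field("term_lists", "all category lists must be nonempty")
  }
  all_terms <- unlist(term_lists, use.names = FALSE)
  cat_of <- rep(names(term_lists), vapply(term_lists, length, integer(1)))
  dup <- unique(all_terms[duplicated(all_terms)])
  dup <- dup[vapply(dup, function(tm) {
    length(unique(cat_of[all_terms == tm])) > 1L
  }, logical(1))]
  if (length(dup)) {
    abort_field("term_lists",
                paste("surface form in two categories:", paste(dup, collapse = ", ")))
  }
  structure(list(name = name, language = language, term_lists = term_lists),
            class = "lexicon")
}

#' Load a lexicon
#'
#' `default_lexicon()` returns one of the two shipped lexicons;
#' `load_lexicon()` reads a user-supplied YAML (or JSON) file with fields
#' `name`, `language` and `term_lists`.
#'
#' @param language `"zh"` (primary) or `"en"` (mirror).
#' @return A [lexicon()] object.
#' @export
#' @examples
#' lex <- default_lexicon("zh")
#' names(lex$term_lists)
default_lexicon <- function(language = c("zh", "en")) {
  language <- match.arg(language)
  path <- system.file("extdata", paste0("lexicon_", language, ".yaml"),
                      package = "tnmstager", mustWork = TRUE)
  load_lexicon(path)
}

#' @rdname default_lexicon
#' @param path YAML or JSON lexicon file.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lexicon(raw$name, raw$language, raw$term_lists)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon> %s (%s): %s\n", x$name, x$language,
              paste(sprintf("%s[%d]", names(x$term_lists),
                            vapply(x$term_lists, length, integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' Resolve an interpretation strategy
#'
#' Under `strict`, only high-specificity metastasis wording counts as
#' evidence for a distant lesion; under `lenient`, nonspecific findings in
#' distant organs also count.
#'
#' @param mode `"strict"` (default, conservative) or `"lenient"`.
#' @return Normalized mode string.
#' @export
interpretation_strategy <- function(mode = c("strict", "lenient")) {
  match.arg(mode)
}
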