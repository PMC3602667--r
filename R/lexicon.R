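#' Keyword lexicon driving the assertion filter
#'
#' Three pairwise-disjoint keyword sets plus the punctuation characters that
#' demark sentence ends:
#'
#' * negation keywords (Dutch defaults: "geen", "niet", "zonder", ...),
#' * speculation keywords ("mogelijk", "waarschijnlijk", "verdacht", ...),
#' * alternatives keywords ("of", "versus", ...).
#'
#' Keywords are matched as whole lowercase tokens, never as substrings.
#' Commas are deliberately absent from the default sentence terminators: a
#' clause like `"cholelithiasis, schrompelnier li?"` must count as a single
#' sentence so that the question mark governs all of it.
#'
#' @param negation,speculation,alternatives character vectors of lowercase
#'   single-token keywords.
#' @param sentence_terminators character vector of single punctuation marks.
#' @return An object of class `keyword_lexicon`.
#' @seealso [apply_assertion_filter()], [read_keyword_file()],
#'   [default_lexicon()]
#' @export
keyword_lexicon <- function(negation = character(),
                            speculation = character(),
                            alternatives = character(),
                            sentence_terminators = c(".", "!", "?", ":", ";")) {
  check_kw <- function(kw, what) {
    kw <- unique(as.character(kw))
    if (any(!nzchar(kw))) stop_badarg(what, " keywords must be non-empty")
    if (any(kw != tolower(kw))) stop_badarg(what, " keywords must be lowercase")
    if (any(grepl("[^[:alnum:]]", kw))) {
      stop_badarg(what, " keywords must be single alphanumeric tokens")
    }
    kw
  }
  negation <- check_kw(negation, "negation")
  speculation <- check_kw(speculation, "speculation")
  alternatives <- check_kw(alternatives, "alternatives")
  all_kw <- c(negation, speculation, alternatives)
  if (anyDuplicated(all_kw)) {
    stop_badarg("keyword sets must be pairwise disjoint; shared: ",
                paste(unique(all_kw[duplicated(all_kw)]), collapse = ", "))
  }
  sentence_terminators <- unique(as.character(sentence_terminators))
  if (any(nchar(sentence_terminators) != 1L)) {
    stop_badarg("sentence terminators must be single characters")
  }
  structure(
    list(negation_keywords = negation,
         speculation_keywords = speculation,
         alternatives_keywords = alternatives,
         sentence_terminators = sentence_terminators),
    class = "keyword_lexicon"
  )
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  cat(sprintf(
    "<keyword_lexicon: %d negation, %d speculation, %d alternatives keywords; terminators %s>\n",
    length(x$negation_keywords), length(x$speculation_keywords),
    length(x$alternatives_keywords),
    paste(x$sentence_terminators, collapse = "")
  ))
  invisible(x)
}

#' Read a keyword file
#'
#' One keyword per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path file path.
#' @return Character vector of keywords.
#' @export
read_keyword_file <- function(path) {
  if (!file.exists(path)) stop_badarg("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Default Dutch lexicon
#'
#' Loads the editable keyword files shipped under
#' `inst/extdata/lexicons` (`negation_nl.txt`, `speculation_nl.txt`,
#' `alternatives_nl.txt`). The medical records the filter was designed for
#' are Dutch, but the mechanism is language-agnostic: supply your own files
#' via [keyword_lexicon()] and [read_keyword_file()] for other languages.
#'
#' @return A [keyword_lexicon()].
#' @export
default_lexicon <- function() {
  dir <- system.file("extdata", "lexicons", package = "casefinder",
                     mustWork = TRUE)
  keyword_lexicon(
    negation = read_keyword_file(file.path(dir, "negation_nl.txt")),
    speculation = read_keyword_file(file.path(dir, "speculation_nl.txt")),
    alternatives = read_keyword_file(file.path(dir, "alternatives_nl.txt"))
  )
}

#' Small English lexicon
#'
#' Convenience lexicon for examples and tests on English text.
#'
#' @return A [keyword_lexicon()].
#' @export
english_lexicon <- function() {
  keyword_lexicon(
    negation = c("no", "not", "without", "never"),
    speculation = c("might", "may", "probable", "probably", "possible",
                    "suspected", "perhaps"),
    alternatives = c("or", "versus", "vs")
  )
}
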