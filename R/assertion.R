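#' Split text into sentences on terminating punctuation
#'
#' A sentence runs up to (but not including) the next terminator character;
#' trailing text without a terminator forms a final sentence with terminator
#' `NA`. Concatenating `sentence` and `terminator` in order reproduces the
#' input exactly, and no sentence contains a terminator character.
#'
#' @param text character scalar.
#' @param terminators character vector of single terminator characters.
#' @return Data frame with character columns `sentence` and `terminator`
#'   (`NA` for the unterminated tail).
#' @export
#' @examples
#' split_sentences("a. b? c")
split_sentences <- function(text, terminators = c(".", "!", "?", ":", ";")) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  empty <- data.frame(sentence = character(), terminator = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  hits <- which(chars %in% terminators)
  if (!length(hits)) {
    return(data.frame(sentence = text, terminator = NA_character_,
                      stringsAsFactors = FALSE))
  }
  starts <- c(1L, hits + 1L)
  ends <- c(hits - 1L, length(chars))
  sent <- substring(text, starts, ends)
  term <- c(chars[hits], NA_character_)
  if (starts[length(starts)] > length(chars)) { # text ends on a terminator
    sent <- sent[-length(sent)]
    term <- term[-length(term)]
  }
  data.frame(sentence = sent, terminator = term, stringsAsFactors = FALSE)
}

# Character position of the end of the earliest whole-token occurrence of any
# keyword in `s`, or NA. Tokens are alphanumeric runs, so a keyword matches
# only when not flanked by alphanumerics.
first_keyword_end <- function(s, keywords) {
  if (!length(keywords) || !nzchar(s)) return(NA_integer_)
  best_start <- NA_integer_
  best_end <- NA_integer_
  for (kw in keywords) {
    m <- regexpr(paste0("(?<![[:alnum:]])", kw, "(?![[:alnum:]])"), s,
                 perl = TRUE)
    if (m > 0L && (is.na(best_start) || m < best_start)) {
      best_start <- as.integer(m)
      best_end <- best_start + attr(m, "match.length") - 1L
    }
  }
  best_end
}

#' Remove negated, speculative, and alternative assertions
#'
#' The assertion filter applied to an entry before featurization:
#'
#' 1. lowercase the text and split it into sentences on the lexicon's
#'    terminator punctuation;
#' 2. drop every sentence containing an alternatives keyword ("of",
#'    "versus", ...) as a whole token;
#' 3. drop every sentence terminated by `?` -- a trailing question mark marks
#'    the whole statement as speculative;
#' 4. in each remaining sentence, remove all words between the first negation
#'    or speculation keyword and the sentence end. The triggering keyword
#'    itself is retained, leaving a usable negative-context token;
#' 5. rejoin the surviving sentences with their terminators.
#'
#' The result is idempotent, and its token multiset is always a subset of the
#' lowercased input's. With an empty lexicon and no `?` in the text the
#' filter only lowercases.
#'
#' @param text character scalar (one entry's free text).
#' @param lexicon a [keyword_lexicon()].
#' @return Filtered, lowercased text.
#' @export
#' @examples
#' lex <- keyword_lexicon(negation = "geen", alternatives = "of")
#' apply_assertion_filter("Patient heeft geen hepatitis. Controle volgende week", lex)
apply_assertion_filter <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "keyword_lexicon"))
  text <- tolower(text)
  ss <- split_sentences(text, lexicon$sentence_terminators)
  if (nrow(ss) == 0L) return("")
  span_kw <- c(lexicon$negation_keywords, lexicon$speculation_keywords)
  out <- character(0)
  for (i in seq_len(nrow(ss))) {
    s <- ss$sentence[i]
    term <- ss$terminator[i]
    if (!is.na(term) && term == "?") next
    if (length(lexicon$alternatives_keywords) &&
        any(tokenize(s) %in% lexicon$alternatives_keywords)) {
      next
    }
    cut <- first_keyword_end(s, span_kw)
    if (!is.na(cut)) s <- substr(s, 1L, cut)
    out <- c(out, paste0(s, if (is.na(term)) "" else term))
  }
  paste0(out, collapse = "")
}
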