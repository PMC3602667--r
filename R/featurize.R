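#' Tokenize filtered text into words
#'
#' Splits on any run of non-alphanumeric characters and drops empty strings;
#' order and duplicates are preserved, single-character tokens are kept.
#' Input is expected to be lowercase already (the assertion filter lowercases
#' its output).
#'
#' @param text character scalar.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize("x- boz: matig coprostase")
tokenize <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(text, "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

# Vectorized tokenization for many texts at once.
tokenize_many <- function(texts) {
  out <- strsplit(as.character(texts), "[^[:alnum:]]+")
  lapply(out, function(t) t[nzchar(t)])
}

#' Pearson chi-square for a 2x2 presence-by-label table
#'
#' The single statistical primitive of the pipeline, used for both feature
#' screening and MyC split scoring. `a`/`b` are the positive/negative
#' training examples containing a token, `c`/`d` those lacking it. Computed
#' by the closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree
#' of freedom and no continuity correction; a degenerate table (any zero row
#' or column margin) yields statistic 0 and p-value 1 by convention.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_statistic(8, 2, 2, 8) # statistic 7.2
chi_square_statistic <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop_badarg("counts must be non-negative")
  }
  if (sum(counts) <= 0) stop_badarg("table total must be positive")
  res <- chi2_cells(a, b, c, d)
  list(statistic = res$statistic, p_value = res$p_value)
}

# Vectorized core: each argument a numeric vector of cell counts. Doubles
# throughout: squared integer products overflow 32-bit range.
chi2_cells <- function(a, b, c, d) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  stat <- numeric(length(a))
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 /
    (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  p <- rep(1, length(a))
  p[ok] <- stats::pchisq(stat[ok], df = 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

#' Build a chi-square-screened bag-of-words vocabulary
#'
#' Scores every distinct token by the chi-square association between its
#' presence in a training example and the example's label, and selects
#' tokens with `p < alpha` (raw p-values, no multiple-testing correction:
#' the screen is a heuristic filter, not an inferential claim). Document
#' frequency is counted over training examples (entries), not patients.
#' Token order is first-occurrence order, making the vocabulary
#' deterministic for a fixed training set.
#'
#' @param tokens list of character vectors, one per training example.
#' @param labels character vector of `"positive"`/`"negative"`, parallel to
#'   `tokens`.
#' @param alpha significance threshold for selection (default 0.05).
#' @return A `feature_vocabulary`: list with a `table` data frame (`token`,
#'   `chi2_stat`, `p_value`, `selected`), `alpha`, and example counts.
#' @export
build_vocabulary <- function(tokens, labels, alpha = 0.05) {
  stopifnot(is.list(tokens), length(tokens) == length(labels))
  if (!all(labels %in% c("positive", "negative"))) {
    stop_badarg("labels must be 'positive' or 'negative'")
  }
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos == 0L || n_neg == 0L) {
    stop_badarg("both classes must be present to score features")
  }
  uniq <- lapply(tokens, unique)
  all_tokens <- unique(unlist(uniq, use.names = FALSE))
  if (is.null(all_tokens)) all_tokens <- character()
  pos_tab <- table(factor(unlist(uniq[labels == "positive"], use.names = FALSE),
                          levels = all_tokens))
  neg_tab <- table(factor(unlist(uniq[labels == "negative"], use.names = FALSE),
                          levels = all_tokens))
  a <- as.numeric(pos_tab)
  b <- as.numeric(neg_tab)
  res <- chi2_cells(a, b, n_pos - a, n_neg - b)
  structure(
    list(
      table = data.frame(token = all_tokens,
                         chi2_stat = res$statistic,
                         p_value = res$p_value,
                         selected = res$p_value < alpha,
                         stringsAsFactors = FALSE),
      alpha = alpha, n_pos = n_pos, n_neg = n_neg
    ),
    class = "feature_vocabulary"
  )
}

#' Tokens retained by the chi-square screen
#'
#' @param vocab a `feature_vocabulary`.
#' @return Character vector of selected tokens, in vocabulary order.
#' @export
selected_tokens <- function(vocab) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  vocab$table$token[vocab$table$selected]
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<feature_vocabulary: %d tokens, %d selected at alpha = %g (%d pos / %d neg examples)>\n",
    nrow(x$table), sum(x$table$selected), x$alpha, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' Binary feature vector for one example
#'
#' Presence/absence indicators over the selected tokens; counts are not
#' used and out-of-vocabulary tokens are ignored.
#'
#' @param tokens character vector of tokens for one example.
#' @param vocab a `feature_vocabulary`.
#' @return Named integer vector of 0/1 over [selected_tokens()].
#' @export
vectorize <- function(tokens, vocab) {
  vectorize_examples(list(tokens), vocab)[1L, ]
}

#' Binary feature matrix for many examples
#'
#' @param tokens list of token vectors.
#' @param vocab a `feature_vocabulary`.
#' @return Integer matrix, one row per example, one column per selected
#'   token.
#' @export
vectorize_examples <- function(tokens, vocab) {
  sel <- selected_tokens(vocab)
  m <- matrix(0L, nrow = length(tokens), ncol = length(sel),
              dimnames = list(NULL, sel))
  if (!length(sel) || !length(tokens)) return(m)
  idx <- lapply(tokens, function(t) match(unique(t), sel))
  rows <- rep(seq_along(tokens), lengths(idx))
  cols <- unlist(idx, use.names = FALSE)
  keep <- !is.na(cols)
  m[cbind(rows[keep], cols[keep])] <- 1L
  m
}

#' Persist a vocabulary as a tab-separated file
#'
#' Columns: token, chi2_stat, p_value, selected.
#'
#' @param vocab a `feature_vocabulary`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  utils::write.table(vocab$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
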