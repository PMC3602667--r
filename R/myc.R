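#' Train a MyC chi-square decision tree
#'
#' MyC grows a binary tree in the style of ID3, but scores candidate splits
#' with the same uncorrected 2x2 chi-square statistic used for feature
#' screening: at each node the unused feature whose presence is most strongly
#' associated with the label is chosen (ties broken toward the
#' lowest-indexed feature). Recursion stops when a node is pure, when no
#' remaining feature reaches `p < alpha`, or when no features remain; a leaf
#' predicts its majority class, with ties resolved toward the positive class
#' (the pipeline's objective is sensitivity-first). No feature repeats on a
#' root-to-leaf path, so tree depth is bounded by the number of features.
#'
#' Split scores depend only on cell counts, so training is invariant to the
#' order of the examples.
#'
#' @param X binary feature matrix (examples x features), as produced by
#'   [vectorize_examples()].
#' @param y character vector of `"positive"`/`"negative"` labels.
#' @param alpha split significance threshold in (0, 1), default 0.05.
#' @return An object of class `myc_tree`.
#' @export
myc_train <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop_badarg("at least one training example required")
  if (length(y) != nrow(X)) stop_badarg("length(y) must equal nrow(X)")
  if (!all(y %in% c("positive", "negative"))) {
    stop_badarg("labels must be 'positive' or 'negative'")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_badarg("alpha must be in (0, 1)")
  }
  structure(
    list(root = myc_grow(X, y == "positive", seq_len(nrow(X)),
                         used = logical(ncol(X)), alpha = alpha),
         alpha = alpha,
         features = colnames(X),
         n_features = ncol(X)),
    class = "myc_tree"
  )
}

myc_leaf <- function(n_pos, n_neg) {
  list(type = "leaf",
       label = if (n_pos >= n_neg) "positive" else "negative",
       n_pos = n_pos, n_neg = n_neg)
}

myc_grow <- function(X, is_pos, rows, used, alpha) {
  n_pos <- sum(is_pos[rows])
  n_neg <- length(rows) - n_pos
  if (n_pos == 0L || n_neg == 0L || all(used)) return(myc_leaf(n_pos, n_neg))
  open <- which(!used)
  sub <- X[rows, open, drop = FALSE]
  tot <- colSums(sub)
  a <- colSums(sub[is_pos[rows], , drop = FALSE])
  b <- tot - a
  sc <- chi2_cells(a, b, n_pos - a, n_neg - b)
  best <- which.max(sc$statistic) # first index wins ties
  if (sc$p_value[best] >= alpha) return(myc_leaf(n_pos, n_neg))
  j <- open[best]
  present <- rows[X[rows, j] == 1L]
  absent <- rows[X[rows, j] == 0L]
  used[j] <- TRUE
  list(type = "split",
       feature = j,
       n_pos = n_pos, n_neg = n_neg,
       absent = myc_grow(X, is_pos, absent, used, alpha),
       present = myc_grow(X, is_pos, present, used, alpha))
}

#' Predict with a MyC tree
#'
#' Follows the presence/absence branch of each split down to a leaf and
#' returns the leaf label.
#'
#' @param tree a [myc_train()] result.
#' @param X binary feature matrix with the same columns the tree was trained
#'   on (a single feature vector is also accepted).
#' @return Character vector of predicted labels.
#' @export
myc_predict <- function(tree, X) {
  stopifnot(inherits(tree, "myc_tree"))
  X <- myc_coerce_matrix(tree, X)
  myc_walk(tree$root, X, seq_len(nrow(X)),
           out = character(nrow(X)), what = "label")
}

# Laplace-smoothed P(positive) from leaf class frequencies.
myc_prob <- function(tree, X) {
  X <- myc_coerce_matrix(tree, X)
  myc_walk(tree$root, X, seq_len(nrow(X)), out = numeric(nrow(X)),
           what = "prob")
}

myc_coerce_matrix <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != tree$n_features) {
    stop_badarg("feature vector has ", ncol(X), " columns; tree expects ",
                tree$n_features)
  }
  X
}

myc_walk <- function(node, X, rows, out, what) {
  if (!length(rows)) return(out)
  if (node$type == "leaf") {
    out[rows] <- if (what == "label") {
      node$label
    } else {
      (node$n_pos + 1) / (node$n_pos + node$n_neg + 2)
    }
    return(out)
  }
  pres <- X[rows, node$feature] == 1L
  out <- myc_walk(node$absent, X, rows[!pres], out, what)
  myc_walk(node$present, X, rows[pres], out, what)
}

myc_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(myc_depth(node$absent), myc_depth(node$present))
}

#' @export
print.myc_tree <- function(x, ...) {
  n_leaves <- local({
    count <- function(node) {
      if (node$type == "leaf") 1L else count(node$absent) + count(node$present)
    }
    count(x$root)
  })
  cat(sprintf("<myc_tree: %d features available, %d leaves, depth %d, alpha = %g>\n",
              x$n_features, n_leaves, myc_depth(x$root), x$alpha))
  invisible(x)
}
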