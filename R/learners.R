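#' Base learner specification
#'
#' The pipeline treats base classifiers as pluggable behind a common
#' contract: train on a binary feature matrix, predict a label (and a class
#' probability) per row. Four families are recognized:
#'
#' * `myc` -- the in-package chi-square decision tree ([myc_train()]);
#'   hyperparameter `alpha` (default 0.05).
#' * `decision_tree` -- a CART tree via \pkg{rpart} (grown deep:
#'   `minsplit = 2`, `cp = 1e-4`, no cross-validation pruning).
#' * `linear_margin` -- a soft-margin SVM with linear kernel via
#'   \pkg{e1071}; hyperparameter `c` (default 4).
#' * `rule_inducer` -- a small greedy sequential-covering rule list
#'   implemented here: rules are conjunctions of token-presence conditions
#'   grown to maximize Laplace-corrected precision for the positive class.
#'
#' @param family one of `"myc"`, `"decision_tree"`, `"rule_inducer"`,
#'   `"linear_margin"`.
#' @param ... family-specific hyperparameters overriding the defaults above.
#' @return An object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(family = c("myc", "decision_tree",
                                         "rule_inducer", "linear_margin"),
                              ...) {
  family <- tryCatch(match.arg(family),
                     error = function(e) {
                       stop_badarg("unknown base learner family: '",
                                   family[1], "'")
                     })
  defaults <- switch(family,
    myc = list(alpha = 0.05),
    decision_tree = list(minsplit = 2, cp = 1e-4),
    rule_inducer = list(max_conditions = 3),
    linear_margin = list(c = 4)
  )
  hyper <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown)) {
    stop_badarg("unknown hyperparameter(s) for family '", family, "': ",
                paste(unknown, collapse = ", "))
  }
  structure(list(family = family, hyperparameters = hyper),
            class = "base_learner_spec")
}

#' Train a base learner
#'
#' Dispatches on the spec's family and wraps the result in the common
#' `trained_model` contract used by [predict.trained_model()]. Degenerate
#' inputs (no features, or a single class) yield a constant majority-class
#' model, with ties resolved toward the positive class.
#'
#' @param spec a [base_learner_spec()].
#' @param X binary feature matrix.
#' @param y character labels (`"positive"`/`"negative"`).
#' @return An object of class `trained_model`.
#' @export
train_base <- function(spec, X, y) {
  stopifnot(inherits(spec, "base_learner_spec"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop_badarg("at least one training example required")
  if (!all(y %in% c("positive", "negative"))) {
    stop_badarg("labels must be 'positive' or 'negative'")
  }
  n_pos <- sum(y == "positive")
  n_neg <- sum(y == "negative")
  if (ncol(X) == 0L || n_pos == 0L || n_neg == 0L) {
    fit <- list(kind = "constant",
                label = if (n_pos >= n_neg) "positive" else "negative",
                p_pos = (n_pos + 1) / (n_pos + n_neg + 2))
  } else {
    fit <- switch(spec$family,
      myc = myc_train(X, y, alpha = spec$hyperparameters$alpha),
      decision_tree = fit_rpart(X, y, spec$hyperparameters),
      linear_margin = fit_svm(X, y, spec$hyperparameters),
      rule_inducer = fit_rules(X, y, spec$hyperparameters)
    )
  }
  structure(list(family = spec$family, spec = spec, fit = fit,
                 n_features = ncol(X)),
            class = "trained_model")
}

#' Predict from a trained base model
#'
#' @param object a `trained_model`.
#' @param X binary feature matrix (or single feature vector).
#' @param type `"label"` for hard class predictions, `"prob"` for the
#'   model's estimate of P(positive).
#' @param ... unused.
#' @return Character vector of labels, or numeric vector of probabilities.
#' @export
predict.trained_model <- function(object, X, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != object$n_features) {
    stop_badarg("feature matrix has ", ncol(X), " columns; model expects ",
                object$n_features)
  }
  fit <- object$fit
  if (is.list(fit) && identical(fit$kind, "constant")) {
    return(switch(type,
                  label = rep(fit$label, nrow(X)),
                  prob = rep(fit$p_pos, nrow(X))))
  }
  switch(object$family,
    myc = if (type == "label") myc_predict(fit, X) else myc_prob(fit, X),
    decision_tree = predict_rpart(fit, X, type),
    linear_margin = predict_svm(fit, X, type),
    rule_inducer = predict_rules(fit, X, type)
  )
}

#' @export
print.trained_model <- function(x, ...) {
  kind <- if (is.list(x$fit) && identical(x$fit$kind, "constant")) {
    paste0("constant '", x$fit$label, "'")
  } else {
    x$family
  }
  cat(sprintf("<trained_model: %s over %d features>\n", kind, x$n_features))
  invisible(x)
}

# --- rpart backend -----------------------------------------------------------

fit_rpart <- function(X, y, hyper) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.label <- factor(y, levels = c("negative", "positive"))
  rpart::rpart(
    .label ~ ., data = df, method = "class",
    control = rpart::rpart.control(minsplit = hyper$minsplit, cp = hyper$cp,
                                   xval = 0)
  )
}

predict_rpart <- function(fit, X, type) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  if (type == "label") {
    as.character(predict(fit, df, type = "class"))
  } else {
    p <- predict(fit, df, type = "prob")
    if ("positive" %in% colnames(p)) unname(p[, "positive"]) else
      rep(0, nrow(df))
  }
}

# --- linear-margin (SVM) backend --------------------------------------------

fit_svm <- function(X, y, hyper) {
  yf <- factor(y, levels = c("negative", "positive"))
  fit <- tryCatch(
    e1071::svm(x = X, y = yf, kernel = "linear", cost = hyper$c,
               scale = FALSE, probability = TRUE),
    error = function(e) NULL, warning = function(w) NULL
  )
  # Platt scaling needs internal CV; on tiny inputs fall back to decision
  # values mapped through a logistic.
  if (is.null(fit)) {
    fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = hyper$c,
                      scale = FALSE, probability = FALSE)
  }
  fit
}

predict_svm <- function(fit, X, type) {
  pr <- predict(fit, X, probability = TRUE, decision.values = TRUE)
  if (type == "label") return(as.character(pr))
  probs <- attr(pr, "probabilities")
  if (!is.null(probs) && "positive" %in% colnames(probs)) {
    return(unname(probs[, "positive"]))
  }
  dec <- attr(pr, "decision.values")
  sgn <- if (grepl("^positive", colnames(dec)[1])) 1 else -1
  stats::plogis(sgn * dec[, 1])
}

# --- greedy sequential-covering rule list -----------------------------------

# Rules are conjunctions of presence conditions predicting "positive"; each
# rule is grown greedily on the yet-uncovered examples by adding the
# condition that maximizes Laplace precision, then the covered examples are
# removed. A default leaf predicts the majority of what remains.
fit_rules <- function(X, y, hyper) {
  remaining <- seq_len(nrow(X))
  is_pos <- y == "positive"
  rules <- list()
  laplace <- function(rows) (sum(is_pos[rows]) + 1) / (length(rows) + 2)
  repeat {
    if (!sum(is_pos[remaining])) break
    conds <- integer()
    rows <- remaining
    repeat {
      if (length(conds) >= hyper$max_conditions) break
      cand <- setdiff(seq_len(ncol(X)), conds)
      prec <- vapply(cand, function(j) {
        covered <- rows[X[rows, j] == 1L]
        if (!length(covered)) -Inf else laplace(covered)
      }, numeric(1))
      best <- cand[which.max(prec)]
      if (!is.finite(max(prec)) || max(prec) <= laplace(rows)) break
      conds <- c(conds, best)
      rows <- rows[X[rows, best] == 1L]
      if (all(is_pos[rows])) break
    }
    if (!length(conds)) break
    covered_pos <- sum(is_pos[rows])
    if (covered_pos < length(rows) - covered_pos) break # not positive-majority
    rules[[length(rules) + 1L]] <- list(conditions = conds,
                                        n_pos = covered_pos,
                                        n_neg = length(rows) - covered_pos)
    remaining <- setdiff(remaining, rows)
    if (!length(remaining)) break
  }
  n_pos_rem <- sum(is_pos[remaining])
  n_neg_rem <- length(remaining) - n_pos_rem
  list(kind = "rules", rules = rules,
       default_label = if (n_pos_rem >= n_neg_rem) "positive" else "negative",
       default_p = (n_pos_rem + 1) / (length(remaining) + 2))
}

predict_rules <- function(fit, X, type) {
  lab <- rep(fit$default_label, nrow(X))
  p <- rep(fit$default_p, nrow(X))
  unmatched <- rep(TRUE, nrow(X))
  for (rule in fit$rules) {
    hit <- unmatched &
      rowSums(X[, rule$conditions, drop = FALSE] == 1L) == length(rule$conditions)
    lab[hit] <- "positive"
    p[hit] <- (rule$n_pos + 1) / (rule$n_pos + rule$n_neg + 2)
    unmatched <- unmatched & !hit
  }
  if (type == "label") lab else p
}
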