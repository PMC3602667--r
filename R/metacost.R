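#' Misclassification cost matrix
#'
#' Two-class cost matrix indexed as `cost[predicted, actual]`. Correct
#' predictions cost 0. The swept parameter is the cost of a false negative
#' (`cost_fn = cost("negative", "positive")`); the false-positive cost is
#' conventionally fixed at 1.
#'
#' @param cost_fn cost of predicting negative for a true positive.
#' @param cost_fp cost of predicting positive for a true negative.
#' @return A 2x2 matrix of class `cost_matrix` with dimnames
#'   `predicted` x `actual` over `positive`/`negative`.
#' @export
cost_matrix <- function(cost_fn = 1, cost_fp = 1) {
  if (cost_fn < 0 || cost_fp < 0) stop_badarg("costs must be non-negative")
  m <- matrix(0, 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  m["negative", "positive"] <- cost_fn
  m["positive", "negative"] <- cost_fp
  structure(m, class = c("cost_matrix", "matrix"))
}

#' The default misclassification-cost grid
#'
#' Nine cost values spanning 1 to 1000: 1, 10, 25, 50, 100, 200, 400, 800,
#' 1000.
#'
#' @return Numeric vector of length 9.
#' @export
cost_grid <- function() c(1, 10, 25, 50, 100, 200, 400, 800, 1000)

#' Relabel by minimum conditional risk
#'
#' Given an estimate of P(positive | x), returns the class whose prediction
#' minimizes the expected misclassification cost
#' `R(i) = sum_j P(j | x) * cost(i, j)`. Ties resolve toward the positive
#' class.
#'
#' @param p_positive numeric vector of probabilities in `[0, 1]`.
#' @param cost a [cost_matrix()].
#' @return Character vector of labels.
#' @export
#' @examples
#' conditional_risk_relabel(0.3, cost_matrix(cost_fn = 10)) # "positive"
conditional_risk_relabel <- function(p_positive, cost) {
  stopifnot(inherits(cost, "cost_matrix"))
  if (any(p_positive < 0 | p_positive > 1)) {
    stop_badarg("p_positive must be in [0, 1]")
  }
  risk_pos <- (1 - p_positive) * cost["positive", "negative"]
  risk_neg <- p_positive * cost["negative", "positive"]
  ifelse(risk_pos <= risk_neg, "positive", "negative")
}

#' Cost-sensitive meta-learning with MetaCost
#'
#' Makes any base learner cost-sensitive without modifying it:
#'
#' 1. draw `n_resamples` bootstrap samples (with replacement, same size as
#'    the training set) and train the base learner on each;
#' 2. estimate P(positive | x) for every original training example from the
#'    ensemble -- by default the mean of the per-model class-probability
#'    estimates, or the fraction of models voting positive when
#'    `vote = "hard"`;
#' 3. relabel every training example to the class minimizing conditional
#'    risk under the cost matrix ([conditional_risk_relabel()]);
#' 4. train a final base model on the relabeled data.
#'
#' Probability estimates use all ensemble members for every example (no
#' out-of-bag exclusion). With hard votes and a deterministic base learner
#' the risk estimates collapse onto multiples of `1/n_resamples`; examples
#' whose ensemble is unanimous then sit at exactly 0 or 1 and can never be
#' swayed by any finite cost, which is why smoothed probabilities are the
#' default.
#'
#' @param spec a [base_learner_spec()].
#' @param X binary feature matrix.
#' @param y character labels.
#' @param cost a [cost_matrix()].
#' @param n_resamples number of bootstrap models (default 10).
#' @param vote `"prob"` (default) or `"hard"`.
#' @param seed optional seed making resampling reproducible.
#' @return An object of class `metacost_model` (also a `trained_model`):
#'   the final model plus the per-example probability estimates
#'   (`$p_positive`), the relabeled training labels (`$relabeled`), and the
#'   originals (`$original`).
#' @export
metacost_train <- function(spec, X, y, cost, n_resamples = 10,
                           vote = c("prob", "hard"), seed = NULL) {
  stopifnot(inherits(spec, "base_learner_spec"), inherits(cost, "cost_matrix"))
  vote <- match.arg(vote)
  if (n_resamples < 1) stop_badarg("n_resamples must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X)
  p_mat <- with_seed_maybe(seed, {
    vapply(seq_len(n_resamples), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- tryCatch(
        train_base(spec, X[idx, , drop = FALSE], y[idx]),
        error = function(e) {
          stop("base training failed on resample ", r, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      if (vote == "hard") {
        as.numeric(predict(m, X, type = "label") == "positive")
      } else {
        predict(m, X, type = "prob")
      }
    }, numeric(n))
  })
  p_positive <- rowMeans(matrix(p_mat, nrow = n))
  relabeled <- conditional_risk_relabel(p_positive, cost)
  final <- train_base(spec, X, relabeled)
  structure(
    list(model = final, p_positive = p_positive, relabeled = relabeled,
         original = y, cost = cost, n_resamples = n_resamples, vote = vote,
         n_features = ncol(X)),
    class = c("metacost_model", "trained_model")
  )
}

#' @export
predict.metacost_model <- function(object, X, type = c("label", "prob"), ...) {
  predict(object$model, X, type = match.arg(type))
}

#' @export
print.metacost_model <- function(x, ...) {
  cat(sprintf(
    "<metacost_model: %s base, %d resamples (%s votes), cost_fn = %g; %d/%d examples relabeled>\n",
    x$model$family, x$n_resamples, x$vote, x$cost["negative", "positive"],
    sum(x$relabeled != x$original), length(x$original)
  ))
  invisible(x)
}
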