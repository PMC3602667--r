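#' Filter and tokenize every entry of a corpus once
#'
#' Applies [apply_assertion_filter()] and [tokenize()] to every entry and
#' returns the token lists keyed by patient and entry id. The assertion
#' filter does not depend on folds, sampling, or learners, so one map can
#' back any number of [run_experiment()] calls on the same corpus and
#' lexicon.
#'
#' @param corpus an `emr_corpus`.
#' @param lexicon a [keyword_lexicon()].
#' @return Named list of token vectors.
#' @export
corpus_token_map <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "emr_corpus"),
            inherits(lexicon, "keyword_lexicon"))
  texts <- unlist(lapply(corpus$patients, function(p) p$entries$text))
  keys <- unlist(lapply(corpus$patients, function(p) {
    entry_key(p$patient_id, p$entries$entry_id)
  }))
  filtered <- vapply(texts, apply_assertion_filter, character(1),
                     lexicon = lexicon, USE.NAMES = FALSE)
  token_map <- tokenize_many(filtered)
  names(token_map) <- keys
  token_map
}

#' Subject-level fold assignment
#'
#' Partitions *patients* (not entries) into `k` folds whose sizes differ by
#' at most one, so that no patient's entries can ever span the training and
#' test side of a split.
#'
#' @param corpus an `emr_corpus`.
#' @param k number of folds (default 5).
#' @param seed optional seed for the random shuffle.
#' @return A data frame of class `fold_assignment` with columns
#'   `patient_id` and `fold`.
#' @export
make_folds <- function(corpus, k = 5, seed = NULL) {
  stopifnot(inherits(corpus, "emr_corpus"))
  if (k < 2) stop_badarg("k must be at least 2")
  ids <- patient_ids(corpus)
  if (length(ids) < k) {
    stop_badarg("corpus has ", length(ids), " patients; need at least k = ", k)
  }
  perm <- with_seed_maybe(seed, sample(ids))
  out <- data.frame(patient_id = perm,
                    fold = rep(seq_len(k), length.out = length(perm)),
                    stringsAsFactors = FALSE)
  structure(out[order(out$patient_id), , drop = FALSE],
            class = c("fold_assignment", "data.frame"), k = k, seed = seed)
}

#' Patient-level confusion counts
#'
#' @param tp,fp,tn,fn non-negative patient counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop_badarg("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: tp %d, fp %d, tn %d, fn %d>\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity (true-positive recognition rate)
#'
#' `tp / (tp + fn)`, computed at the patient level.
#'
#' @param counts a [confusion_counts()].
#' @return Numeric scalar.
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tp + counts$fn
  if (denom == 0) stop_badarg("sensitivity undefined: no positive patients")
  counts$tp / denom
}

#' Specificity (true-negative recognition rate)
#'
#' `tn / (tn + fp)`, computed at the patient level.
#'
#' @param counts a [confusion_counts()].
#' @return Numeric scalar.
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$tn + counts$fp
  if (denom == 0) stop_badarg("specificity undefined: no negative patients")
  counts$tn / denom
}

#' Classify a patient from all of its entries
#'
#' Every entry -- seen, implicit, and unseen alike -- is assertion-filtered,
#' tokenized, vectorized against the training fold's vocabulary, and
#' classified; the patient is predicted positive iff at least one entry is
#' predicted positive. This any-entry-positive aggregation mirrors the
#' labeling rule: a patient is a case if evidence appears in any entry.
#'
#' @param model a `trained_model` (or `metacost_model`).
#' @param patient a [patient_record()].
#' @param vocab the training fold's `feature_vocabulary`.
#' @param lexicon a [keyword_lexicon()].
#' @return `"positive"` or `"negative"`.
#' @export
classify_patient <- function(model, patient, vocab, lexicon) {
  toks <- tokenize_many(vapply(patient$entries$text, apply_assertion_filter,
                               character(1), lexicon = lexicon,
                               USE.NAMES = FALSE))
  X <- vectorize_examples(toks, vocab)
  if (any(predict(model, X, type = "label") == "positive")) "positive"
  else "negative"
}

#' Run one cross-validated case-identification experiment
#'
#' For each fold: the texts of all entries are assertion-filtered and
#' tokenized; the training patients' entries are assembled into examples
#' (with or without set expansion); the chi-square vocabulary is built on
#' the assembled training fold only; the plan's under-/over-sampling then
#' reshapes the class balance of the training examples; the base learner is
#' trained (wrapped in MetaCost when a cost matrix is supplied); and every
#' test-fold patient is classified from all of its entries via
#' [classify_patient()]. Confusion counts are pooled over folds
#' (micro-average).
#'
#' @param corpus an `emr_corpus`.
#' @param plan a [sampling_plan()].
#' @param learner a [base_learner_spec()].
#' @param lexicon a [keyword_lexicon()].
#' @param cost optional [cost_matrix()]; when given, training is wrapped in
#'   [metacost_train()].
#' @param k fold count used when `folds` is not supplied.
#' @param folds optional precomputed [make_folds()] assignment (lets several
#'   configurations share identical folds).
#' @param alpha feature-selection threshold.
#' @param n_resamples MetaCost bootstrap count.
#' @param vote MetaCost vote type, see [metacost_train()].
#' @param seed optional seed controlling folds, sampling, and resampling.
#' @param keep_models keep each fold's model and vocabulary in the result.
#' @param token_map optional precomputed [corpus_token_map()]; the filter is
#'   fold- and configuration-independent, so sweeps over many
#'   configurations of one corpus can share it.
#' @return An object of class `eval_result`: per-fold and pooled
#'   [confusion_counts()], `sensitivity`, `specificity`, the mean realized
#'   training imbalance ratio, per-patient predictions, and the
#'   configuration that produced them.
#' @export
run_experiment <- function(corpus, plan, learner, lexicon, cost = NULL,
                           k = 5, folds = NULL, alpha = 0.05,
                           n_resamples = 10, vote = c("prob", "hard"),
                           seed = NULL, keep_models = FALSE,
                           token_map = NULL) {
  stopifnot(inherits(corpus, "emr_corpus"), inherits(plan, "sampling_plan"),
            inherits(learner, "base_learner_spec"),
            inherits(lexicon, "keyword_lexicon"))
  vote <- match.arg(vote)
  if (!is.null(cost)) stopifnot(inherits(cost, "cost_matrix"))
  with_seed_maybe(seed, {
    if (is.null(folds)) folds <- make_folds(corpus, k = k)
    k <- attr(folds, "k")

    # The filter is fold-independent: tokenize every entry once up front.
    if (is.null(token_map)) token_map <- corpus_token_map(corpus, lexicon)

    fold_of <- stats::setNames(folds$fold, folds$patient_id)
    per_fold <- vector("list", k)
    predictions <- vector("list", k)
    models <- if (keep_models) vector("list", k) else NULL

    for (f in seq_len(k)) {
      res <- tryCatch(
        run_fold(corpus, fold_of, f, plan, learner, lexicon, cost,
                 alpha, n_resamples, vote, token_map, keep_models),
        error = function(e) {
          stop("fold ", f, ": ", conditionMessage(e), call. = FALSE)
        }
      )
      per_fold[[f]] <- res$row
      predictions[[f]] <- res$predictions
      if (keep_models) models[[f]] <- res$model_bundle
    }

    per_fold <- do.call(rbind, per_fold)
    pooled <- confusion_counts(tp = sum(per_fold$tp), fp = sum(per_fold$fp),
                               tn = sum(per_fold$tn), fn = sum(per_fold$fn))
    structure(
      list(per_fold = per_fold, pooled = pooled,
           sensitivity = sensitivity(pooled),
           specificity = specificity(pooled),
           imbalance_ratio = mean(per_fold$imbalance_ratio),
           predictions = do.call(rbind, predictions),
           plan = plan, learner = learner, cost = cost, k = k,
           alpha = alpha, models = models),
      class = "eval_result"
    )
  })
}

run_fold <- function(corpus, fold_of, f, plan, learner, lexicon, cost,
                     alpha, n_resamples, vote, token_map, keep_models) {
  in_test <- fold_of[patient_ids(corpus)] == f
  train_patients <- corpus$patients[!in_test]
  test_patients <- corpus$patients[in_test]

  # Vocabulary is screened on the assembled training fold; sampling then
  # reshapes the class balance without changing the feature space.
  ex0 <- assemble_training_set(train_patients, plan$use_set_expansion)
  vocab <- build_vocabulary(token_map[entry_key(ex0$patient_id, ex0$entry_id)],
                            ex0$label, alpha = alpha)
  ex <- apply_sampling_plan(ex0, plan)
  toks <- token_map[entry_key(ex$patient_id, ex$entry_id)]
  X <- vectorize_examples(toks, vocab)
  model <- if (is.null(cost)) {
    train_base(learner, X, ex$label)
  } else {
    metacost_train(learner, X, ex$label, cost, n_resamples = n_resamples,
                   vote = vote)
  }

  # Batch-classify all test entries at once, then aggregate per patient.
  test_keys <- lapply(test_patients, function(p) {
    entry_key(p$patient_id, p$entries$entry_id)
  })
  all_toks <- token_map[unlist(test_keys)]
  labs <- predict(model, vectorize_examples(all_toks, vocab), type = "label")
  idx <- factor(rep(seq_along(test_patients), lengths(test_keys)),
                levels = seq_along(test_patients))
  pred_pos <- vapply(split(labs == "positive", idx), any, logical(1))
  gold <- vapply(test_patients, `[[`, character(1), "gold_label")
  pred <- ifelse(pred_pos, "positive", "negative")

  row <- data.frame(
    fold = f,
    tp = sum(pred == "positive" & gold == "positive"),
    fp = sum(pred == "positive" & gold == "negative"),
    tn = sum(pred == "negative" & gold == "negative"),
    fn = sum(pred == "negative" & gold == "positive"),
    imbalance_ratio = imbalance_ratio(ex)
  )
  list(
    row = row,
    predictions = data.frame(
      patient_id = vapply(test_patients, `[[`, character(1), "patient_id"),
      gold = gold, predicted = pred, fold = f, stringsAsFactors = FALSE
    ),
    model_bundle = if (keep_models) list(model = model, vocab = vocab)
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result: sensitivity %.3f, specificity %.3f over %d folds (imbalance ratio %.1f)>\n",
    x$sensitivity, x$specificity, x$k, x$imbalance_ratio
  ))
  invisible(x)
}

#' Cohen's kappa for two annotators
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' marginal-product expected agreement, plus a large-sample 95% confidence
#' interval `kappa +/- 1.96 * se`, where
#' `se = sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param agreement_table 2x2 matrix of counts; rows are annotator 1's
#'   labels, columns annotator 2's.
#' @return List with `kappa`, `ci` (length-2 vector), `p_observed`,
#'   `p_expected`, `n`.
#' @export
#' @examples
#' cohen_kappa(matrix(c(40, 5, 10, 45), 2, 2)) # kappa 0.70
cohen_kappa <- function(agreement_table) {
  m <- as.matrix(agreement_table)
  stopifnot(nrow(m) == 2, ncol(m) == 2, all(m >= 0))
  n <- sum(m)
  if (n <= 0) stop_badarg("agreement table total must be positive")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) stop_badarg("kappa undefined: expected agreement is 1")
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  list(kappa = kappa, ci = c(kappa - 1.96 * se, kappa + 1.96 * se),
       p_observed = p_o, p_expected = p_e, n = n)
}

#' Categorize false-negative patients
#'
#' Assigns each missed positive patient to exactly one of four error
#' categories by a fixed decision cascade, using the ground-truth sidecar
#' written by the synthetic generator:
#'
#' 1. `labeling_error` -- the sidecar marks the gold label itself as wrong;
#' 2. `evidence_removed_by_filter` -- the evidence token is present in the
#'    evidence entry before filtering but absent after;
#' 3. `spelling_variant` -- the sidecar marks the evidence surface form as a
#'    misspelled variant;
#' 4. `evidence_not_in_model` -- everything else: the evidence was intact
#'    but the learned model did not pick it up.
#'
#' @param fn_patients list of [patient_record()]s predicted negative despite
#'   a positive gold label.
#' @param lexicon the [keyword_lexicon()] used by the pipeline.
#' @param truth ground-truth sidecar data frame (see [generate_corpus()]).
#' @param vocab optional `feature_vocabulary` of the model, recorded for
#'   reference.
#' @return An object of class `error_breakdown`: named counts and
#'   percentages over the four categories.
#' @export
categorize_false_negatives <- function(fn_patients, lexicon, truth,
                                       vocab = NULL) {
  categories <- c("evidence_not_in_model", "evidence_removed_by_filter",
                  "spelling_variant", "labeling_error")
  counts <- stats::setNames(integer(4), categories)
  for (p in fn_patients) {
    tr <- truth[truth$patient_id == p$patient_id, , drop = FALSE]
    if (nrow(tr) != 1L) {
      stop_badarg("no ground-truth record for patient '", p$patient_id, "'")
    }
    cat_p <- if (isTRUE(tr$label_is_error)) {
      "labeling_error"
    } else {
      ev_tok <- tr$evidence_token
      ev_entry <- p$entries[p$entries$entry_id == tr$evidence_entry_id, ,
                            drop = FALSE]
      pre <- if (nrow(ev_entry)) tokenize(tolower(ev_entry$text)) else character()
      post <- if (nrow(ev_entry)) {
        tokenize(apply_assertion_filter(ev_entry$text, lexicon))
      } else character()
      if (!is.na(ev_tok) && ev_tok %in% pre && !(ev_tok %in% post)) {
        "evidence_removed_by_filter"
      } else if (isTRUE(tr$evidence_misspelled)) {
        "spelling_variant"
      } else {
        "evidence_not_in_model"
      }
    }
    counts[cat_p] <- counts[cat_p] + 1L
  }
  total <- sum(counts)
  structure(
    list(counts = counts,
         percentages = if (total > 0) 100 * counts / total else counts * 0,
         n = total),
    class = "error_breakdown"
  )
}

#' @export
print.error_breakdown <- function(x, ...) {
  cat(sprintf("Error analysis of %d false negatives\n", x$n))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-28s %4d (%.0f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  }
  invisible(x)
}
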