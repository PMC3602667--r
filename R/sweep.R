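#' Sweep a sampling percentage or cost grid over one corpus
#'
#' Re-runs the cross-validated experiment at every grid point, holding the
#' fold assignment fixed across the grid and across learners so that rows
#' are comparable. Three modes:
#'
#' * `"undersample"` -- grid of under-sampling percentages (default 0-100 in
#'   steps of 10; the no-expansion grid conventionally stops at 90 because
#'   100% would delete every negative example);
#' * `"oversample"` -- grid of positive-entry duplication counts (default
#'   0-10);
#' * `"cost"` -- the nine-step misclassification-cost grid [cost_grid()],
#'   training through [metacost_train()].
#'
#' @param corpus an `emr_corpus`.
#' @param mode one of `"undersample"`, `"oversample"`, `"cost"`.
#' @param learners named list of [base_learner_spec()]s (a single spec is
#'   also accepted).
#' @param lexicon a [keyword_lexicon()].
#' @param use_set_expansion logical, applied to every grid point.
#' @param grid optional numeric grid overriding the mode's default.
#' @param k fold count.
#' @param seed optional seed (folds, sampling, resampling).
#' @param ... further arguments passed to [run_experiment()].
#' @return Data frame shaped like the published sweep tables: one row per
#'   grid point with sensitivity/specificity per learner and the realized
#'   (display-rounded) imbalance ratio.
#' @export
run_sweep <- function(corpus, mode = c("undersample", "oversample", "cost"),
                      learners, lexicon, use_set_expansion = TRUE,
                      grid = NULL, k = 5, seed = NULL, ...) {
  mode <- match.arg(mode)
  if (inherits(learners, "base_learner_spec")) learners <- list(learners)
  if (is.null(names(learners)) || any(!nzchar(names(learners)))) {
    names(learners) <- vapply(learners, `[[`, character(1), "family")
  }
  grid <- grid %||% switch(mode,
    undersample = seq(0, if (use_set_expansion) 100 else 90, by = 10),
    oversample = 0:10,
    cost = cost_grid()
  )
  with_seed_maybe(seed, {
    folds <- make_folds(corpus, k = k)
    token_map <- corpus_token_map(corpus, lexicon)
    rows <- lapply(grid, function(g) {
      plan <- switch(mode,
        undersample = sampling_plan(use_set_expansion, undersample_pct = g),
        oversample = sampling_plan(use_set_expansion,
                                   oversample_duplications = g),
        cost = sampling_plan(use_set_expansion)
      )
      cost <- if (mode == "cost") cost_matrix(cost_fn = g) else NULL
      row <- list(value = g)
      ratio <- NA_real_
      for (nm in names(learners)) {
        res <- run_experiment(corpus, plan, learners[[nm]], lexicon,
                              cost = cost, folds = folds,
                              token_map = token_map, ...)
        row[[paste0(nm, "_sens")]] <- res$sensitivity
        row[[paste0(nm, "_spec")]] <- res$specificity
        ratio <- res$imbalance_ratio
      }
      row$imbalance_ratio <- format_imbalance_ratio(ratio)
      as.data.frame(row)
    })
    out <- do.call(rbind, rows)
    names(out)[1] <- switch(mode, undersample = "undersample_pct",
                            oversample = "duplications", cost = "cost_fn")
    attr(out, "mode") <- mode
    out
  })
}

#' Write a sweep table as tab-separated text
#'
#' @param table data frame from [run_sweep()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
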