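#' Read a pipeline configuration file
#'
#' YAML configuration tying the modules into a reproducible experiment.
#' Recognized keys (all optional unless noted):
#'
#' * `corpus` -- path to a JSON-lines corpus file, or
#' * `preset` -- a [shape_preset()] name plus optional `scale`; exactly one
#'   of `corpus`/`preset` must be given;
#' * `lexicon` -- list of `negation`/`speculation`/`alternatives` keyword
#'   file paths (defaults to the shipped Dutch lexicon);
#' * `folds`, `seed`, `alpha`;
#' * `plan` -- `use_set_expansion`, `undersample_pct`,
#'   `oversample_duplications`;
#' * `learner` -- `family` plus hyperparameters;
#' * `cost_fn`, `n_resamples` -- enable MetaCost for `evaluate`;
#' * `output_dir` (default `"."`).
#'
#' @param path YAML file path.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_badarg("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param config a raw named list with the keys above (useful for building
#'   configurations programmatically).
#' @export
as_pipeline_config <- function(config) {
  has_corpus <- !is.null(config$corpus)
  has_preset <- !is.null(config$preset)
  if (has_corpus == has_preset) {
    stop_badarg("exactly one corpus source required: set 'corpus' or 'preset'")
  }
  config$folds <- config$folds %||% 5
  config$alpha <- config$alpha %||% 0.05
  config$n_resamples <- config$n_resamples %||% 10
  config$output_dir <- config$output_dir %||% "."
  structure(config, class = "pipeline_config")
}

config_lexicon <- function(config) {
  if (is.null(config$lexicon)) return(default_lexicon())
  keyword_lexicon(
    negation = read_keyword_file(config$lexicon$negation),
    speculation = read_keyword_file(config$lexicon$speculation),
    alternatives = read_keyword_file(config$lexicon$alternatives)
  )
}

config_corpus <- function(config) {
  if (!is.null(config$corpus)) return(read_corpus(config$corpus))
  cfg <- shape_preset(config$preset, scale = config$scale %||% 1,
                      seed = config$seed)
  generate_corpus(cfg)$corpus
}

config_plan <- function(config) {
  p <- config$plan %||% list()
  sampling_plan(
    use_set_expansion = p$use_set_expansion %||% TRUE,
    undersample_pct = p$undersample_pct %||% 0,
    oversample_duplications = p$oversample_duplications %||% 0,
    seed = p$seed
  )
}

config_learner <- function(config) {
  l <- config$learner %||% list(family = "myc")
  do.call(base_learner_spec, c(list(family = l$family %||% "myc"),
                               l[setdiff(names(l), "family")]))
}

write_manifest <- function(config, out_dir, outputs) {
  manifest <- list(
    package = "casefinder",
    version = as.character(utils::packageVersion("casefinder")),
    r_version = R.version.string,
    config = unclass(config),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Pipeline commands
#'
#' Thin command wrappers used by the `casefinder` command-line script
#' (`inst/cli/casefinder`); each writes its outputs plus a `manifest.json`
#' (configuration, seeds, package version) sufficient to reproduce the run
#' into the configured output directory.
#'
#' * `cmd_simulate()` generates a synthetic corpus (`corpus.jsonl`) and its
#'   ground-truth sidecar (`truth.jsonl`) from a preset.
#' * `cmd_evaluate()` runs one cross-validated configuration and writes
#'   `evaluation.tsv` (pooled and per-fold counts and metrics).
#' * `cmd_sweep()` runs an under-sampling, over-sampling, or cost sweep and
#'   writes `sweep_<mode>.tsv` shaped like the published tables.
#'
#' @param config a `pipeline_config` (see [read_pipeline_config()]).
#' @param mode sweep mode for `cmd_sweep`.
#' @return The main output path, invisibly.
#' @export
cmd_simulate <- function(config) {
  config <- as_pipeline_config(unclass(config))
  if (is.null(config$preset)) stop_badarg("simulate requires a 'preset'")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- shape_preset(config$preset, scale = config$scale %||% 1,
                      seed = config$seed)
  sim <- generate_corpus(cfg)
  corpus_path <- file.path(config$output_dir, "corpus.jsonl")
  truth_path <- file.path(config$output_dir, "truth.jsonl")
  write_corpus(sim$corpus, corpus_path)
  write_truth(sim$truth, truth_path)
  write_manifest(config, config$output_dir, c(corpus_path, truth_path))
  message("wrote ", corpus_path, " and ", truth_path)
  invisible(corpus_path)
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(config) {
  config <- as_pipeline_config(unclass(config))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- config_corpus(config)
  res <- run_experiment(
    corpus,
    plan = config_plan(config),
    learner = config_learner(config),
    lexicon = config_lexicon(config),
    cost = if (!is.null(config$cost_fn)) cost_matrix(cost_fn = config$cost_fn),
    k = config$folds,
    alpha = config$alpha,
    n_resamples = config$n_resamples,
    seed = config$seed
  )
  out <- file.path(config$output_dir, "evaluation.tsv")
  tab <- res$per_fold
  tab$sensitivity <- tab$tp / (tab$tp + tab$fn)
  tab$specificity <- tab$tn / (tab$tn + tab$fp)
  pooled <- data.frame(fold = NA, tp = res$pooled$tp, fp = res$pooled$fp,
                       tn = res$pooled$tn, fn = res$pooled$fn,
                       imbalance_ratio = res$imbalance_ratio,
                       sensitivity = res$sensitivity,
                       specificity = res$specificity)
  utils::write.table(rbind(tab, pooled), out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(config, config$output_dir, out)
  message(sprintf("sensitivity %.3f, specificity %.3f -> %s",
                  res$sensitivity, res$specificity, out))
  invisible(out)
}

#' @rdname cmd_simulate
#' @export
cmd_sweep <- function(config, mode = c("undersample", "oversample", "cost")) {
  mode <- match.arg(mode)
  config <- as_pipeline_config(unclass(config))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- config_corpus(config)
  plan <- config_plan(config)
  tab <- run_sweep(
    corpus, mode = mode,
    learners = list(config_learner(config)),
    lexicon = config_lexicon(config),
    use_set_expansion = plan$use_set_expansion,
    k = config$folds, seed = config$seed,
    alpha = config$alpha, n_resamples = config$n_resamples
  )
  out <- file.path(config$output_dir, paste0("sweep_", mode, ".tsv"))
  write_sweep_table(tab, out)
  write_manifest(config, config$output_dir, out)
  message("wrote ", out)
  invisible(out)
}
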