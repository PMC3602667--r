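#' Sampling plan for one training configuration
#'
#' Bundles the two imbalance-handling knobs with the set-expansion flag.
#' Under- and over-sampling are the two arms of the modified random sampling
#' strategy and are varied separately, never combined in one plan.
#'
#' @param use_set_expansion include implicit entries of negative patients as
#'   additional negative training examples.
#' @param undersample_pct percentage in `[0, 100]` of the eligible negative
#'   pool to remove (implicit entries when expanding, seen negative entries
#'   otherwise).
#' @param oversample_duplications integer in `[0, 10]`: how many extra copies
#'   of every positive example to add.
#' @param seed optional seed making the random removal reproducible.
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(use_set_expansion = TRUE,
                          undersample_pct = 0,
                          oversample_duplications = 0,
                          seed = NULL) {
  if (undersample_pct < 0 || undersample_pct > 100) {
    stop_badarg("undersample_pct must be in [0, 100]")
  }
  if (oversample_duplications < 0 || oversample_duplications > 10 ||
      oversample_duplications != round(oversample_duplications)) {
    stop_badarg("oversample_duplications must be an integer in [0, 10]")
  }
  if (undersample_pct > 0 && oversample_duplications > 0) {
    stop_badarg("under- and over-sampling are varied separately; ",
                "set at most one of them in a plan")
  }
  structure(list(use_set_expansion = isTRUE(use_set_expansion),
                 undersample_pct = undersample_pct,
                 oversample_duplications = as.integer(oversample_duplications),
                 seed = seed),
            class = "sampling_plan")
}

#' Assemble entry-level training examples from patient records
#'
#' Without set expansion each patient contributes its single seen entry,
#' labeled with the patient's gold label. With set expansion every implicit
#' entry of a negative patient is added as a further negative example.
#' Unseen entries (non-seen entries of positive patients) are never included
#' for training: their evidence status is unknown.
#'
#' @param patients an `emr_corpus` or a list of [patient_record()] objects.
#' @param use_set_expansion logical.
#' @return Data frame of training examples with columns `patient_id`,
#'   `entry_id`, `label`, `provenance` (`seen_pos`, `seen_neg`, `implicit`,
#'   or `duplicate`), and `text`.
#' @export
assemble_training_set <- function(patients, use_set_expansion = TRUE) {
  if (inherits(patients, "emr_corpus")) patients <- patients$patients
  pid <- eid <- lab <- prov <- txt <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    e <- p$entries
    take <- e$role == "seen"
    if (use_set_expansion && p$gold_label == "negative") {
      take <- take | e$role == "implicit"
    }
    e <- e[take, , drop = FALSE]
    pid[[i]] <- rep(p$patient_id, nrow(e))
    eid[[i]] <- e$entry_id
    lab[[i]] <- rep(p$gold_label, nrow(e))
    prov[[i]] <- ifelse(e$role == "seen",
                        if (p$gold_label == "positive") "seen_pos" else "seen_neg",
                        "implicit")
    txt[[i]] <- e$text
  }
  data.frame(
    patient_id = unlist(pid) %||% character(),
    entry_id = unlist(eid) %||% character(),
    label = unlist(lab) %||% character(),
    provenance = unlist(prov) %||% character(),
    text = unlist(txt) %||% character(),
    stringsAsFactors = FALSE
  )
}

#' Randomly remove negative training examples
#'
#' With set expansion, removal draws only from the implicit entries, so every
#' negative patient keeps at least its seen entry; at 100% all implicit
#' entries are gone. Without set expansion, removal draws from the seen
#' negative entries, effectively deleting negative patients from the training
#' set. Positive examples are never removed. The number removed is
#' `pct`% of the eligible pool, rounded half away from zero.
#'
#' @param examples training-example data frame from
#'   [assemble_training_set()].
#' @param pct percentage in `[0, 100]`.
#' @param use_set_expansion must match the flag the examples were assembled
#'   with.
#' @param seed optional seed for the random draw.
#' @return The examples data frame with the sampled rows removed (original
#'   order preserved).
#' @export
undersample <- function(examples, pct, use_set_expansion = TRUE, seed = NULL) {
  if (!is.numeric(pct) || length(pct) != 1L || pct < 0 || pct > 100) {
    stop_badarg("pct must be a percentage in [0, 100]")
  }
  eligible <- if (use_set_expansion) {
    which(examples$provenance == "implicit")
  } else {
    which(examples$provenance == "seen_neg")
  }
  n_remove <- round_half_away(pct / 100 * length(eligible))
  if (n_remove == 0L) return(examples)
  drop <- with_seed_maybe(seed, {
    eligible[sample.int(length(eligible), n_remove)]
  })
  examples[-drop, , drop = FALSE]
}

#' Duplicate positive training examples
#'
#' Appends `duplications` extra copies of every positive example, marked
#' with provenance `"duplicate"`. Deterministic: no randomness is involved.
#' Only seen positive entries exist as training-eligible positives, so
#' duplication acts on those.
#'
#' @param examples training-example data frame.
#' @param duplications integer in `[0, 10]`.
#' @return The augmented data frame.
#' @export
oversample <- function(examples, duplications) {
  if (!is.numeric(duplications) || length(duplications) != 1L ||
      duplications < 0 || duplications > 10 ||
      duplications != round(duplications)) {
    stop_badarg("duplications must be an integer in [0, 10]")
  }
  if (duplications == 0) return(examples)
  pos <- which(examples$label == "positive")
  if (!length(pos)) return(examples)
  dup <- examples[rep(pos, duplications), , drop = FALSE]
  dup$provenance <- "duplicate"
  out <- rbind(examples, dup)
  rownames(out) <- NULL
  out
}

#' Imbalance ratio of a training set
#'
#' Number of negative examples divided by number of positive examples.
#'
#' @param examples training-example data frame.
#' @return The exact quotient.
#' @seealso [format_imbalance_ratio()] for the display convention.
#' @export
imbalance_ratio <- function(examples) {
  n_pos <- sum(examples$label == "positive")
  n_neg <- sum(examples$label == "negative")
  if (n_pos == 0L) stop_badarg("imbalance ratio undefined: no positive examples")
  n_neg / n_pos
}

#' Display convention for imbalance ratios
#'
#' Ratios at or above 1 are rounded (half away from zero) to the nearest
#' integer; ratios below 1 to one decimal, e.g. 42, 16, 1363, 0.5.
#'
#' @param ratio numeric vector of ratios.
#' @return Numeric vector of display values.
#' @export
format_imbalance_ratio <- function(ratio) {
  ifelse(ratio >= 1, round_half_away(ratio), round_half_away(ratio, 1))
}

#' Apply a sampling plan to an assembled training set
#'
#' @param examples training-example data frame.
#' @param plan a [sampling_plan()].
#' @return The resampled data frame.
#' @export
apply_sampling_plan <- function(examples, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  if (plan$undersample_pct > 0) {
    examples <- undersample(examples, plan$undersample_pct,
                            use_set_expansion = plan$use_set_expansion,
                            seed = plan$seed)
  }
  if (plan$oversample_duplications > 0) {
    examples <- oversample(examples, plan$oversample_duplications)
  }
  examples
}
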