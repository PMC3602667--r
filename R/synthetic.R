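#' Default evidence lexicon for synthetic corpora
#'
#' Five hepatobiliary-flavoured evidence tokens, each with one fixed
#' misspelled surface variant (e.g. "levercirrhose" for "levercirrose").
#' Variants are fixed alternative spellings rather than random edits, so a
#' variant form can recur across patients the way real spelling variation
#' does.
#'
#' @return Data frame with columns `token` and `variant`.
#' @export
default_evidence_lexicon <- function() {
  data.frame(
    token = c("cholelithiasis", "levercirrose", "hepatitis",
              "cholecystitis", "cholestase"),
    variant = c("cholelitiasis", "levercirrhose", "hepatitus",
                "colecystitis", "colestase"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic EMR corpus generator
#'
#' Describes a corpus with the statistical structure the pipeline assumes:
#' rare positive patients each carrying exactly one evidence-bearing seen
#' entry, negative patients with one seen and many implicit entries, evidence
#' keywords with fixed spelling variants, and negated/speculative mentions
#' realized through the same pathways the assertion filter removes. Text is
#' synthetic token sequences, not natural prose: the pipeline is purely
#' lexical, so token-level structure suffices and keeps the generator
#' auditable.
#'
#' @param n_positive,n_negative patient counts.
#' @param entries_per_patient list with `mean` (total entries per patient,
#'   including the seen one) and `dispersion` (negative-binomial size;
#'   `Inf` for Poisson).
#' @param evidence_lexicon data frame of evidence `token`s and their
#'   misspelled `variant` forms.
#' @param circumstantial_terms evidence-adjacent disease-context terms
#'   (symptoms, organs, examinations) shared across positive patients: each
#'   positive seen entry carries two of them alongside the evidence token,
#'   and they occasionally appear, unnegated, in other entries of either
#'   class.
#' @param background_vocab_size number of background tokens; frequencies
#'   follow a Zipf profile.
#' @param tokens_per_entry list with `mean` and `dispersion` for the
#'   background token count of an entry.
#' @param negation_rate probability a positive patient's evidence mention is
#'   negated or speculative (keyword prefix or a `?`-terminated sentence).
#' @param misspelling_rate probability the evidence surface form is the
#'   variant spelling.
#' @param circumstantial_rate per-entry probability that a non-evidence
#'   entry mentions a circumstantial term.
#' @param negative_mention_rate per-entry probability that a non-evidence
#'   entry contains a *negated/speculative* evidence mention (the reason
#'   such patients were retrieved by a broad query in the first place).
#' @param label_error_rate probability a positive patient is mislabeled:
#'   its "evidence" is in fact only speculative.
#' @param background_negation_rate,background_question_rate per-entry rates
#'   of negation keywords and `?`-terminated sentences in ordinary
#'   background text, present in both classes.
#' @param symptom_rate per-slot inclusion probability for the two
#'   circumstantial-term slots of a positive seen entry (1 = both always
#'   present).
#' @param unseen_total,implicit_total optional exact totals of unseen and
#'   implicit entries; when set they are distributed over the patients and
#'   override the per-patient draw (used by [shape_preset()]).
#' @param seed optional seed; generation is bit-reproducible for a fixed
#'   seed.
#' @param name corpus name.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positive = 50, n_negative = 450,
                             entries_per_patient = list(mean = 6,
                                                        dispersion = Inf),
                             evidence_lexicon = default_evidence_lexicon(),
                             circumstantial_terms = c("galblaas", "echo",
                                                      "lever", "galsteen",
                                                      "icterus", "koorts",
                                                      "buikpijn", "alat"),
                             background_vocab_size = 100,
                             tokens_per_entry = list(mean = 12,
                                                     dispersion = Inf),
                             negation_rate = 0.15,
                             misspelling_rate = 0.10,
                             circumstantial_rate = 0.02,
                             negative_mention_rate = 0.10,
                             label_error_rate = 0,
                             background_negation_rate = 0.15,
                             background_question_rate = 0.05,
                             symptom_rate = 1,
                             unseen_total = NULL, implicit_total = NULL,
                             seed = NULL, name = "synthetic") {
  rates <- c(negation_rate = negation_rate,
             misspelling_rate = misspelling_rate,
             circumstantial_rate = circumstantial_rate,
             negative_mention_rate = negative_mention_rate,
             label_error_rate = label_error_rate,
             background_negation_rate = background_negation_rate,
             background_question_rate = background_question_rate,
             symptom_rate = symptom_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_badarg("all rates must lie in [0, 1]: ",
                paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (n_positive < 1 || n_negative < 1) {
    stop_badarg("n_positive and n_negative must be at least 1")
  }
  if (background_vocab_size < 1) {
    stop_badarg("background_vocab_size must be at least 1")
  }
  if (entries_per_patient$mean < 1 || tokens_per_entry$mean < 1) {
    stop_badarg("count distribution means must be at least 1")
  }
  stopifnot(is.data.frame(evidence_lexicon),
            all(c("token", "variant") %in% names(evidence_lexicon)),
            nrow(evidence_lexicon) >= 1)
  structure(
    list(n_positive = as.integer(n_positive),
         n_negative = as.integer(n_negative),
         entries_per_patient = entries_per_patient,
         evidence_lexicon = evidence_lexicon,
         circumstantial_terms = circumstantial_terms,
         background_vocab_size = as.integer(background_vocab_size),
         tokens_per_entry = tokens_per_entry,
         negation_rate = negation_rate,
         misspelling_rate = misspelling_rate,
         circumstantial_rate = circumstantial_rate,
         negative_mention_rate = negative_mention_rate,
         label_error_rate = label_error_rate,
         background_negation_rate = background_negation_rate,
         background_question_rate = background_question_rate,
         symptom_rate = symptom_rate,
         unseen_total = unseen_total, implicit_total = implicit_total,
         seed = seed, name = name),
    class = "synthetic_config"
  )
}

#' Preset configurations matching the two study data-set shapes
#'
#' Returns a [synthetic_config()] whose patient counts and entry totals
#' match the published shape of the corresponding data set exactly:
#' `hepatobiliary` has 656 positive / 317 negative patients with 61,179
#' unseen and 27,276 implicit entries; `renal` has 237 positive / 3,751
#' negative patients with 58,022 unseen and 319,204 implicit entries.
#' A `scale` below 1 shrinks every count proportionally while preserving the
#' imbalance structure, which keeps experiments on the renal shape (nearly
#' 400,000 entries at full size) tractable.
#'
#' @param name `"hepatobiliary"` or `"renal"`.
#' @param scale positive scaling factor applied to all counts.
#' @param ... further arguments passed to [synthetic_config()] (rates,
#'   seed, ...).
#' @return A `synthetic_config`.
#' @export
shape_preset <- function(name = c("hepatobiliary", "renal"), scale = 1, ...) {
  name <- tryCatch(match.arg(name),
                   error = function(e) {
                     stop_badarg("unknown preset: '", name[1], "'")
                   })
  stopifnot(is.numeric(scale), scale > 0)
  counts <- switch(name,
    hepatobiliary = list(pos = 656, neg = 317, unseen = 61179,
                         implicit = 27276),
    renal = list(pos = 237, neg = 3751, unseen = 58022, implicit = 319204)
  )
  n_pos <- max(1L, round(counts$pos * scale))
  n_neg <- max(1L, round(counts$neg * scale))
  synthetic_config(
    n_positive = n_pos,
    n_negative = n_neg,
    unseen_total = round(counts$unseen * scale),
    implicit_total = round(counts$implicit * scale),
    name = if (scale == 1) name else sprintf("%s (scale %g)", name, scale),
    ...
  )
}

# Distribute `total` extra entries over `n` patients: each gets the floor
# share, and the remainder goes to a random subset.
allocate_exact <- function(total, n) {
  base <- total %/% n
  extra <- integer(n)
  rem <- total %% n
  if (rem > 0) extra[sample.int(n, rem)] <- 1L
  base + extra
}

draw_counts <- function(n, mean, dispersion) {
  if (mean <= 0) return(integer(n))
  if (is.infinite(dispersion)) {
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = dispersion, mu = mean)
  }
}

#' Generate a synthetic labeled corpus with a ground-truth sidecar
#'
#' Realizes a [synthetic_config()]: every positive patient receives exactly
#' one seen entry containing an evidence token (possibly the misspelled
#' variant, possibly negated or speculative) plus unseen background entries;
#' every negative patient receives one seen and several implicit background
#' entries. Background text in both classes carries negation keywords and
#' `?`-terminated sentences at fixed rates, and non-evidence entries may
#' contain negated evidence mentions and unnegated circumstantial terms.
#' The sidecar records, per patient, the evidence entry and surface form and
#' the negation/misspelling/label-error flags, enabling the false-negative
#' error taxonomy.
#'
#' Generated corpora are designed to be filtered with [default_lexicon()]:
#' the negation and speculation keywords they embed are drawn from it.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `corpus` (an [emr_corpus()]) and `truth`
#'   (the sidecar data frame; see [write_truth()]).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed_maybe(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  vocab <- sprintf("bg%03d", seq_len(cfg$background_vocab_size))
  zipf <- 1 / seq_len(cfg$background_vocab_size)
  neg_kw <- c("geen", "niet", "zonder")
  spec_kw <- c("mogelijk", "waarschijnlijk", "verdacht")

  n_pos <- cfg$n_positive
  n_neg <- cfg$n_negative

  extra_pos <- if (!is.null(cfg$unseen_total)) {
    allocate_exact(cfg$unseen_total, n_pos)
  } else {
    draw_counts(n_pos, cfg$entries_per_patient$mean - 1,
                cfg$entries_per_patient$dispersion)
  }
  extra_neg <- if (!is.null(cfg$implicit_total)) {
    allocate_exact(cfg$implicit_total, n_neg)
  } else {
    draw_counts(n_neg, cfg$entries_per_patient$mean - 1,
                cfg$entries_per_patient$dispersion)
  }

  n_entries <- n_pos + sum(extra_pos) + n_neg + sum(extra_neg)

  # Background sentence of every entry, generated in one vectorized pass.
  lens <- pmax(3L, draw_counts(n_entries, cfg$tokens_per_entry$mean,
                               cfg$tokens_per_entry$dispersion))
  toks <- sample(vocab, sum(lens), replace = TRUE, prob = zipf)
  tok_list <- split(toks, rep(seq_len(n_entries), lens))
  negated_bg <- stats::runif(n_entries) < cfg$background_negation_rate
  question_bg <- stats::runif(n_entries) < cfg$background_question_rate
  base_text <- vapply(seq_len(n_entries), function(i) {
    tt <- tok_list[[i]]
    if (negated_bg[i]) {
      kw <- sample(c(neg_kw, spec_kw), 1L)
      pos <- sample.int(length(tt), 1L)
      tt <- append(tt, kw, after = pos - 1L)
    }
    s <- paste0(paste(tt, collapse = " "), ".")
    if (question_bg[i]) {
      s <- paste0(s, " ", paste(sample(vocab, 2L, prob = zipf), collapse = " "),
                  "?")
    }
    s
  }, character(1))

  # Optional additions for non-evidence entries (both classes).
  mention <- stats::runif(n_entries) < cfg$negative_mention_rate
  circ <- stats::runif(n_entries) < cfg$circumstantial_rate
  negated_evidence_sentence <- function() {
    surf <- sample(cfg$evidence_lexicon$token, 1L)
    if (stats::runif(1) < 0.5) {
      paste0(" ", sample(c(neg_kw, spec_kw), 1L), " ", surf, ".")
    } else {
      paste0(" ", surf, " ", sample(vocab, 1L, prob = zipf), "?")
    }
  }
  decorate_plain <- function(i) {
    s <- base_text[i]
    if (mention[i]) s <- paste0(s, negated_evidence_sentence())
    if (circ[i]) {
      s <- paste0(s, " ", sample(cfg$circumstantial_terms, 1L), ".")
    }
    s
  }

  patients <- vector("list", n_pos + n_neg)
  truth <- vector("list", n_pos + n_neg)
  cursor <- 0L # index into base_text

  mislabeled <- stats::runif(n_pos) < cfg$label_error_rate
  for (i in seq_len(n_pos)) {
    pid <- sprintf("pos%04d", i)
    n_e <- 1L + extra_pos[i]
    entry_ids <- paste0("e", seq_len(n_e))
    seen_idx <- sample.int(n_e, 1L)
    texts <- character(n_e)
    for (j in seq_len(n_e)) {
      cursor <- cursor + 1L
      texts[j] <- if (j == seen_idx) base_text[cursor] else decorate_plain(cursor)
    }

    ev_row <- cfg$evidence_lexicon[sample.int(nrow(cfg$evidence_lexicon), 1L), ]
    misspelled <- stats::runif(1) < cfg$misspelling_rate
    surface <- if (misspelled) ev_row$variant else ev_row$token
    negated <- stats::runif(1) < cfg$negation_rate
    ev_sentence <- if (mislabeled[i]) {
      paste0(" ", sample(spec_kw, 1L), " ", surface, ".")
    } else if (negated) {
      negation_marker <- stats::runif(1) < 0.5
      if (negation_marker) {
        paste0(" ", sample(c(neg_kw, spec_kw), 1L), " ", surface, ".")
      } else {
        paste0(" ", surface, " ", sample(vocab, 1L, prob = zipf), "?")
      }
    } else {
      paste0(" ", surface, ".")
    }
    texts[seen_idx] <- paste0(texts[seen_idx], ev_sentence)
    if (!mislabeled[i]) {
      ctx <- sample(cfg$circumstantial_terms,
                    min(2L, length(cfg$circumstantial_terms)))
      ctx <- ctx[stats::runif(length(ctx)) < cfg$symptom_rate]
      if (length(ctx)) {
        texts[seen_idx] <- paste0(texts[seen_idx], " ",
                                  paste(ctx, collapse = " "), ".")
      }
    }

    roles <- rep("unseen", n_e)
    roles[seen_idx] <- "seen"
    patients[[i]] <- patient_record(pid, "positive",
                                    data.frame(entry_id = entry_ids,
                                               role = roles, text = texts,
                                               stringsAsFactors = FALSE))
    truth[[i]] <- data.frame(
      patient_id = pid,
      evidence_entry_id = entry_ids[seen_idx],
      evidence_token = surface,
      evidence_negated = negated || mislabeled[i],
      evidence_misspelled = misspelled,
      label_is_error = mislabeled[i],
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(n_neg)) {
    pid <- sprintf("neg%04d", i)
    n_e <- 1L + extra_neg[i]
    entry_ids <- paste0("e", seq_len(n_e))
    seen_idx <- sample.int(n_e, 1L)
    texts <- character(n_e)
    for (j in seq_len(n_e)) {
      cursor <- cursor + 1L
      texts[j] <- decorate_plain(cursor)
    }
    roles <- rep("implicit", n_e)
    roles[seen_idx] <- "seen"
    patients[[n_pos + i]] <- patient_record(pid, "negative",
                                            data.frame(entry_id = entry_ids,
                                                       role = roles,
                                                       text = texts,
                                                       stringsAsFactors = FALSE))
    truth[[n_pos + i]] <- data.frame(
      patient_id = pid,
      evidence_entry_id = NA_character_,
      evidence_token = NA_character_,
      evidence_negated = FALSE,
      evidence_misspelled = FALSE,
      label_is_error = FALSE,
      stringsAsFactors = FALSE
    )
  }

  list(corpus = emr_corpus(patients, name = cfg$name),
       truth = do.call(rbind, truth))
}

#' Write / read the ground-truth sidecar
#'
#' JSON-lines, one object per patient, written next to the corpus file by
#' convention. Fields: `patient_id`, `evidence_entry_id`, `evidence_token`
#' (`null` for negative patients), `evidence_negated`,
#' `evidence_misspelled`, `label_is_error`.
#'
#' @param truth sidecar data frame from [generate_corpus()].
#' @param path file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   sidecar data frame.
#' @export
write_truth <- function(truth, path) {
  lines <- vapply(seq_len(nrow(truth)), function(i) {
    as.character(jsonlite::toJSON(as.list(truth[i, , drop = FALSE]),
                                  auto_unbox = TRUE, na = "null"))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_badarg("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]])
    data.frame(
      patient_id = rec$patient_id,
      evidence_entry_id = rec$evidence_entry_id %||% NA_character_,
      evidence_token = rec$evidence_token %||% NA_character_,
      evidence_negated = isTRUE(rec$evidence_negated),
      evidence_misspelled = isTRUE(rec$evidence_misspelled),
      label_is_error = isTRUE(rec$label_is_error),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
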