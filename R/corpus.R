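#' Labeled patient records with role-tagged free-text entries
#'
#' The unit of labeling and of cross-validation is the patient. A patient
#' record carries a binary gold label (`"positive"` or `"negative"`) and one
#' or more free-text entries (visit notes, specialist letters), each tagged
#' with a role:
#'
#' * `seen` -- the single entry examined during manual labeling: the evidence
#'   entry for a positive patient, a randomly chosen entry for a negative one.
#' * `implicit` -- any other entry of a *negative* patient. Because the whole
#'   record was reviewed and found negative, these are usable as additional
#'   negative training examples ("set expansion").
#' * `unseen` -- any other entry of a *positive* patient. Their evidence
#'   status is unknown, so they are excluded from training but included at
#'   test time.
#'
#' @param patient_id character scalar, unique within a corpus.
#' @param gold_label `"positive"` or `"negative"`.
#' @param entries data frame with character columns `entry_id`, `role`
#'   (`"seen"`, `"implicit"`, or `"unseen"`), and `text`.
#' @return An object of class `patient_record`.
#' @seealso [emr_corpus()], [read_corpus()], [summarize_corpus()]
#' @export
#' @examples
#' patient_record("p1", "positive",
#'   data.frame(entry_id = "e1", role = "seen", text = "cholelithiasis."))
patient_record <- function(patient_id, gold_label, entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  p <- structure(
    list(
      patient_id = as.character(patient_id),
      gold_label = as.character(gold_label),
      entries = entries[, c("entry_id", "role", "text"), drop = FALSE]
    ),
    class = "patient_record"
  )
  validate_patient_record(p)
  p
}

validate_patient_record <- function(p) {
  pid <- p$patient_id
  fail <- function(...) {
    stop_badarg("invalid patient record '", pid, "': ", ...)
  }
  if (length(pid) != 1L || is.na(pid) || !nzchar(pid)) {
    stop_badarg("patient_id must be a non-empty string")
  }
  if (!p$gold_label %in% c("positive", "negative")) {
    fail("gold_label must be 'positive' or 'negative'")
  }
  e <- p$entries
  if (!is.data.frame(e) || nrow(e) == 0L) fail("at least one entry required")
  if (!all(c("entry_id", "role", "text") %in% names(e))) {
    fail("entries need columns entry_id, role, text")
  }
  if (anyDuplicated(e$entry_id)) fail("duplicate entry_id")
  if (!all(e$role %in% c("seen", "implicit", "unseen"))) {
    fail("role must be one of seen/implicit/unseen")
  }
  if (any(!nzchar(trimws(e$text)))) fail("entry text must be non-empty")
  n_seen <- sum(e$role == "seen")
  if (n_seen != 1L) fail("exactly one 'seen' entry required, found ", n_seen)
  other <- e$role[e$role != "seen"]
  if (p$gold_label == "positive" && any(other != "unseen")) {
    fail("non-seen entries of a positive patient must be 'unseen'")
  }
  if (p$gold_label == "negative" && any(other != "implicit")) {
    fail("non-seen entries of a negative patient must be 'implicit'")
  }
  invisible(p)
}

#' Construct a corpus of patient records
#'
#' @param patients list of [patient_record()] objects with unique patient ids.
#' @param name free-text corpus name.
#' @return An object of class `emr_corpus`: a list with elements `patients`
#'   and `name`.
#' @export
emr_corpus <- function(patients = list(), name = "") {
  corpus <- structure(list(patients = patients, name = as.character(name)),
                      class = "emr_corpus")
  validate_corpus(corpus)
  corpus
}

#' Validate corpus invariants
#'
#' Checks every patient record and the uniqueness of patient ids; errors name
#' the offending patient.
#'
#' @param corpus an `emr_corpus`.
#' @return The corpus, invisibly, if valid.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "emr_corpus"))
  for (p in corpus$patients) validate_patient_record(p)
  ids <- vapply(corpus$patients, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) {
    stop_badarg("duplicate patient_id in corpus: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  invisible(corpus)
}

patient_ids <- function(corpus) {
  vapply(corpus$patients, `[[`, character(1), "patient_id")
}

#' @export
print.emr_corpus <- function(x, ...) {
  s <- summarize_corpus(x)
  cat(sprintf(
    "<emr_corpus%s: %d patients (%d positive, %d negative), %d entries>\n",
    if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
    s$n_positive + s$n_negative, s$n_positive, s$n_negative,
    s$n_seen_pos + s$n_seen_neg + s$n_implicit + s$n_unseen
  ))
  invisible(x)
}

#' Read a corpus from a JSON-lines file
#'
#' One JSON object per line, one line per patient:
#' `{"patient_id": ..., "gold_label": ..., "entries": [{"entry_id": ...,
#' "role": ..., "text": ...}, ...]}`. Files are UTF-8. Malformed lines raise
#' a parse error naming the line number; invariant violations raise a
#' validation error naming the patient.
#'
#' @param path file path.
#' @param name corpus name; defaults to the file name.
#' @return An [emr_corpus()].
#' @export
read_corpus <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop_badarg("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  patients <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
      error = function(e) {
        stop_badarg("parse error at line ", i, " of ", path, ": ",
                    conditionMessage(e))
      }
    )
    if (is.null(rec$patient_id) || is.null(rec$gold_label) ||
        is.null(rec$entries) || !is.data.frame(rec$entries)) {
      stop_badarg("parse error at line ", i, " of ", path,
                  ": record must have patient_id, gold_label and entries")
    }
    patients[[i]] <- patient_record(rec$patient_id, rec$gold_label, rec$entries)
  }
  emr_corpus(patients, name = name)
}

#' Write a corpus to a JSON-lines file
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p))` reproduces
#' `x` exactly, including non-ASCII text.
#'
#' @param corpus an `emr_corpus`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  lines <- vapply(corpus$patients, function(p) {
    as.character(jsonlite::toJSON(
      list(patient_id = p$patient_id, gold_label = p$gold_label,
           entries = p$entries),
      dataframe = "rows", auto_unbox = TRUE
    ))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Tally a corpus by label and entry role
#'
#' Patient and entry counts in the layout used to describe data-set shapes:
#' positive/negative patients, their seen entries, and the implicit and
#' unseen entry pools. One seen entry per patient, so `n_seen_pos`
#' equals `n_positive` and `n_seen_neg` equals `n_negative` by construction.
#'
#' @param corpus an `emr_corpus`.
#' @return A `corpus_summary`: list with `n_positive`, `n_negative`,
#'   `n_seen_pos`, `n_seen_neg`, `n_implicit`, `n_unseen`.
#' @export
summarize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "emr_corpus"))
  lab <- vapply(corpus$patients, `[[`, character(1), "gold_label")
  roles <- lapply(corpus$patients, function(p) p$entries$role)
  n_role <- function(which_lab, role) {
    sum(vapply(roles[lab == which_lab], function(r) sum(r == role), integer(1)))
  }
  structure(list(
    n_positive = sum(lab == "positive"),
    n_negative = sum(lab == "negative"),
    n_seen_pos = n_role("positive", "seen"),
    n_seen_neg = n_role("negative", "seen"),
    n_implicit = n_role("negative", "implicit"),
    n_unseen = n_role("positive", "unseen")
  ), class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("Corpus summary\n")
  cat(sprintf("  Positive cases   %6d (seen entries %d, unseen entries %d)\n",
              x$n_positive, x$n_seen_pos, x$n_unseen))
  cat(sprintf("  Negative cases   %6d (seen entries %d, implicit entries %d)\n",
              x$n_negative, x$n_seen_neg, x$n_implicit))
  invisible(x)
}

#' Concatenate corpora with disjoint patient ids
#'
#' @param ... `emr_corpus` objects.
#' @param name name for the combined corpus.
#' @return An `emr_corpus` holding all patients.
#' @export
combine_corpora <- function(..., name = "") {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "emr_corpus")))
  emr_corpus(do.call(c, lapply(parts, `[[`, "patients")), name = name)
}
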