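# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding: 0.5 always moves away from zero, unlike [base::round()]
#' which rounds to even. Used for sampling removal counts and for the display
#' convention of imbalance ratios.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# state; with a NULL seed the ambient RNG stream is used.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Key used to index entries across a corpus (unit separator cannot occur in
# identifiers coming from the JSON-lines reader).
entry_key <- function(patient_id, entry_id) {
  paste(patient_id, entry_id, sep = "\x1f")
}

stop_badarg <- function(...) stop(..., call. = FALSE)
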