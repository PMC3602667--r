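# Shared fixtures and independent oracles, built in code.

make_entries <- function(ids, roles, texts) {
  data.frame(entry_id = ids, role = roles, text = texts,
             stringsAsFactors = FALSE)
}

# Spec of the smallest interesting corpus: 2 positive patients (1 seen + 2
# unseen each), 1 negative patient (1 seen + 3 implicit).
tiny_corpus <- function() {
  emr_corpus(list(
    patient_record("p1", "positive", make_entries(
      c("e1", "e2", "e3"), c("seen", "unseen", "unseen"),
      c("hepatitis aangetoond", "controle afspraak", "brief specialist"))),
    patient_record("p2", "positive", make_entries(
      c("e1", "e2", "e3"), c("seen", "unseen", "unseen"),
      c("echo cholelithiasis", "lab uitslag", "telefonisch consult"))),
    patient_record("p3", "negative", make_entries(
      c("e1", "e2", "e3", "e4"),
      c("seen", "implicit", "implicit", "implicit"),
      c("rugklachten", "griep", "verkoudheid", "controle")))
  ), name = "tiny")
}

# Entry-level training-example frame with the published data-set shapes,
# built directly (ratio arithmetic needs counts, not text).
shape_examples <- function(n_pos, n_neg_seen, n_implicit = 0) {
  pos <- data.frame(
    patient_id = paste0("p", seq_len(n_pos)), entry_id = "s",
    label = "positive", provenance = "seen_pos", text = "x",
    stringsAsFactors = FALSE)
  neg <- data.frame(
    patient_id = paste0("n", seq_len(n_neg_seen)), entry_id = "s",
    label = "negative", provenance = "seen_neg", text = "x",
    stringsAsFactors = FALSE)
  out <- rbind(pos, neg)
  if (n_implicit > 0) {
    imp <- data.frame(
      patient_id = paste0("n", rep_len(seq_len(n_neg_seen), n_implicit)),
      entry_id = paste0("i", seq_len(n_implicit)),
      label = "negative", provenance = "implicit", text = "x",
      stringsAsFactors = FALSE)
    out <- rbind(out, imp)
  }
  out
}

# Structural corpus with given patient counts and an exact implicit-entry
# total; text is a placeholder token.
skeleton_corpus <- function(n_pos, n_neg, n_implicit) {
  base <- n_implicit %/% n_neg
  extra <- c(rep(1L, n_implicit %% n_neg), rep(0L, n_neg - n_implicit %% n_neg))
  patients <- c(
    lapply(seq_len(n_pos), function(i) {
      patient_record(paste0("p", i), "positive",
                     make_entries("e1", "seen", "x"))
    }),
    lapply(seq_len(n_neg), function(i) {
      n_e <- 1L + base + extra[i]
      patient_record(paste0("n", i), "negative",
                     make_entries(paste0("e", seq_len(n_e)),
                                  c("seen", rep("implicit", n_e - 1L)),
                                  rep("x", n_e)))
    })
  )
  emr_corpus(patients, name = "skeleton")
}

# Independent chi-square oracle: expected-count summation over the 2x2
# table (rows: token present/absent; columns: positive/negative).
chi2_brute <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) return(0)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Independent greedy tree oracle: exhaustively scores every unused feature
# at every node with chi2_brute and recurses, mirroring the documented
# split/stop/tie conventions.
oracle_tree <- function(X, y, alpha = 0.05, rows = seq_len(nrow(X)),
                        used = logical(ncol(X))) {
  n_pos <- sum(y[rows] == "positive")
  n_neg <- length(rows) - n_pos
  leaf <- list(leaf = TRUE,
               label = if (n_pos >= n_neg) "positive" else "negative")
  if (n_pos == 0 || n_neg == 0 || all(used)) return(leaf)
  stats <- rep(-1, ncol(X))
  for (j in which(!used)) {
    a <- sum(X[rows, j] == 1 & y[rows] == "positive")
    b <- sum(X[rows, j] == 1 & y[rows] == "negative")
    stats[j] <- chi2_brute(a, b, n_pos - a, n_neg - b)
  }
  j <- which.max(stats)
  if (stats::pchisq(stats[j], 1, lower.tail = FALSE) >= alpha) return(leaf)
  used[j] <- TRUE
  list(leaf = FALSE, feature = j,
       absent = oracle_tree(X, y, alpha, rows[X[rows, j] == 0], used),
       present = oracle_tree(X, y, alpha, rows[X[rows, j] == 1], used))
}

oracle_predict <- function(tree, X) {
  apply(X, 1, function(x) {
    node <- tree
    while (!node$leaf) {
      node <- if (x[node$feature] == 1) node$present else node$absent
    }
    node$label
  })
}

# Random clinical-note-like text mixing keywords, punctuation, and case.
random_text <- function() {
  pool <- c("geen", "niet", "mogelijk", "of", "versus", "lever", "koorts",
            "galblaas", "echo", "status", "na", "bb", "x", "li", "re",
            "Cholelithiasis", "MATIG", "coprostase")
  n <- sample(2:14, 1)
  words <- sample(pool, n, replace = TRUE)
  seps <- sample(c(" ", " ", ". ", "? ", ": ", ", ", "! ", "; "),
                 n - 1, replace = TRUE)
  txt <- paste0(paste0(words[-n], seps, collapse = ""), words[n])
  if (stats::runif(1) < 0.3) txt <- paste0(txt, sample(c(".", "?", "!"), 1))
  txt
}

# Multiset inclusion: every token of x occurs in y at least as often.
multiset_subset <- function(x, y) {
  tx <- table(x)
  ty <- table(y)
  all(names(tx) %in% names(ty)) &&
    all(tx <= ty[names(tx)])
}

# Small separable toy problem: feature 1 perfectly predicts the label.
toy_separable <- function(n_pos = 5, n_neg = 5) {
  X <- rbind(cbind(1, stats::rbinom(n_pos, 1, 0.5)),
             cbind(0, stats::rbinom(n_neg, 1, 0.5)))
  colnames(X) <- c("marker", "noise")
  list(X = X, y = rep(c("positive", "negative"), c(n_pos, n_neg)))
}
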