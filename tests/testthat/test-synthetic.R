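test_that("generated corpora always satisfy the corpus invariants", {
  for (s in 1:3) {
    sim <- generate_corpus(synthetic_config(n_positive = 8, n_negative = 25,
                                            seed = s))
    expect_silent(validate_corpus(sim$corpus))
    s_sum <- summarize_corpus(sim$corpus)
    expect_equal(s_sum$n_positive, 8)
    expect_equal(s_sum$n_negative, 25)
    expect_equal(nrow(sim$truth), 33)
  }
  expect_error(synthetic_config(negation_rate = 1.2), "rates")
  expect_error(synthetic_config(n_positive = 0), "at least 1")
})

test_that("every positive patient's seen entry carries its recorded evidence form", {
  sim <- generate_corpus(synthetic_config(n_positive = 40, n_negative = 10,
                                          seed = 11))
  tr <- sim$truth[!is.na(sim$truth$evidence_token), ]
  expect_equal(nrow(tr), 40)
  for (i in seq_len(nrow(tr))) {
    p <- Filter(function(x) x$patient_id == tr$patient_id[i],
                sim$corpus$patients)[[1]]
    seen <- p$entries[p$entries$role == "seen", ]
    expect_equal(seen$entry_id, tr$evidence_entry_id[i])
    expect_true(tr$evidence_token[i] %in% tokenize(tolower(seen$text)))
  }
})

test_that("the negated fraction tracks the configured rate", {
  negated <- unlist(lapply(1:4, function(s) {
    sim <- generate_corpus(synthetic_config(n_positive = 100, n_negative = 5,
                                            negation_rate = 0.3, seed = s))
    sim$truth$evidence_negated[!is.na(sim$truth$evidence_token)]
  }))
  # 400 draws at rate 0.3: allow 4 binomial standard errors
  expect_lt(abs(mean(negated) - 0.3), 4 * sqrt(0.3 * 0.7 / 400))
})

test_that("negated evidence is removed by the default-lexicon filter", {
  lex <- default_lexicon()
  sim <- generate_corpus(synthetic_config(n_positive = 60, n_negative = 5,
                                          negation_rate = 1, seed = 21))
  tr <- sim$truth[!is.na(sim$truth$evidence_token), ]
  for (i in seq_len(nrow(tr))) {
    p <- Filter(function(x) x$patient_id == tr$patient_id[i],
                sim$corpus$patients)[[1]]
    seen <- p$entries[p$entries$role == "seen", ]
    post <- tokenize(apply_assertion_filter(seen$text, lex))
    expect_false(tr$evidence_token[i] %in% post)
  }
})

test_that("presets reproduce the published data-set shapes exactly", {
  cfg <- shape_preset("hepatobiliary")
  expect_equal(cfg$n_positive, 656)
  expect_equal(cfg$n_negative, 317)
  cfg_r <- shape_preset("renal")
  expect_equal(cfg_r$n_positive, 237)
  expect_equal(cfg_r$n_negative, 3751)
  expect_error(shape_preset("cardiac"), "unknown preset")

  # exact entry totals at a reduced scale
  sim <- generate_corpus(shape_preset("renal", scale = 0.02, seed = 1))
  s <- summarize_corpus(sim$corpus)
  expect_equal(s$n_positive, round(237 * 0.02))
  expect_equal(s$n_negative, round(3751 * 0.02))
  expect_equal(s$n_unseen, round(58022 * 0.02))
  expect_equal(s$n_implicit, round(319204 * 0.02))
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- shape_preset("hepatobiliary", scale = 0.03, seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$truth, b$truth)
})

test_that("label errors are speculative mentions flagged in the sidecar", {
  sim <- generate_corpus(synthetic_config(n_positive = 60, n_negative = 5,
                                          label_error_rate = 0.5, seed = 31))
  err <- sim$truth[sim$truth$label_is_error %in% TRUE, ]
  expect_gt(nrow(err), 5)
  lex <- default_lexicon()
  for (i in seq_len(nrow(err))) {
    p <- Filter(function(x) x$patient_id == err$patient_id[i],
                sim$corpus$patients)[[1]]
    seen <- p$entries[p$entries$role == "seen", ]
    # the mention survives raw tokenization but not the filter
    expect_true(err$evidence_token[i] %in% tokenize(tolower(seen$text)))
    expect_false(err$evidence_token[i] %in%
                   tokenize(apply_assertion_filter(seen$text, lex)))
  }
})

test_that("the ground-truth sidecar round trips through JSON-lines", {
  sim <- generate_corpus(synthetic_config(n_positive = 6, n_negative = 10,
                                          seed = 3))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_truth(sim$truth, path)
  expect_equal(read_truth(path), sim$truth)
})
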