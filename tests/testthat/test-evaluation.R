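test_that("fold assignment partitions patients into near-equal folds", {
  sim <- generate_corpus(synthetic_config(n_positive = 2, n_negative = 8,
                                          seed = 1))
  f <- make_folds(sim$corpus, k = 5, seed = 1)
  expect_setequal(f$patient_id, patient_ids(sim$corpus))
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))

  sim11 <- generate_corpus(synthetic_config(n_positive = 3, n_negative = 8,
                                            seed = 2))
  f11 <- make_folds(sim11$corpus, k = 5, seed = 2)
  expect_equal(sort(as.integer(table(f11$fold))), c(2L, 2L, 2L, 2L, 3L))

  expect_identical(make_folds(sim$corpus, 5, seed = 7),
                   make_folds(sim$corpus, 5, seed = 7))
  expect_error(make_folds(sim$corpus, k = 11), "at least k")
})

test_that("sensitivity and specificity are exact quotients with guarded denominators", {
  expect_equal(sensitivity(confusion_counts(tp = 9, fn = 1)), 0.9)
  expect_equal(specificity(confusion_counts(tn = 0, fp = 5)), 0)
  expect_error(sensitivity(confusion_counts(tn = 3, fp = 1)), "undefined")
  expect_error(specificity(confusion_counts(tp = 3, fn = 1)), "undefined")
})

test_that("a patient is positive iff at least one entry is classified positive", {
  # model that fires only on the token "ev"
  tokens <- c(rep(list(c("ev", "bg")), 6), rep(list("bg"), 6))
  labels <- rep(c("positive", "negative"), each = 6)
  vocab <- build_vocabulary(tokens, labels)
  model <- train_base(base_learner_spec("myc"),
                      vectorize_examples(tokens, vocab), labels)
  lex <- keyword_lexicon()

  pos <- patient_record("a", "positive", make_entries(
    paste0("e", 1:7), c("seen", rep("unseen", 6)),
    c(rep("bg", 6), "bg ev")))
  expect_equal(classify_patient(model, pos, vocab, lex), "positive")

  neg <- patient_record("b", "negative", make_entries(
    paste0("e", 1:3), c("seen", "implicit", "implicit"), rep("bg", 3)))
  expect_equal(classify_patient(model, neg, vocab, lex), "negative")

  single <- patient_record("c", "positive", make_entries("e1", "seen", "ev"))
  expect_equal(classify_patient(model, single, vocab, lex), "positive")
})

test_that("experiments are deterministic and pool counts across folds", {
  sim <- generate_corpus(synthetic_config(n_positive = 10, n_negative = 40,
                                          seed = 5))
  lex <- default_lexicon()
  r1 <- run_experiment(sim$corpus, sampling_plan(TRUE),
                       base_learner_spec("myc"), lex, seed = 5)
  r2 <- run_experiment(sim$corpus, sampling_plan(TRUE),
                       base_learner_spec("myc"), lex, seed = 5)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$predictions, r2$predictions)

  expect_equal(r1$pooled$tp, sum(r1$per_fold$tp))
  expect_equal(r1$pooled$fn, sum(r1$per_fold$fn))
  expect_equal(r1$pooled$tp + r1$pooled$fn, 10)
  expect_equal(r1$pooled$tn + r1$pooled$fp, 40)
  # every patient is tested exactly once
  expect_setequal(r1$predictions$patient_id, patient_ids(sim$corpus))
  expect_equal(anyDuplicated(r1$predictions$patient_id), 0L)
})

test_that("label-independent text yields chance-level discrimination", {
  # single-entry patients whose text carries no label signal: the classifier
  # cannot distinguish classes, so P(pred pos | pos) == P(pred pos | neg)
  # and sensitivity ~= 1 - specificity up to binomial noise.
  lex <- keyword_lexicon()
  gaps <- sapply(1:5, function(s) {
    set.seed(s)
    patients <- lapply(1:80, function(i) {
      txt <- paste(sample(sprintf("w%02d", 1:30), 8, replace = TRUE),
                   collapse = " ")
      patient_record(paste0("q", i),
                     if (i <= 40) "positive" else "negative",
                     make_entries("e1", "seen", txt))
    })
    corpus <- emr_corpus(patients)
    r <- run_experiment(corpus, sampling_plan(TRUE),
                        base_learner_spec("myc"), lex, seed = s)
    r$sensitivity - (1 - r$specificity)
  })
  expect_lt(abs(mean(gaps)), 0.15)
})

test_that("kappa matches hand computation with a large-sample interval", {
  k <- cohen_kappa(matrix(c(40, 5, 10, 45), 2, 2))
  expect_equal(k$p_observed, 0.85)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.7)
  expect_equal(k$ci[2] - k$ci[1],
               2 * 1.96 * sqrt(0.85 * 0.15 / (100 * 0.25)))

  expect_equal(cohen_kappa(matrix(c(30, 0, 0, 70), 2, 2))$kappa, 1)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2, 2))$kappa, 0)
  expect_error(cohen_kappa(matrix(c(10, 0, 0, 0), 2, 2)), "undefined")
})

test_that("false negatives fall through the documented error cascade", {
  lex <- default_lexicon()
  mk_truth <- function(pid, eid, tok, neg = FALSE, mis = FALSE, err = FALSE) {
    data.frame(patient_id = pid, evidence_entry_id = eid,
               evidence_token = tok, evidence_negated = neg,
               evidence_misspelled = mis, label_is_error = err,
               stringsAsFactors = FALSE)
  }
  p_filter <- patient_record("f1", "positive", make_entries(
    "e1", "seen", "echo bb: cholelithiasis net zichtbaar?"))
  p_spell <- patient_record("f2", "positive", make_entries(
    "e1", "seen", "beeld van levercirrhose"))
  p_model <- patient_record("f3", "positive", make_entries(
    "e1", "seen", "duidelijke cholestase aanwezig"))
  p_label <- patient_record("f4", "positive", make_entries(
    "e1", "seen", "waarschijnlijk hepatitis"))
  truth <- rbind(
    mk_truth("f1", "e1", "cholelithiasis", neg = TRUE),
    mk_truth("f2", "e1", "levercirrhose", mis = TRUE),
    mk_truth("f3", "e1", "cholestase"),
    mk_truth("f4", "e1", "hepatitis", neg = TRUE, err = TRUE)
  )
  br <- categorize_false_negatives(list(p_filter, p_spell, p_model, p_label),
                                   lex, truth)
  expect_equal(unname(br$counts["evidence_removed_by_filter"]), 1L)
  expect_equal(unname(br$counts["spelling_variant"]), 1L)
  expect_equal(unname(br$counts["evidence_not_in_model"]), 1L)
  expect_equal(unname(br$counts["labeling_error"]), 1L)
  expect_equal(sum(br$counts), br$n)
  expect_equal(sum(br$percentages), 100)

  # label error wins even when the filter also removed the evidence
  br2 <- categorize_false_negatives(list(p_label), lex, truth)
  expect_equal(unname(br2$counts["labeling_error"]), 1L)

  expect_error(categorize_false_negatives(list(p_filter), lex,
                                          truth[-1, , drop = FALSE]),
               "f1")
})
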