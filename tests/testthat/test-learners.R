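test_that("MyC finds a perfect separator and stops on uninformative features", {
  set.seed(2)
  toy <- toy_separable()
  tree <- myc_train(toy$X, toy$y)
  expect_equal(myc_predict(tree, toy$X), toy$y)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$feature, 1) # the marker column
  expect_equal(tree$root$absent$type, "leaf")
  expect_equal(tree$root$present$type, "leaf")

  # all features independent of the label -> single majority leaf
  X <- matrix(rep(c(1, 0), 8), ncol = 2)
  y <- rep(c("positive", "negative", "negative", "negative"), 2)
  tree2 <- myc_train(X, y)
  expect_equal(tree2$root$type, "leaf")
  expect_equal(tree2$root$label, "negative")

  # tie at a leaf resolves toward positive
  tree3 <- myc_train(matrix(c(1, 0), 2, 1), c("positive", "negative"),
                     alpha = 0.05)
  expect_equal(tree3$root$type, "leaf") # n=2 cannot reach significance
  expect_equal(tree3$root$label, "positive")

  expect_error(myc_train(matrix(0, 0, 2), character()), "at least one")
})

test_that("MyC agrees with an exhaustive greedy oracle on random data sets", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 20
    X <- matrix(stats::rbinom(n * 6, 1, 0.4), n, 6)
    # two nested informative features plus noise
    y <- ifelse(X[, 1] == 1 | (X[, 2] == 1 & stats::runif(n) < 0.8),
                "positive", "negative")
    if (length(unique(y)) < 2) next
    tree <- myc_train(X, y)
    oracle <- oracle_tree(X, y)
    expect_equal(myc_predict(tree, X), unname(oracle_predict(oracle, X)))
    # and on unseen random vectors
    Xnew <- matrix(stats::rbinom(40 * 6, 1, 0.5), 40, 6)
    expect_equal(myc_predict(tree, Xnew),
                 unname(oracle_predict(oracle, Xnew)))
  }
})

test_that("MyC training is invariant to example order and bounded in depth", {
  set.seed(13)
  X <- matrix(stats::rbinom(200, 1, 0.5), 40, 5)
  y <- ifelse(X[, 3] == 1, "positive",
              sample(c("positive", "negative"), 40, TRUE, c(0.2, 0.8)))
  tree <- myc_train(X, y)
  perm <- sample(40)
  tree_p <- myc_train(X[perm, ], y[perm])
  grid <- as.matrix(expand.grid(rep(list(0:1), 5)))
  expect_equal(myc_predict(tree, grid), myc_predict(tree_p, grid))
  expect_lte(casefinder:::myc_depth(tree$root), ncol(X))
})

test_that("base learner dispatch trains every family to separate a toy problem", {
  set.seed(3)
  toy <- toy_separable(8, 8)
  for (fam in c("myc", "decision_tree", "linear_margin", "rule_inducer")) {
    model <- train_base(base_learner_spec(fam), toy$X, toy$y)
    expect_s3_class(model, "trained_model")
    expect_equal(predict(model, toy$X), toy$y, info = fam)
    p <- predict(model, toy$X, type = "prob")
    expect_true(all(p >= 0 & p <= 1), info = fam)
  }
  expect_error(base_learner_spec("boosting"), "unknown base learner")
  expect_error(base_learner_spec("myc", gamma = 1), "unknown hyperparameter")
})

test_that("degenerate training inputs give a constant sensitivity-first model", {
  X <- matrix(stats::rbinom(20, 1, 0.5), 10, 2)
  m <- train_base(base_learner_spec("myc"), X, rep("negative", 10))
  expect_equal(unique(predict(m, X)), "negative")
  # no informative columns at all
  m2 <- train_base(base_learner_spec("linear_margin"),
                   matrix(numeric(0), 4, 0),
                   c("positive", "positive", "negative", "negative"))
  expect_equal(unique(predict(m2, matrix(numeric(0), 2, 0))), "positive")
})

test_that("conditional risk relabeling minimizes expected cost, ties to positive", {
  expect_equal(conditional_risk_relabel(0.3, cost_matrix(cost_fn = 10)),
               "positive") # risk(pos)=0.7 < risk(neg)=3
  expect_equal(conditional_risk_relabel(0.3, cost_matrix()), "negative")
  expect_equal(conditional_risk_relabel(0.5, cost_matrix(5, 5)), "positive")
  expect_equal(conditional_risk_relabel(c(0, 1), cost_matrix(cost_fn = 2)),
               c("negative", "positive"))
  expect_error(conditional_risk_relabel(1.2, cost_matrix()), "\\[0, 1\\]")
})

test_that("MetaCost with unit costs never relabels a correctly-voted example", {
  set.seed(8)
  sim <- generate_corpus(synthetic_config(n_positive = 15, n_negative = 60,
                                          seed = 8))
  ex <- assemble_training_set(sim$corpus, TRUE)
  lex <- default_lexicon()
  toks <- casefinder:::tokenize_many(
    vapply(ex$text, apply_assertion_filter, character(1), lexicon = lex,
           USE.NAMES = FALSE))
  vocab <- build_vocabulary(toks, ex$label)
  X <- vectorize_examples(toks, vocab)
  mc <- metacost_train(base_learner_spec("myc"), X, ex$label, cost_matrix(),
                       seed = 1)
  vote_label <- ifelse(mc$p_positive > 0.5, "positive",
                       ifelse(mc$p_positive < 0.5, "negative", NA))
  agree <- !is.na(vote_label) & vote_label == mc$original
  expect_true(all(mc$relabeled[agree] == mc$original[agree]))

  # reproducibility under a fixed seed
  mc2 <- metacost_train(base_learner_spec("myc"), X, ex$label, cost_matrix(),
                        seed = 1)
  expect_identical(mc$relabeled, mc2$relabeled)
})

test_that("positive relabels grow monotonically along the cost grid", {
  set.seed(9)
  sim <- generate_corpus(synthetic_config(n_positive = 12, n_negative = 80,
                                          seed = 9))
  ex <- assemble_training_set(sim$corpus, FALSE)
  lex <- default_lexicon()
  toks <- casefinder:::tokenize_many(
    vapply(ex$text, apply_assertion_filter, character(1), lexicon = lex,
           USE.NAMES = FALSE))
  vocab <- build_vocabulary(toks, ex$label)
  X <- vectorize_examples(toks, vocab)
  n_pos_relabels <- sapply(cost_grid(), function(cf) {
    mc <- metacost_train(base_learner_spec("myc"), X, ex$label,
                         cost_matrix(cost_fn = cf), seed = 4)
    sum(mc$relabeled == "positive")
  })
  expect_true(all(diff(n_pos_relabels) >= 0))
  # at cost 1000 every example's smoothed vote clears the relabel threshold
  expect_equal(n_pos_relabels[length(n_pos_relabels)], nrow(X))
})
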