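test_that("a plan never combines under- and over-sampling", {
  expect_error(sampling_plan(TRUE, undersample_pct = 10,
                             oversample_duplications = 2),
               "separately")
  expect_error(sampling_plan(TRUE, undersample_pct = 120), "\\[0, 100\\]")
  expect_error(sampling_plan(TRUE, oversample_duplications = 11), "\\[0, 10\\]")
  expect_s3_class(sampling_plan(FALSE, undersample_pct = 50), "sampling_plan")
})

test_that("training assembly uses seen entries, expands with implicit, never unseen", {
  corpus <- tiny_corpus()
  ex <- assemble_training_set(corpus, use_set_expansion = FALSE)
  expect_equal(nrow(ex), 3)
  expect_equal(sum(ex$label == "positive"), 2)
  expect_equal(sum(ex$label == "negative"), 1)

  ex2 <- assemble_training_set(corpus, use_set_expansion = TRUE)
  expect_equal(nrow(ex2), 6)
  expect_equal(sum(ex2$label == "positive"), 2)
  expect_equal(sum(ex2$label == "negative"), 4)
  expect_equal(sum(ex2$provenance == "implicit"), 3)
  # unseen entries of positive patients are excluded
  expect_false(any(ex2$patient_id %in% c("p1", "p2") & ex2$entry_id != "e1"))
})

test_that("assembly of a hepatobiliary-shaped corpus yields the published example counts", {
  corpus <- skeleton_corpus(656, 317, 27276)
  ex <- assemble_training_set(corpus, use_set_expansion = TRUE)
  expect_equal(sum(ex$label == "positive"), 656)
  expect_equal(sum(ex$label == "negative"), 27593) # 317 seen + 27,276 implicit
})

test_that("under-sampling removes the documented pools and spares positives", {
  hep <- shape_examples(656, 317, 27276)
  expect_identical(undersample(hep, 0, TRUE), hep)

  # expansion mode at 100%: only the seen negatives remain
  out <- undersample(hep, 100, use_set_expansion = TRUE, seed = 1)
  expect_equal(sum(out$label == "negative"), 317)
  expect_true(all(out$provenance[out$label == "negative"] == "seen_neg"))
  expect_equal(format_imbalance_ratio(imbalance_ratio(out)), 0.5)

  # no-expansion mode at 80% on the renal shape
  ren <- shape_examples(237, 3751, 0)
  out2 <- undersample(ren, 80, use_set_expansion = FALSE, seed = 1)
  expect_equal(sum(out2$label == "negative"), 750)
  expect_equal(format_imbalance_ratio(imbalance_ratio(out2)), 3)

  expect_error(undersample(hep, 101, TRUE), "\\[0, 100\\]")
})

test_that("under-sampling properties: positives and seen negatives protected, seeded draws reproducible", {
  ex <- shape_examples(30, 40, 200)
  set.seed(5)
  for (pct in c(10, 35, 50, 77, 90, 100)) {
    out <- undersample(ex, pct, use_set_expansion = TRUE, seed = pct)
    expect_equal(sum(out$label == "positive"), 30)
    expect_equal(sum(out$provenance == "seen_neg"), 40)
    expect_equal(sum(out$provenance == "implicit"),
                 200 - round(pct / 100 * 200))
    expect_identical(out, undersample(ex, pct, TRUE, seed = pct))
  }
})

test_that("over-sampling duplicates every positive deterministically", {
  hep <- shape_examples(656, 317, 27276)
  expect_identical(oversample(hep, 0), hep)

  out <- oversample(hep, 1)
  expect_equal(sum(out$label == "positive"), 1312)
  expect_equal(format_imbalance_ratio(imbalance_ratio(out)), 21)
  expect_equal(sum(out$provenance == "duplicate"), 656)
  expect_true(all(out$label[out$provenance == "duplicate"] == "positive"))

  ren <- shape_examples(237, 3751, 0)
  out2 <- oversample(ren, 4)
  expect_equal(sum(out2$label == "positive"), 1185)
  expect_equal(format_imbalance_ratio(imbalance_ratio(out2)), 3)

  expect_error(oversample(hep, 11), "\\[0, 10\\]")
})

test_that("imbalance ratio is the exact negative/positive quotient with the display convention", {
  ren <- shape_examples(237, 3751, 0)
  expect_equal(imbalance_ratio(ren), 3751 / 237)
  expect_equal(format_imbalance_ratio(imbalance_ratio(ren)), 16)

  ren_exp <- shape_examples(237, 3751, 319204)
  expect_equal(format_imbalance_ratio(imbalance_ratio(ren_exp)), 1363)

  even <- shape_examples(10, 10, 0)
  expect_equal(imbalance_ratio(even), 1)

  only_neg <- shape_examples(3, 5, 0)
  only_neg <- only_neg[only_neg$label == "negative", ]
  expect_error(imbalance_ratio(only_neg), "undefined")
})

test_that("the ratio is monotone non-increasing along both sampling grids", {
  ex <- shape_examples(25, 50, 300)
  r_us <- sapply(seq(0, 100, 10), function(p) {
    imbalance_ratio(undersample(ex, p, TRUE, seed = 9))
  })
  expect_true(all(diff(r_us) <= 0))
  r_ov <- sapply(0:10, function(d) imbalance_ratio(oversample(ex, d)))
  expect_true(all(diff(r_ov) <= 0))
})
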