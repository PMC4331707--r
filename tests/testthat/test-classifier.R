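test_that("threshold selection finds the accuracy-maximising midpoint", {
  expect_equal(select_threshold(c(900, 800), c(100, 200)), 500)
  expect_warning(t0 <- select_threshold(c(5, 5), c(5, 5)), "degenerate")
  expect_equal(t0, 5)
})

test_that("threshold selection matches an exhaustive accuracy sweep", {
  set.seed(77)
  for (i in 1:100) {
    pos <- round(runif(sample(3:20, 1), 0, 1000), 1)
    neg <- round(runif(sample(3:20, 1), 0, 1000), 1)
    thr <- select_threshold(pos, neg)
    acc <- (sum(pos > thr) + sum(neg <= thr)) / (length(pos) + length(neg))
    expect_equal(acc, brute_best_accuracy(pos, neg), tolerance = 1e-12)
  }
})

test_that("classification is strict: a score equal to the threshold is negative", {
  card <- setNames(rep(500, 400), dipeptides())
  out <- classify_sequences(card, c(q = "ILVA"), threshold = 500)
  expect_equal(as.character(out$label), "negative")
  out <- classify_sequences(card, c(q = "ILVA"), threshold = 499)
  expect_equal(as.character(out$label), "positive")
})

test_that("evaluation metrics satisfy their closed-form identities", {
  d <- make_planted(n = 40, seed = 19)
  card <- initial_card(d$positives, d$negatives)
  sp <- score_sequences(card, d$positives)
  sn <- score_sequences(card, d$negatives)
  ev <- evaluate_card(card, d$positives, d$negatives,
                      select_threshold(sp, sn))
  cts <- as.list(ev$counts)
  expect_equal(ev$accuracy, (cts$TP + cts$TN) / 80)
  expect_equal(ev$sensitivity, cts$TP / (cts$TP + cts$FN))
  expect_equal(ev$specificity, cts$TN / (cts$TN + cts$FP))
  expect_equal(ev$mcc,
               (cts$TP * cts$TN - cts$FP * cts$FN) /
                 sqrt((cts$TP + cts$FP) * (cts$TP + cts$FN) *
                        (cts$TN + cts$FP) * (cts$TN + cts$FN)))
  expect_equal(ev$auc, auc_rank(sp, sn))
})

test_that("perfect separation yields accuracy, MCC and AUC of 1", {
  pos <- setNames(rep("APAPAPAP", 10), paste0("p", 1:10))
  neg <- setNames(rep("LKLKLKLK", 10), paste0("n", 1:10))
  card <- initial_card(pos, neg)
  thr <- select_threshold(score_sequences(card, pos),
                          score_sequences(card, neg))
  ev <- evaluate_card(card, pos, neg, thr)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$mcc, 1)
  expect_equal(ev$auc, 1)
})

test_that("random scores on balanced labels give near-zero MCC", {
  set.seed(55)
  card <- setNames(runif(400, 0, 1000), dipeptides())
  d <- simulate_dataset(250, 250, c(30, 50), seed = 56)
  sp <- score_sequences(card, d$positives)
  sn <- score_sequences(card, d$negatives)
  ev <- evaluate_card(card, d$positives, d$negatives, stats::median(c(sp, sn)))
  expect_lt(abs(ev$mcc), 0.1)
})

test_that("ROC points are monotone and integrate to the rank AUC", {
  # perfect separation passes through (0, 1)
  roc <- roc_points(c(9, 8), c(1, 2))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc_trapezoid(roc), 1)
  expect_equal(roc_auc_trapezoid(roc_points(5, 3)), 1)

  set.seed(91)
  for (i in 1:20) {
    pos <- runif(25); neg <- runif(25)   # continuous, ties absent
    roc <- roc_points(pos, neg)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
    expect_equal(roc_auc_trapezoid(roc), auc_rank(pos, neg),
                 tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(95)
  pos <- runif(30, 0, 1000); neg <- runif(30, 0, 1000)
  a0 <- auc_rank(pos, neg)
  expect_equal(auc_rank(log1p(pos), log1p(neg)), a0)
  expect_equal(auc_rank(pos^3, neg^3), a0)
  expect_equal(auc_rank(pos / 1000 - 2, neg / 1000 - 2), a0)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  pos <- sample(1:50, 40, replace = TRUE)
  neg <- sample(1:50, 35, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(40, 35)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(auc_rank(pos, neg), ref, tolerance = 1e-12)
})
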