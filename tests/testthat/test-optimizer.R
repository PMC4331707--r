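test_that("pearson_r matches the closed form and validates its input", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearson_r(x, y), brute_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("rank AUC equals exhaustive pairwise comparison, ties at half", {
  expect_equal(auc_rank(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_rank(2, 2), 0.5)
  set.seed(17)
  for (i in 1:30) {
    pos <- sample(1:10, 12, replace = TRUE)   # integer scores force ties
    neg <- sample(1:10, 9, replace = TRUE)
    expect_equal(auc_rank(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
  expect_error(auc_rank(numeric(), 1:3), "undefined")
})

test_that("fitness combines CV AUC and anchor correlation exactly", {
  d <- make_planted(n = 40, seed = 2)
  card <- initial_card(d$positives, d$negatives)
  f <- scm_fitness(card, d$positives, d$negatives, control = scm_control(),
                   seed = 9)
  expect_equal(f$fitness, 0.9 * f$auc + 0.1 * f$r, tolerance = 1e-12)
  expect_equal(f$r, 1)                      # card anchored to itself
  expect_true(f$auc > 0.5 && f$auc <= 1)
  # identical folds, identical result
  f2 <- scm_fitness(card, d$positives, d$negatives, seed = 9)
  expect_identical(f, f2)
})

test_that("a perfectly separating card reaches the fitness upper bound", {
  pos <- rep(c(p1 = "APAPAPAPAPAP"), 12)
  neg <- rep(c(n1 = "LKLKLKLKLKLK"), 12)
  names(pos) <- paste0("p", 1:12); names(neg) <- paste0("n", 1:12)
  card <- initial_card(pos, neg)
  f <- scm_fitness(card, pos, neg, control = scm_control(cv_folds = 4),
                   seed = 1)
  expect_equal(f$auc, 1)
  expect_equal(f$fitness, 1, tolerance = 1e-12)
})

test_that("a random card on null data has chance-level CV AUC", {
  d <- simulate_dataset(100, 100, c(60, 80), seed = 13)
  set.seed(14)
  card <- setNames(runif(400, 0, 1000), dipeptides())
  f <- scm_fitness(card, d$positives, d$negatives, seed = 15)
  expect_lt(abs(f$auc - 0.5), 0.05)
})

test_that("zero generations returns the initial card unchanged", {
  d <- make_planted(n = 30, seed = 3)
  card <- initial_card(d$positives, d$negatives)
  opt <- scm_optimize(card, d$positives, d$negatives,
                      scm_control(generations = 0L), seed = 4)
  expect_identical(opt$scores, card)
  expect_identical(opt$fitness, opt$initial_fitness)
})

test_that("the GA is reproducible, elitist, and bound-respecting", {
  d <- make_planted(n = 30, seed = 6)
  card <- initial_card(d$positives, d$negatives)
  ctl <- scm_control(pop_size = 8L, generations = 6L)
  o1 <- scm_optimize(card, d$positives, d$negatives, ctl, seed = 21)
  o2 <- scm_optimize(card, d$positives, d$negatives, ctl, seed = 21)
  expect_identical(o1$scores, o2$scores)
  expect_identical(o1$trace, o2$trace)
  # elitism: the trace never decreases and never drops below the start
  expect_true(all(diff(o1$trace$best_fitness) >= 0))
  expect_gte(o1$fitness$fitness, o1$initial_fitness$fitness)
  expect_true(all(o1$scores >= 0 & o1$scores <= 1000))
  expect_equal(o1$fitness$fitness,
               0.9 * o1$fitness$auc + 0.1 * o1$fitness$r, tolerance = 1e-12)
})

test_that("with all weight on the anchor term the initial card stays optimal", {
  d <- make_planted(n = 24, seed = 8)
  card <- initial_card(d$positives, d$negatives)
  ctl <- scm_control(pop_size = 6L, generations = 5L, w1 = 0, w2 = 1)
  o <- scm_optimize(card, d$positives, d$negatives, ctl, seed = 30)
  expect_equal(o$initial_fitness$fitness, 1)
  expect_equal(o$fitness$fitness, 1)       # r = 1 is the maximum; never degraded
  expect_equal(o$fitness$r, 1)
})

test_that("stratified folds keep both classes represented", {
  # the smallest legal layout: every fold must still hold one of each class
  pos <- c(p1 = "APAPAP", p2 = "APAPAA")
  neg <- c(n1 = "LKLKLK", n2 = "KLKLKL", n3 = "LLKKLL", n4 = "KKLLKK")
  expect_no_warning(
    f <- scm_fitness(initial_card(pos, neg), pos, neg,
                     control = scm_control(cv_folds = 2L), seed = 1))
  expect_true(is.finite(f$auc))
  expect_error(scm_fitness(initial_card(pos, neg), pos, neg,
                           control = scm_control(cv_folds = 3L), seed = 1),
               "exceeds")
})
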