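test_that("weighted accuracy matches its printed examples", {
  # all correct -> 1
  cm <- murmur_confusion(c("Present", "Unknown", "Absent"),
                         c("Present", "Unknown", "Absent"))
  expect_equal(weighted_accuracy(cm), 1)
  # 3 true Present all correct, one true Absent predicted Present -> 15/16
  cm2 <- murmur_confusion(c("Present", "Present", "Present", "Present"),
                          c("Present", "Present", "Present", "Absent"))
  expect_equal(weighted_accuracy(cm2), 15 / 16)
  # unit weights reduce to plain accuracy
  set.seed(1)
  pred <- sample(c("Present", "Unknown", "Absent"), 60, replace = TRUE)
  truth <- sample(c("Present", "Unknown", "Absent"), 60, replace = TRUE)
  cm3 <- murmur_confusion(pred, truth)
  expect_equal(weighted_accuracy(cm3, weights = c(1, 1, 1)),
               mean(pred == truth))
  expect_error(weighted_accuracy(murmur_confusion(character(0),
                                                  character(0))), "empty")
})

test_that("weighted accuracy equals a brute-force weighted sum on random confusions", {
  # oracle: enumerate labeled examples explicitly and apply the weights
  set.seed(7)
  for (i in 1:1000) {
    m <- matrix(rpois(9, 4), 3, 3)
    if (sum(m) == 0) next
    truth <- rep(rep(c("Present", "Unknown", "Absent"), each = 3), as.vector(m))
    pred <- rep(rep(c("Present", "Unknown", "Absent"), times = 3), as.vector(m))
    w_of <- c(Present = 5, Unknown = 3, Absent = 1)
    oracle <- sum(w_of[truth] * (pred == truth)) / sum(w_of[truth])
    cm <- murmur_confusion(pred, truth)
    expect_equal(weighted_accuracy(cm), oracle, tolerance = 1e-12)
  }
})

test_that("weighted accuracy is 1 iff the confusion is diagonal", {
  set.seed(2)
  for (i in 1:50) {
    cls <- c("Present", "Unknown", "Absent")
    m <- matrix(rpois(9, 2), 3, 3, dimnames = list(predicted = cls,
                                                   truth = cls))
    if (sum(m) == 0) next
    acc <- weighted_accuracy(m)
    expect_gte(acc, 0); expect_lte(acc, 1)
    if (sum(m) > 0 && all(m[row(m) != col(m)] == 0)) expect_equal(acc, 1)
    if (any(m[row(m) != col(m)] > 0)) expect_lt(acc, 1)
  }
})

test_that("outcome cost follows the component formula", {
  zero <- cost_params(function(n) 0, function(s, n) 0,
                      function(t) 0, function(f) 0)
  cnt <- list(n_tp = 3, n_fp = 2, n_fn = 1, n_tn = 4, n_patients = 10)
  expect_equal(outcome_cost(cnt, zero), 0)
  # linear test costs -> (100 + 1000 + 1000 + 10000) / 10 = 1210
  lin <- cost_params(
    c_algorithm = function(n) 10 * n,
    c_expert = function(s, n) 500 * s,
    c_treatment = function(t) 1000 * t,
    c_error = function(f) 10000 * f)
  cnt2 <- list(n_tp = 1, n_fp = 1, n_fn = 1, n_tn = 7, n_patients = 10)
  expect_equal(outcome_cost(cnt2, lin), 1210)
  # doubling counts under homogeneous linear costs leaves the mean unchanged
  cnt3 <- lapply(cnt2, `*`, 2)
  expect_equal(outcome_cost(cnt3, lin), 1210)
})

test_that("outcome cost is monotone in false negatives for monotone c_error", {
  lin <- cost_params()
  base <- list(n_tp = 2, n_fp = 2, n_fn = 0, n_tn = 6, n_patients = 10)
  costs <- vapply(0:5, function(fn) {
    cnt <- base; cnt$n_fn <- fn
    outcome_cost(cnt, lin)
  }, numeric(1))
  expect_true(all(diff(costs) >= 0))
})

test_that("outcome counts tally decisions correctly", {
  oc <- outcome_counts(c("Abnormal", "Abnormal", "Normal", "Normal"),
                       c("Abnormal", "Normal", "Abnormal", "Normal"))
  expect_equal(oc$n_tp, 1); expect_equal(oc$n_fp, 1)
  expect_equal(oc$n_fn, 1); expect_equal(oc$n_tn, 1)
  expect_equal(oc$n_patients, 4)
})

test_that("AUROC: perfect separation, chance level, and pair-count oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  set.seed(3)
  n <- 1e4
  sc <- stats::runif(n); lb <- rep(0:1, n / 2)
  expect_lt(abs(auroc(sc, lb) - 0.5), 0.02)
  # brute force over all positive/negative pairs at n <= 50
  for (rep in 1:5) {
    s <- stats::rnorm(30); y <- sample(0:1, 30, replace = TRUE,
                                       prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    pos <- s[y == 1]; neg <- s[y == 0]
    oracle <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, y), oracle, tolerance = 1e-12)
  }
  expect_true(is.na(auroc(1:5, rep(1, 5))))
})

test_that("AUPRC step interpolation and F1 behave on known cases", {
  # perfect ranking: AUPRC = 1
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all-positive labels give AUPRC 1, no positives give NA
  expect_equal(auprc(runif(5), rep(1, 5)), 1)
  expect_true(is.na(auprc(runif(5), rep(0, 5))))
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 0, 1, 0), positive = "1"), 0.5)
  # macro F1 over three classes
  expect_equal(f1_score(c("a", "b", "c"), c("a", "b", "c")), 1)
})

test_that("standard_metrics handles vector and matrix scores", {
  set.seed(4)
  m <- standard_metrics(c(0.9, 0.7, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(m$auroc, 1); expect_equal(m$accuracy, 1)
  probs <- matrix(c(0.7, 0.2, 0.1,
                    0.1, 0.8, 0.1,
                    0.2, 0.2, 0.6), 3, byrow = TRUE,
                  dimnames = list(NULL, c("Present", "Unknown", "Absent")))
  mm <- standard_metrics(probs, c("Present", "Unknown", "Absent"))
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$f1, 1)
})
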