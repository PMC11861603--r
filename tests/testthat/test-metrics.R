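test_that("the binary worked example gives precision/recall 0.75, accuracy 0.8", {
  # 10 samples: positives -> 3 TP + 1 FN; negatives -> 1 FP + 5 TN
  y <- c(rep(1, 4), rep(2, 6))
  p1 <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.2)
  prob <- cbind(p1, 1 - p1)
  rep <- compute_metrics(y, prob)
  expect_equal(rep$per_class$precision[1], 0.75)
  expect_equal(rep$per_class$recall[1], 0.75)
  expect_equal(rep$accuracy, 0.8)
  expect_equal(rep$confusion[1, 1], 3L)
  expect_equal(rep$confusion[2, 1], 1L)
  expect_equal(rep$confusion[1, 2], 1L)
  expect_equal(rep$confusion[2, 2], 5L)
})

test_that("perfect predictions yield unit metrics and a diagonal confusion", {
  y <- rep(1:4, each = 5)
  prob <- matrix(0.01, 20, 4); prob[cbind(1:20, y)] <- 0.97
  rep <- compute_metrics(y, prob)
  expect_equal(rep$top1_accuracy, 1)
  expect_equal(rep$top3_accuracy, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$roc_auc, 1)
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0))
  expect_equal(sum(rep$confusion), rep$n_samples)
})

test_that("macro metrics and AUC match brute-force oracles on random input", {
  set.seed(77)
  n <- 500; K <- 15
  y <- sample.int(K, n, replace = TRUE)
  raw <- matrix(rexp(n * K), n, K)
  # tilt probabilities toward the truth so predictions are non-trivial
  raw[cbind(1:n, y)] <- raw[cbind(1:n, y)] + runif(n, 0, 2)
  prob <- raw / rowSums(raw)
  rep <- compute_metrics(y, prob)
  o <- brute_metrics(y, prob)
  expect_equal(rep$top1_accuracy, o$top1, tolerance = 1e-12)
  expect_equal(rep$top3_accuracy, o$top3, tolerance = 1e-12)
  expect_equal(rep$precision, o$precision, tolerance = 1e-12)
  expect_equal(rep$recall, o$recall, tolerance = 1e-12)
  sub <- 1:200
  rep200 <- compute_metrics(y[sub], prob[sub, ])
  expect_equal(rep200$roc_auc, brute_macro_auc(y[sub], prob[sub, ]),
               tolerance = 1e-9)
})

test_that("metric invariants hold across random prediction sets", {
  set.seed(42)
  for (i in 1:5) {
    K <- sample(3:8, 1); n <- 60
    y <- sample.int(K, n, replace = TRUE)
    prob <- matrix(runif(n * K), n, K); prob <- prob / rowSums(prob)
    rep <- compute_metrics(y, prob)
    expect_gte(rep$top3_accuracy, rep$top1_accuracy)
    expect_true(all(unlist(rep[c("top1_accuracy", "top3_accuracy",
                                 "precision", "recall", "roc_auc")]) >= 0))
    expect_true(all(unlist(rep[c("top1_accuracy", "top3_accuracy",
                                 "precision", "recall", "roc_auc")]) <= 1))
    expect_equal(sum(rep$confusion), n)
  }
})

test_that("compute_metrics validates its inputs", {
  y <- c(1, 2)
  expect_error(compute_metrics(y, matrix(c(0.9, 0.4, 0.3, 0.4), 2)), "sum to 1")
  expect_error(compute_metrics(c(1, 2, 1), matrix(0.5, 2, 2)), "match")
  expect_error(compute_metrics(c(1, 1), matrix(0.5, 2, 2)), "degenerate")
  expect_error(compute_metrics(c(1, 3), matrix(0.5, 2, 2)), "1..K")
})
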