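test_that("branch topology: 64->2 spatial chain, 256 flatten, 1024 features", {
  m <- build_single(5, seed = 2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  f <- branch_features(m, x)
  expect_equal(dim(f), c(1024L, 2L))
  # the flatten layer saw a (2, 2, 64, N) map
  flat <- Filter(function(l) l$type == "flatten", m$branches[[1]])[[1]]
  expect_equal(flat$xdim[1:3], c(2L, 2L, 64L))
  # spatial chain halves at every block
  pools <- Filter(function(l) l$type == "pool", m$branches[[1]])
  expect_length(pools, 5)
})

test_that("fusion head: 3072-dim concatenation, 256 units, softmax rows", {
  m <- build_fusion(fusion_spec(7), seed = 3)
  expect_length(m$branches, 3)
  expect_equal(nrow(m$head[[1]]$W), 3072L)
  expect_equal(ncol(m$head[[1]]$W), 256L)
  expect_equal(ncol(m$head[[3]]$W), 7L)
  xs <- lapply(1:3, function(i) array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4)))
  p <- predict(m, xs)
  expect_equal(dim(p), c(4L, 7L))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("parameter count is bounded and matches direct arithmetic", {
  m <- build_fusion(fusion_spec(15), seed = 1)
  n <- count_params(m)
  expect_lte(n, 5e6)
  conv_p <- function(cin, cout) 9 * cin * cout + cout
  branch <- conv_p(3, 32) + conv_p(32, 64) + conv_p(64, 128) +
    conv_p(128, 128) + conv_p(128, 64) + (256 * 1024 + 1024)
  head <- (3072 * 256 + 256) + (256 * 15 + 15)
  expect_equal(n, 3 * branch + head)
})

test_that("input shape mismatches raise named errors", {
  m <- build_single(3, seed = 1)
  bad <- array(0, c(32, 64, 3, 1))
  expect_error(predict(m, bad), "shape mismatch")
  b <- build_baseline_1d(3, seed = 1)
  expect_error(predict(b, array(0, c(64, 64, 3, 1))), "shape mismatch")
})

test_that("the 1-D baseline accepts raw segments and validates divisibility", {
  b <- build_baseline_1d(4, segment_length = 2500, seed = 5)
  x <- array(rnorm(2500 * 3 * 3), c(1, 2500, 3, 3))
  p <- predict(b, x)
  expect_equal(dim(p), c(3L, 4L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_length(b$branches, 1)
  expect_error(build_baseline_1d(4, segment_length = 2501),
               "not divisible")
})

test_that("a zeroed branch still yields valid distributions", {
  m <- build_fusion(fusion_spec(4), seed = 8)
  xs <- lapply(1:3, function(i) array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  xs[[2]] <- xs[[2]] * 0
  p <- predict(m, xs)
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})

test_that("softmax argmax is invariant under strictly monotone logit maps", {
  set.seed(6)
  z <- matrix(rnorm(15 * 10), 15, 10)
  p1 <- actifuse:::softmax_cols(z)
  p2 <- actifuse:::softmax_cols(2.5 * z + 3)
  expect_identical(max.col(t(p1)), max.col(t(p2)))
  expect_equal(colSums(p1), rep(1, 10), tolerance = 1e-12)
})

test_that("plateau schedule reproduces 0.005 * 0.7^2 after two stagnations", {
  # epoch 1 improves from Inf; stagnation triggers reductions applied from
  # epochs 5 and 8
  lrs <- plateau_lr_sequence(rep(1, 8), lr0 = 0.005, factor = 0.7, patience = 3)
  expect_equal(lrs[8], 0.005 * 0.7^2)
  expect_equal(lrs[5], 0.005 * 0.7)
  # an improvement resets the wait counter
  lrs2 <- plateau_lr_sequence(c(1, 0.9, 0.95, 0.96, 0.8, 0.85, 0.9), 0.005, 0.7, 3)
  expect_equal(lrs2, rep(0.005, 7))
})

test_that("the network can memorize a small sample (capacity check)", {
  set.seed(7)
  n <- 8
  x <- array(runif(64 * 64 * 3 * n), c(64, 64, 3, n))
  y <- rep(1:4, 2)
  m <- build_single(4, seed = 7)
  m <- train_model(m, x, y, x, y, train_config(epochs = 30, seed = 7))
  expect_equal(tail(m$history$train_acc, 1), 1)
})

test_that("a linearly separable toy reaches perfect accuracy within 20 epochs", {
  # spatially constant images, one colour per class (kept non-colinear so
  # the classes stay separable through near-affine activations)
  n_per <- 2
  x <- array(0, c(64, 64, 3, 3 * n_per))
  cols <- rbind(c(0.9, 0.1, 0.1), c(0.1, 0.9, 0.1), c(0.1, 0.1, 0.9))
  for (k in 1:3) for (j in 1:n_per) for (c in 1:3)
    x[, , c, (k - 1) * n_per + j] <- cols[k, c]
  y <- rep(1:3, each = n_per)
  m <- build_single(3, seed = 9)
  m <- train_model(m, x, y, x, y, train_config(epochs = 20, seed = 9))
  expect_equal(tail(m$history$train_acc, 1), 1)
})

test_that("training is deterministic given the seed and records history", {
  ds <- tiny_dataset(classes = c("WK", "FF"), n_subjects = 4, reps = 2)
  split <- split_by_subject(ds, 0.25, 0.34, seed = 2)
  data <- prepare_har_data(split, methods = "rp", with_series = FALSE)
  cfg <- train_config(epochs = 2, seed = 31)
  m1 <- fit_har_condition(data, "rp", cfg)
  m2 <- fit_har_condition(data, "rp", cfg)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_named(m1$history,
               c("epoch", "lr", "train_loss", "train_acc", "val_loss", "val_acc"))
  expect_equal(nrow(m1$history), 2)
})

test_that("train_model rejects empty data and labels outside the taxonomy", {
  m <- build_single(3, seed = 1)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_error(train_model(m, x, c(1, 5), x, c(1, 2), train_config(epochs = 1)),
               "taxonomy")
  expect_error(train_model(m, x, 1L, x, c(1, 2), train_config(epochs = 1)),
               "mismatch")
})

test_that("checkpoints round-trip through disk with their sidecar", {
  m <- build_single(3, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  expect_identical(predict(back, x), predict(m, x))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_classes, 3)
})
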