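test_that("segment_signal cuts non-overlapping windows and drops remainders", {
  mk <- function(n) matrix(seq_len(3 * n), ncol = 3)
  expect_length(segment_signal(mk(7500), 250, 10), 3)
  expect_length(segment_signal(mk(2250), 250, 10), 0)
  s <- segment_signal(mk(6250), 250, 10, subject_id = "S9", label = "WK")
  expect_length(s, 2)
  expect_equal(dim(s[[1]]$samples), c(2500L, 3L))
  expect_equal(s[[2]]$segment_index, 2L)
  expect_equal(s[[2]]$subject_id, "S9")
  # concatenation reproduces the first floor(N/L)*L rows exactly
  rebuilt <- do.call(rbind, lapply(s, function(x) x$samples))
  expect_identical(unname(rebuilt), unname(mk(6250)[1:5000, ] * 1.0))
})

test_that("segment_signal rejects non-finite input and bad parameters", {
  bad <- matrix(1, 100, 3); bad[5, 2] <- NA
  expect_error(segment_signal(bad, 250, 10), "non-finite")
  expect_error(segment_signal(matrix(1, 10, 3), -1, 10), "positive")
  expect_error(accel_segment(matrix(Inf, 10, 3)), "non-finite")
})

test_that("split_by_subject is subject-disjoint, exhaustive and seeded", {
  segs <- unlist(lapply(sprintf("P%02d", 1:20), function(sid)
    segment_signal(matrix(rnorm(3 * 5000), ncol = 3), 250, 10,
                   subject_id = sid, label = "WK")), recursive = FALSE)
  for (seed in 1:100) {
    sp <- split_by_subject(segs, 0.2, 0.25, seed = seed)
    expect_length(intersect(sp$test_subjects,
                            c(sp$train_subjects, sp$val_subjects)), 0)
    expect_length(intersect(sp$train_subjects, sp$val_subjects), 0)
  }
  sp <- split_by_subject(segs, 0.2, 0.25, seed = 7)
  # fractions apply to subject counts: 4 test, 4 val, 12 train
  expect_length(sp$test_subjects, 4)
  expect_length(sp$val_subjects, 4)
  expect_length(sp$train_subjects, 12)
  # exhaustive and disjoint over segments
  expect_equal(length(sp$train) + length(sp$validation) + length(sp$test),
               length(segs))
  sp2 <- split_by_subject(segs, 0.2, 0.25, seed = 7)
  expect_identical(sp$test_subjects, sp2$test_subjects)
  expect_identical(sp$train_subjects, sp2$train_subjects)
  few <- segs[1:2]
  expect_error(split_by_subject(few, 0.2, 0.25, 1), "at least 3")
})

test_that("add_gaussian_noise has the stated sd, determinism and purity", {
  seg <- toy_segment(seed = 5)
  expect_identical(add_gaussian_noise(seg, 0, 1)$samples, seg$samples)
  noisy <- add_gaussian_noise(seg, 275, seed = 42)
  expect_lt(abs(sd(noisy$samples - seg$samples) - 275) / 275, 0.05)
  expect_identical(noisy$samples, add_gaussian_noise(seg, 275, seed = 42)$samples)
  expect_false(identical(noisy$samples,
                         add_gaussian_noise(seg, 275, seed = 43)$samples))
  expect_identical(noisy$fs, seg$fs)
  expect_identical(noisy$label, seg$label)
  expect_identical(noisy$subject_id, seg$subject_id)
  expect_identical(dim(noisy$samples), dim(seg$samples))
  expect_error(add_gaussian_noise(seg, -1, 1), "non-negative")
})

test_that("dataset_sigma pools all values with a two-pass variance", {
  const <- accel_segment(matrix(7, 2500, 3))
  expect_equal(dataset_sigma(list(const)), 0)
  set.seed(9)
  vals <- rnorm(100020)
  segs <- lapply(split(vals, rep(1:20, each = 5001)), function(v)
    accel_segment(matrix(v, ncol = 3), fs = 250))
  expect_lt(abs(dataset_sigma(segs) - 1), 0.02)
  # brute-force two-pass oracle on a 100-value fixture
  set.seed(10)
  fix <- matrix(rnorm(99, 5, 3), 33, 3)
  seg <- accel_segment(fix)
  expect_equal(dataset_sigma(list(seg)), sd(as.vector(fix)), tolerance = 1e-10)
  expect_error(dataset_sigma(list()), "empty")
})

test_that("segments survive a CSV round trip", {
  segs <- list(toy_segment(f = 2, seed = 1, subject = "A", label = "WK"),
               toy_segment(seed = 2, subject = "B", label = "FF"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(segs, path)
  back <- read_segments_csv(path)
  expect_length(back, 2)
  ord <- order(vapply(back, function(s) s$subject_id, character(1)))
  back <- back[ord]
  for (i in 1:2) {
    expect_equal(unname(back[[i]]$samples), unname(segs[[i]]$samples))
    expect_identical(back[[i]]$label, segs[[i]]$label)
    expect_identical(back[[i]]$fs, segs[[i]]$fs)
  }
})
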