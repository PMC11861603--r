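# Independent oracles and small fixture builders used across the suite.

# Direct DFT of one frame: X[w] = sum_n x[n] exp(-i 2 pi w n / L).
naive_dft_power <- function(frame) {
  L <- length(frame)
  nb <- L %/% 2 + 1
  vapply(0:(nb - 1), function(w) {
    ex <- exp(-2i * pi * w * (0:(L - 1)) / L)
    Mod(sum(frame * ex))^2
  }, numeric(1))
}

# Frame-by-frame STFT power oracle (matches the documented conventions).
naive_stft_power <- function(series, L, H, window = "hann") {
  win <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  else rep(1, L)
  n_frames <- (length(series) - L) %/% H + 1
  sapply(seq_len(n_frames), function(m)
    naive_dft_power(series[((m - 1) * H + 1):((m - 1) * H + L)] * win))
}

# Brute-force multiclass metrics from first principles.
brute_metrics <- function(y, prob) {
  K <- ncol(prob); n <- nrow(prob)
  pred <- integer(n)
  for (i in 1:n) pred[i] <- which(prob[i, ] == max(prob[i, ]))[1]
  prec <- rec <- numeric(K)
  for (k in 1:K) {
    tp <- sum(pred == k & y == k)
    fp <- sum(pred == k & y != k)
    fn <- sum(pred != k & y == k)
    prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  top3 <- mean(sapply(1:n, function(i) {
    ord <- order(prob[i, ], decreasing = TRUE)
    y[i] %in% ord[1:min(3, K)]
  }))
  list(top1 = mean(pred == y), top3 = top3,
       precision = mean(prec), recall = mean(rec))
}

# Rank-based one-vs-rest AUC (equivalent to enumerating all thresholds,
# with ties credited 1/2), macro-averaged.
brute_macro_auc <- function(y, prob) {
  K <- ncol(prob)
  aucs <- c()
  for (k in 1:K) {
    pos <- prob[y == k, k]; neg <- prob[y != k, k]
    if (length(pos) == 0 || length(neg) == 0) next
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    aucs <- c(aucs, mean(cmp))
  }
  mean(aucs)
}

# A quick deterministic segment with controllable content.
toy_segment <- function(f = NULL, n = 2500, fs = 250, seed = 1,
                        label = "WK", subject = "S1") {
  set.seed(seed)
  t <- (0:(n - 1)) / fs
  x <- matrix(rnorm(3 * n, 0, 20), n, 3)
  if (!is.null(f))
    x <- x + cbind(300 * sin(2 * pi * f * t), 200 * cos(2 * pi * f * t),
                   500 * sin(2 * pi * f * t + 1))
  x[, 3] <- x[, 3] + 980
  accel_segment(x, fs = fs, subject_id = subject, label = label)
}

# Small subject-grouped synthetic problem shared by training tests.
tiny_dataset <- function(classes = c("WK", "JR", "FF"), n_subjects = 6,
                         reps = 2, seed = 3) {
  simulate_dataset(synthetic_config(classes = classes,
                                    n_subjects = n_subjects,
                                    reps_per_class = reps, seed = seed))
}
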