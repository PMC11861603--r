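test_that("stft frame and bin counts follow the documented formulas", {
  x <- rnorm(2500)
  P <- stft_magnitude(x, 250, spectrogram_config(window_seconds = 5))
  expect_equal(dim(P), c(1250 %/% 2 + 1, 3))  # L=1250, H=625 -> 3 frames
  P1 <- stft_magnitude(x, 250, spectrogram_config(window_seconds = 10))
  expect_equal(ncol(P1), 1)                  # degenerate single frame
  expect_equal(nrow(P1), 1251)
  P2 <- stft_magnitude(x, 250, spectrogram_config(window_seconds = 1,
                                                  overlap_fraction = 0.5))
  expect_equal(ncol(P2), (2500 - 250) %/% 125 + 1)
  expect_error(stft_magnitude(rnorm(100), 250,
                              spectrogram_config(window_seconds = 1)),
               "shorter")
})

test_that("stft of a zero series is identically zero", {
  P <- stft_magnitude(numeric(500), 250, spectrogram_config(window_seconds = 1))
  expect_true(all(P == 0))
})

test_that("a 10 Hz sinusoid at fs=250 peaks at frequency bin 10", {
  t <- (0:2499) / 250
  x <- sin(2 * pi * 10 * t)
  P <- stft_magnitude(x, 250, spectrogram_config(window_seconds = 1,
                                                 window = "rectangular"))
  for (m in seq_len(ncol(P)))
    expect_equal(which.max(P[, m]), 11L)  # bin 10 with 0-based indexing
})

test_that("stft matches the naive per-frame DFT oracle", {
  set.seed(4)
  for (win in c("hann", "rectangular")) {
    x <- rnorm(64)
    cfg <- spectrogram_config(window_seconds = 16 / 250, overlap_fraction = 0.5,
                              window = win)
    P <- stft_magnitude(x, 250, cfg)
    O <- naive_stft_power(x, L = 16, H = 8, window = win)
    expect_lt(max(abs(P - O)) / max(O), 1e-8)
  }
})

test_that("spectrogram images satisfy the output contract", {
  seg <- toy_segment(f = 3, seed = 6)
  img <- spectrogram_image(seg)
  expect_s3_class(img, "recon_image")
  expect_identical(dim(img$pixels), c(64L, 64L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  expect_identical(img$method, "spectrogram")
  expect_identical(img$source$label, "WK")
  # purity: identical input -> bit-identical output
  expect_identical(img$pixels, spectrogram_image(seg)$pixels)
})

test_that("a silent segment maps to a spatially uniform spectrogram image", {
  seg <- accel_segment(matrix(0, 2500, 3))
  img <- spectrogram_image(seg)
  expect_equal(length(unique(as.vector(matrix(img$pixels, ncol = 3)))), 3)
  for (k in 1:3) expect_equal(length(unique(as.vector(img$pixels[, , k]))), 1)
})

test_that("window sweep configurations cover 1/2/5/10 s with half overlap", {
  for (ws in c(1, 2, 5, 10)) {
    cfg <- spectrogram_config(window_seconds = ws)
    expect_equal(cfg$overlap_fraction, 0.5)
    img <- spectrogram_image(toy_segment(f = 2, seed = ws), cfg)
    expect_identical(dim(img$pixels), c(64L, 64L, 3L))
  }
})
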