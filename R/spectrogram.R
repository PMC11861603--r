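#' Spectrogram configuration
#'
#' Parameters of the STFT spectrogram encoding. The window length is given
#' in seconds (1, 2, 5 or 10 at 250 Hz in the window-size sweep); frames
#' overlap by `overlap_fraction` of the window (default one half). With the
#' default 10 s window on a 10 s segment the spectrogram degenerates to a
#' single frame, which is the best-performing configuration of the method.
#'
#' @param window_seconds STFT window length in seconds (default 10).
#' @param overlap_fraction fraction of window overlap, in \[0, 1) (default 0.5).
#' @param log_scale logical: convert power to decibels (10*log10, floored at
#'   1e-12) before normalisation (default TRUE).
#' @param colormap name of the 256-entry colour lookup table (`"viridis"`
#'   default, `"gray"` for grayscale replication).
#' @param window window function: `"hann"` (default) or `"rectangular"`.
#' @return Object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window_seconds = 10, overlap_fraction = 0.5,
                               log_scale = TRUE, colormap = "viridis",
                               window = c("hann", "rectangular")) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  if (window_seconds <= 0) stop("`window_seconds` must be positive", call. = FALSE)
  structure(list(window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction, log_scale = log_scale,
                 colormap = colormap, window = match.arg(window)),
            class = "spectrogram_config")
}

#' STFT power spectrogram of one series
#'
#' Computes the squared magnitude of the short-time Fourier transform: the
#' series is cut into frames of length `L = round(window_seconds * fs)` with
#' hop `H = round(L * (1 - overlap_fraction))`, each frame is multiplied by
#' the window function and Fourier transformed, and the one-sided power
#' `|X(m, w)|^2` is returned.
#'
#' @param series numeric vector, length >= window length.
#' @param fs sampling rate in Hz.
#' @param cfg a [spectrogram_config()].
#' @return Numeric matrix of dim `(floor(L/2) + 1, floor((N - L)/H) + 1)`:
#'   frequency bins (0 .. Nyquist) by frames.
#' @export
stft_magnitude <- function(series, fs, cfg = spectrogram_config()) {
  N <- length(series)
  L <- as.integer(round(cfg$window_seconds * fs))
  H <- as.integer(round(L * (1 - cfg$overlap_fraction)))
  if (H < 1L) H <- 1L
  if (N < L)
    stop("series shorter than the STFT window", call. = FALSE)
  win <- if (cfg$window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  } else rep(1, L)
  n_frames <- (N - L) %/% H + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  frames <- vapply(starts, function(s) series[(s + 1):(s + L)] * win,
                   numeric(L))
  X <- stats::mvfft(matrix(frames, nrow = L))
  n_bins <- L %/% 2L + 1L
  P <- Mod(X[seq_len(n_bins), , drop = FALSE])^2
  dimnames(P) <- NULL
  P
}

#' Spectrogram image of a segment
#'
#' Computes the power spectrogram of each axis, converts to decibels when
#' `log_scale`, horizontally stacks the x, y and z spectrograms into a
#' single matrix (frequency on the vertical axis, time-by-axis on the
#' horizontal), jointly min-max normalises, maps through the colour lookup
#' table, resizes bilinearly to 64 x 64 and quantizes to 8 bits. Frequency
#' increases downward in pixel rows (row 1 = DC).
#'
#' @inheritParams stft_magnitude
#' @param segment an [accel_segment()].
#' @return A [recon_image()] with `method = "spectrogram"`.
#' @export
spectrogram_image <- function(segment, cfg = spectrogram_config()) {
  stopifnot(inherits(segment, "accel_segment"))
  specs <- lapply(1:3, function(k)
    stft_magnitude(segment$samples[, k], segment$fs, cfg))
  stacked <- do.call(cbind, specs)
  if (cfg$log_scale) stacked <- 10 * log10(pmax(stacked, 1e-12))
  norm <- minmax01(stacked)
  rgb <- apply_colormap(norm, make_colormap(cfg$colormap))
  img <- quantize8(resize_bilinear(rgb))
  recon_image(img, "spectrogram",
              source = list(subject_id = segment$subject_id,
                            label = segment$label,
                            segment_index = segment$segment_index))
}
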