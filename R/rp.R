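#' Recurrence-plot configuration
#'
#' The classical recurrence plot thresholds the pairwise distance matrix
#' through a Heaviside step; here the binarisation is omitted and the
#' distance matrix is used directly, so the full distance structure is kept.
#' The 2500-sample series is block-averaged down to `downsample_length`
#' points before the O(n^2) matrix is formed, then the matrix is resized to
#' 64 x 64 — an approximation of computing the full-resolution plot and
#' resizing it.
#'
#' @param downsample_length number of points per axis before the pairwise
#'   matrix (default 256, >= 2).
#' @return Object of class `rp_config`.
#' @export
rp_config <- function(downsample_length = 256L) {
  if (downsample_length < 2) stop("`downsample_length` must be >= 2", call. = FALSE)
  structure(list(downsample_length = as.integer(downsample_length)),
            class = "rp_config")
}

# Block-average a vector down to `m` points (contiguous equal blocks; the
# last block absorbs any remainder).
block_average <- function(v, m) {
  n <- length(v)
  if (n <= m) return(v)
  idx <- pmin(floor((seq_len(n) - 1) * m / n) + 1, m)
  as.numeric(tapply(v, idx, mean))
}

#' Unthresholded recurrence matrix of one series
#'
#' `D[i, j] = |v[i] - v[j]|`: scalar absolute differences (embedding
#' dimension 1), no Heaviside threshold. Symmetric with zero diagonal.
#'
#' @param v numeric vector.
#' @return `length(v) x length(v)` numeric matrix.
#' @export
rp_distance_matrix <- function(v) {
  abs(outer(v, v, "-"))
}

#' Recurrence-plot image of a segment
#'
#' Per axis: block-average to `downsample_length` points, form the
#' unthresholded distance matrix, min-max normalise per axis, and place the
#' x, y, z matrices in the R, G, B channels. The three-channel matrix is
#' bilinearly resized to 64 x 64 and quantized to 8 bits. A constant axis
#' yields an all-zero channel.
#'
#' @param segment an [accel_segment()].
#' @param cfg an [rp_config()].
#' @return A [recon_image()] with `method = "rp"`.
#' @export
rp_image <- function(segment, cfg = rp_config()) {
  stopifnot(inherits(segment, "accel_segment"))
  m <- cfg$downsample_length
  chans <- lapply(1:3, function(k) {
    v <- block_average(segment$samples[, k], m)
    minmax01(rp_distance_matrix(v))
  })
  side <- nrow(chans[[1]])
  rgb <- array(unlist(chans), c(side, side, 3L))
  img <- quantize8(resize_bilinear(rgb))
  recon_image(img, "rp",
              source = list(subject_id = segment$subject_id,
                            label = segment$label,
                            segment_index = segment$segment_index))
}
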