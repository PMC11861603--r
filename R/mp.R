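#' Multi-channel-plot digit decomposition
#'
#' All 7500 values of a segment are jointly min-max scaled to the real
#' interval \[0, 255\]; each scaled value v is then split into its integer
#' part (R), its first-to-second decimal digits (G) and its third-to-fourth
#' decimal digits (B):
#' `R = floor(v)`, `G = floor(frac(v) * 100)`, `B = floor(frac(v) * 1e4) %% 100`.
#' The decomposition is exactly invertible to within 1e-4:
#' `v ~= R + G/100 + B/1e4`.
#'
#' @param v numeric vector of scaled values in \[0, 255\].
#' @return Integer matrix with columns `R`, `G`, `B`.
#' @examples
#' mp_encode(123.4567)  # R=123, G=45, B=67
#' @export
mp_encode <- function(v) {
  stopifnot(all(v >= 0), all(v <= 255 + 1e-9))
  # truncate at the 4th decimal; the 1e-6 guard keeps decimal inputs such as
  # 123.4567 (not exactly representable in binary) on the intended grid cell
  d4 <- floor(v * 1e4 + 1e-6)
  R <- d4 %/% 10000
  G <- (d4 %% 10000) %/% 100
  B <- d4 %% 100
  cbind(R = as.integer(R), G = as.integer(G), B = as.integer(B))
}

#' Multi-channel-plot image of a segment
#'
#' Scales the segment's 7500 values jointly to \[0, 255\], decomposes each
#' value into RGB digits with [mp_encode()], lays each axis's 2500 pixels
#' out row-major as a 50 x 50 tile, stacks the x, y, z tiles vertically into
#' a 150 x 50 three-channel image, and resizes to 64 x 64. A constant
#' segment (degenerate min-max) maps to all-black pixels.
#'
#' @param segment an [accel_segment()] with 2500 samples per axis (or any
#'   square-number length).
#' @return A [recon_image()] with `method = "mp"`.
#' @export
mp_image <- function(segment) {
  stopifnot(inherits(segment, "accel_segment"))
  x <- segment$samples
  n <- nrow(x)
  side <- as.integer(round(sqrt(n)))
  if (side * side != n)
    stop("segment length must be a perfect square for the MP tiling", call. = FALSE)
  lo <- min(x); hi <- max(x)
  scaled <- if (hi - lo <= 0) array(0, dim(x)) else (x - lo) / (hi - lo) * 255
  tiles <- lapply(1:3, function(k) {
    rgbv <- mp_encode(scaled[, k])
    # row-major 50 x 50 tile per channel
    array(c(matrix(rgbv[, 1], side, side, byrow = TRUE),
            matrix(rgbv[, 2], side, side, byrow = TRUE),
            matrix(rgbv[, 3], side, side, byrow = TRUE)),
          c(side, side, 3L))
  })
  stackimg <- array(0, c(3L * side, side, 3L))
  for (k in 1:3)
    stackimg[((k - 1) * side + 1):(k * side), , ] <- tiles[[k]]
  img <- quantize8(resize_bilinear(stackimg / 255))
  recon_image(img, "mp",
              source = list(subject_id = segment$subject_id,
                            label = segment$label,
                            segment_index = segment$segment_index))
}
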