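#' Image-reconstruction containers and shared helpers
#'
#' A `recon_image` is a 64 x 64 x 3 array of 8-bit intensities (stored as
#' integers in \[0, 255\]) produced by one of the three signal-to-image
#' transforms, tagged with the method and the segment it came from.
#'
#' @param pixels integer/numeric array `64 x 64 x 3` with values in
#'   \[0, 255\].
#' @param method one of `"spectrogram"`, `"rp"`, `"mp"`.
#' @param source list with `subject_id`, `label`, `segment_index`.
#' @return Object of class `recon_image`.
#' @export
recon_image <- function(pixels, method, source = NULL) {
  method <- match.arg(method, c("spectrogram", "rp", "mp"))
  if (!identical(dim(pixels), c(64L, 64L, 3L)))
    stop("`pixels` must be a 64 x 64 x 3 array", call. = FALSE)
  if (any(pixels < 0 | pixels > 255))
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, method = method, source = source),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> method=%s, 64x64x3, range [%d, %d]\n",
              x$method, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Min-max scale to [0, 1]; a constant input maps to all zeros (a constant
# signal carries no contrast).
minmax01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(array(0, dim(m)))
  (m - lo) / (hi - lo)
}

# Bilinear resize of a 2-D matrix or H x W x 3 array to `h x w`.
resize_bilinear <- function(m, h = 64, w = 64) {
  EBImage::resize(m, w = h, h = w, filter = "bilinear")
}

# Clamp to [0,1], quantize to 8-bit.
quantize8 <- function(m) {
  m <- pmin(pmax(m, 0), 1)
  array(as.integer(round(m * 255)), dim(m))
}

# 256-entry RGB colormap matrix (256 x 3, values in [0,1]).
make_colormap <- function(name = "viridis") {
  if (identical(name, "gray")) {
    g <- seq(0, 1, length.out = 256)
    return(cbind(g, g, g))
  }
  t(grDevices::col2rgb(grDevices::hcl.colors(256, name)) / 255)
}

# Map a [0,1] matrix through a 256-entry colormap -> H x W x 3 array.
apply_colormap <- function(m, cmap) {
  idx <- pmin(pmax(as.integer(floor(m * 255)) + 1L, 1L), 256L)
  array(cmap[idx, ], c(dim(m), 3L))
}

#' Apply all three reconstructions to a segment
#'
#' Returns the spectrogram, recurrence-plot and multi-channel-plot images of
#' one segment, in that fixed order: the triple fed to the three branches of
#' the fusion network.
#'
#' @param segment an [accel_segment()].
#' @param spec_cfg a [spectrogram_config()].
#' @param rp_cfg an [rp_config()].
#' @return Named list `list(spectrogram =, rp =, mp =)` of [recon_image()].
#' @export
reconstruct_all <- function(segment, spec_cfg = spectrogram_config(),
                            rp_cfg = rp_config()) {
  list(spectrogram = spectrogram_image(segment, spec_cfg),
       rp = rp_image(segment, rp_cfg),
       mp = mp_image(segment))
}

#' Write / read a reconstruction image as PNG
#'
#' Lossless 8-bit RGB round trip via the png package.
#'
#' @param image a [recon_image()].
#' @param path file path.
#' @param method method tag to attach on reading.
#' @return `write_recon_png` returns `path` invisibly; `read_recon_png`
#'   returns a [recon_image()].
#' @export
write_recon_png <- function(image, path) {
  stopifnot(inherits(image, "recon_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' @rdname write_recon_png
#' @export
read_recon_png <- function(path, method = "spectrogram") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  recon_image(round(px[, , 1:3] * 255), method = method)
}
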