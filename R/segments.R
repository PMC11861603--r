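#' Tri-axial accelerometer segments
#'
#' An `accel_segment` is one fixed-length window of tri-axial accelerometer
#' data: a numeric matrix with `fs * segment_seconds` rows and columns
#' (x, y, z), in raw sensor counts, together with the sampling rate, the
#' subject it came from, its activity label, and its ordinal index within
#' that subject/activity recording. It is the unit of classification.
#'
#' @param samples numeric matrix, `n x 3`, axis order (x, y, z); all values
#'   must be finite.
#' @param fs sampling rate in Hz (default 250).
#' @param subject_id opaque subject identifier.
#' @param label activity class identifier (typically a taxonomy abbreviation).
#' @param segment_index ordinal of this segment within subject/activity.
#' @return An object of class `accel_segment`.
#' @export
accel_segment <- function(samples, fs = 250, subject_id = "S1", label = "NA",
                          segment_index = 1L) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("`samples` must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("non-finite values in `samples`", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  fs <- as.double(fs)
  storage.mode(samples) <- "double"
  colnames(samples) <- c("ax", "ay", "az")
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id),
                 label = as.character(label),
                 segment_index = as.integer(segment_index)),
            class = "accel_segment")
}

#' @export
print.accel_segment <- function(x, ...) {
  cat(sprintf("<accel_segment> %d samples x 3 axes @ %g Hz (%.1f s)\n",
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  subject %s, label %s, segment %d\n",
              x$subject_id, x$label, x$segment_index))
  invisible(x)
}

#' Cut a continuous stream into fixed-length segments
#'
#' Splits a raw tri-axial stream into consecutive non-overlapping windows of
#' `segment_seconds` seconds. The trailing remainder (any incomplete window)
#' is discarded. No filtering, resampling or normalisation is applied: the
#' downstream image encodings operate on raw counts.
#'
#' @param stream numeric matrix `N x 3` of raw accelerometer values.
#' @param fs sampling rate in Hz.
#' @param segment_seconds window length in seconds (default 10).
#' @inheritParams accel_segment
#' @return List of [accel_segment()] objects, `floor(N / (fs*segment_seconds))`
#'   of them, with `segment_index` running from 1.
#' @examples
#' s <- segment_signal(matrix(rnorm(7500 * 3), ncol = 3), fs = 250,
#'                     segment_seconds = 10, subject_id = "S1", label = "WK")
#' length(s)  # 3
#' @export
segment_signal <- function(stream, fs = 250, segment_seconds = 10,
                           subject_id = "S1", label = "NA") {
  stream <- as.matrix(stream)
  if (ncol(stream) != 3L)
    stop("`stream` must have 3 columns", call. = FALSE)
  if (nrow(stream) > 0L && !all(is.finite(stream)))
    stop("non-finite values in `stream`", call. = FALSE)
  if (fs <= 0 || segment_seconds <= 0)
    stop("`fs` and `segment_seconds` must be positive", call. = FALSE)
  L <- as.integer(round(fs * segment_seconds))
  k <- if (nrow(stream) >= L) nrow(stream) %/% L else 0L
  lapply(seq_len(k), function(i)
    accel_segment(stream[((i - 1L) * L + 1L):(i * L), , drop = FALSE],
                  fs = fs, subject_id = subject_id, label = label,
                  segment_index = i))
}

#' Subject-independent train/validation/test split
#'
#' Partitions segments at the subject level so that no subject contributes to
#' more than one of train, validation and test. `test_fraction` is the
#' fraction of subjects assigned to the test set; `val_fraction` is the
#' fraction of the *remaining* (training) subjects held out for validation,
#' mirroring the usual protocol of carving the validation set out of the
#' training pool. Fractions are rounded to the nearest subject count.
#'
#' @param segments list of [accel_segment()].
#' @param test_fraction fraction of subjects for testing, in (0, 1).
#' @param val_fraction fraction of the non-test subjects for validation,
#'   in \[0, 1); default 0.25.
#' @param seed integer seed; the same seed always yields the same partition.
#' @return Object of class `dataset_split`: list with elements `train`,
#'   `validation`, `test` (lists of segments), the subject id vectors
#'   `train_subjects`, `val_subjects`, `test_subjects`, and `split_seed`.
#' @export
split_by_subject <- function(segments, test_fraction = 0.2,
                             val_fraction = 0.25, seed = 1L) {
  stopifnot(length(segments) > 0L)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1)
    stop("`val_fraction` must be in [0, 1)", call. = FALSE)
  subj <- vapply(segments, function(s) s$subject_id, character(1))
  subjects <- sort(unique(subj))
  n <- length(subjects)
  if (n < 3L)
    stop("need at least 3 distinct subjects to split", call. = FALSE)
  n_test <- max(1L, as.integer(round(n * test_fraction)))
  if (n_test >= n) stop("test fraction leaves no training subjects", call. = FALSE)
  perm <- with_seed(seed, sample(subjects))
  test_s <- perm[seq_len(n_test)]
  rest <- perm[(n_test + 1L):n]
  n_val <- as.integer(round(length(rest) * val_fraction))
  if (val_fraction > 0 && n_val == 0L) n_val <- 1L
  if (n_val >= length(rest)) n_val <- length(rest) - 1L
  val_s <- if (n_val > 0L) rest[seq_len(n_val)] else character(0)
  train_s <- rest[setdiff(seq_along(rest), seq_len(n_val))]
  structure(list(
    train = segments[subj %in% train_s],
    validation = segments[subj %in% val_s],
    test = segments[subj %in% test_s],
    train_subjects = sort(train_s), val_subjects = sort(val_s),
    test_subjects = sort(test_s), split_seed = as.integer(seed)),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(paste0("<dataset_split> %d train / %d validation / %d test ",
                     "segments\n  subjects: %d / %d / %d (disjoint), seed %d\n"),
              length(x$train), length(x$validation), length(x$test),
              length(x$train_subjects), length(x$val_subjects),
              length(x$test_subjects), x$split_seed))
  invisible(x)
}

#' Add i.i.d. Gaussian sensor noise to a segment
#'
#' Adds zero-mean Gaussian noise with standard deviation `sigma` (raw counts)
#' independently to every value of every axis. Used by the noise-robustness
#' sweep, where test segments are perturbed at fractions of the dataset's
#' pooled standard deviation (see [dataset_sigma()]).
#'
#' @param segment an [accel_segment()].
#' @param sigma noise standard deviation, `>= 0`, in raw counts.
#' @param seed integer seed; same seed gives bit-identical output.
#' @return A new `accel_segment`; the input is not modified.
#' @export
add_gaussian_noise <- function(segment, sigma, seed = 1L) {
  stopifnot(inherits(segment, "accel_segment"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  out <- segment
  if (sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(length(segment$samples), 0, sigma),
                                    nrow = nrow(segment$samples)))
    out$samples <- segment$samples + noise
    colnames(out$samples) <- colnames(segment$samples)
  }
  out
}

#' Pooled standard deviation of a segment collection
#'
#' The standard deviation of all values of all axes of all segments pooled
#' into one sample (two-pass, denominator `n - 1`). Noise levels for the
#' robustness sweep are expressed as percentages of this quantity.
#'
#' @param segments non-empty list of [accel_segment()].
#' @return A single number.
#' @export
dataset_sigma <- function(segments) {
  if (length(segments) == 0L) stop("`segments` is empty", call. = FALSE)
  n_tot <- sum(vapply(segments, function(s) length(s$samples), numeric(1)))
  mu <- sum(vapply(segments, function(s) sum(s$samples), numeric(1))) / n_tot
  ss <- sum(vapply(segments, function(s) sum((s$samples - mu)^2), numeric(1)))
  sqrt(ss / (n_tot - 1))
}

#' Read and write segments as long-format CSV
#'
#' The on-disk format is a long CSV with fixed columns `subject_id`, `label`,
#' `segment_index`, `sample_index`, `ax`, `ay`, `az` (one row per sample) and
#' the sampling rate recorded in an `fs` column (constant).
#'
#' @param segments list of [accel_segment()].
#' @param path file path.
#' @return `write_segments_csv` returns `path` invisibly; `read_segments_csv`
#'   returns a list of segments.
#' @export
write_segments_csv <- function(segments, path) {
  dfs <- lapply(segments, function(s)
    data.frame(subject_id = s$subject_id, label = s$label,
               segment_index = s$segment_index,
               sample_index = seq_len(nrow(s$samples)),
               ax = s$samples[, 1], ay = s$samples[, 2], az = s$samples[, 3],
               fs = s$fs))
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "segment_index", "sample_index",
            "ax", "ay", "az", "fs")
  if (!all(need %in% names(df)))
    stop("segment CSV is missing required columns", call. = FALSE)
  key <- interaction(df$subject_id, df$label, df$segment_index, drop = TRUE)
  lapply(split(df, key), function(d) {
    d <- d[order(d$sample_index), ]
    accel_segment(cbind(d$ax, d$ay, d$az), fs = d$fs[1],
                  subject_id = d$subject_id[1], label = d$label[1],
                  segment_index = d$segment_index[1])
  })
}
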