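# Bridges between segment lists and the batch tensors the network consumes.

# Stack recon images into a (64, 64, 3, N) tensor scaled to [0, 1].
tensor_from_images <- function(imgs) {
  n <- length(imgs)
  arr <- array(0, c(64L, 64L, 3L, n))
  for (i in seq_len(n)) arr[, , , i] <- imgs[[i]]$pixels / 255
  arr
}

# Stack raw segments into a (1, L, 3, N) tensor standardized with the given
# centre/scale (raw counts).
tensor_from_series <- function(segments, center, scale) {
  n <- length(segments)
  L <- nrow(segments[[1]]$samples)
  arr <- array(0, c(1L, L, 3L, n))
  for (i in seq_len(n))
    arr[1, , , i] <- (segments[[i]]$samples - center) / scale
  arr
}

segment_labels <- function(segments) vapply(segments, function(s) s$label, character(1))

#' Prepare model-ready tensors from a subject-independent split
#'
#' Reconstructs every segment of each partition with the three image
#' transforms, stacks the results into batch tensors scaled to \[0, 1\],
#' and standardizes the raw series for the 1-D baseline using the training
#' partition's pooled mean and standard deviation. Class identity is encoded
#' as an integer index into the sorted set of labels present in the split.
#'
#' @param split a [split_by_subject()] result.
#' @param spec_cfg a [spectrogram_config()].
#' @param rp_cfg an [rp_config()].
#' @param methods reconstruction methods to compute (default all three).
#' @param with_series also build the raw-series tensor (default TRUE).
#' @return Object of class `har_data`: list with `classes`, `series_center`,
#'   `series_scale`, and per-partition lists (`train`, `validation`, `test`)
#'   each holding `x` (named list of image tensors), `series`, `y`,
#'   `subjects`.
#' @export
prepare_har_data <- function(split, spec_cfg = spectrogram_config(),
                             rp_cfg = rp_config(),
                             methods = c("spectrogram", "rp", "mp"),
                             with_series = TRUE) {
  stopifnot(inherits(split, "dataset_split"))
  classes <- sort(unique(c(segment_labels(split$train),
                           segment_labels(split$validation),
                           segment_labels(split$test))))
  center <- mean(vapply(split$train, function(s) mean(s$samples), numeric(1)))
  scale <- dataset_sigma(split$train)
  part <- function(segments) {
    y <- match(segment_labels(segments), classes)
    x <- lapply(methods, function(m) {
      imgs <- lapply(segments, function(s) switch(m,
        spectrogram = spectrogram_image(s, spec_cfg),
        rp = rp_image(s, rp_cfg),
        mp = mp_image(s)))
      tensor_from_images(imgs)
    })
    names(x) <- methods
    list(x = x,
         series = if (with_series) tensor_from_series(segments, center, scale),
         y = y,
         subjects = vapply(segments, function(s) s$subject_id, character(1)))
  }
  structure(list(classes = classes, series_center = center,
                 series_scale = scale,
                 train = part(split$train),
                 validation = part(split$validation),
                 test = part(split$test)),
            class = "har_data")
}

condition_inputs <- function(data, partition, condition) {
  p <- data[[partition]]
  switch(condition,
    fusion = p$x[c("spectrogram", "rp", "mp")],
    baseline_1d = list(p$series),
    p$x[condition])
}

#' Fit one model condition on prepared data
#'
#' The five conditions of the method-comparison experiment: the
#' three-branch `"fusion"` model, the single-reconstruction models
#' (`"spectrogram"`, `"rp"`, `"mp"`) and the raw-series `"baseline_1d"`.
#' Builds the architecture (weights seeded from `cfg$seed`), trains on the
#' training partition with validation monitoring, and tags the model with
#' the input methods it expects so that later evaluation (including the
#' noise sweep) can rebuild its inputs.
#'
#' @param data a [prepare_har_data()] result.
#' @param condition one of `"fusion"`, `"spectrogram"`, `"rp"`, `"mp"`,
#'   `"baseline_1d"`.
#' @param cfg a [train_config()].
#' @param branch a [branch_spec()].
#' @return A trained `har_cnn` with `input_methods`, `classes` and series
#'   scaling constants attached.
#' @export
fit_har_condition <- function(data, condition = c("fusion", "spectrogram",
                                                  "rp", "mp", "baseline_1d"),
                              cfg = train_config(), branch = branch_spec()) {
  condition <- match.arg(condition)
  stopifnot(inherits(data, "har_data"))
  K <- length(data$classes)
  init_seed <- derive_seed(cfg$seed, 101)
  model <- switch(condition,
    fusion = build_fusion(fusion_spec(K), branch, seed = init_seed),
    baseline_1d = build_baseline_1d(K, segment_length = dim(data$train$series)[2],
                                    branch = branch, seed = init_seed),
    build_single(K, branch, seed = init_seed))
  model <- train_model(model,
                       condition_inputs(data, "train", condition),
                       data$train$y,
                       condition_inputs(data, "validation", condition),
                       data$validation$y, cfg)
  model$condition <- condition
  model$input_methods <- switch(condition,
    fusion = c("spectrogram", "rp", "mp"),
    baseline_1d = "series",
    condition)
  model$classes <- data$classes
  model$series_center <- data$series_center
  model$series_scale <- data$series_scale
  model
}

#' Evaluate a fitted condition on a partition
#'
#' @param model a model from [fit_har_condition()].
#' @param data a [prepare_har_data()] result.
#' @param partition `"test"` (default), `"validation"` or `"train"`.
#' @return A [compute_metrics()] report.
#' @export
evaluate_har_model <- function(model, data, partition = "test") {
  stopifnot(inherits(model, "har_cnn"), inherits(data, "har_data"))
  x <- condition_inputs(data, partition, model$condition)
  p <- predict_proba(model, x)
  compute_metrics(data[[partition]]$y, p, class_names = data$classes)
}
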