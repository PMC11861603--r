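# Experiment harnesses: window-size sweep, reconstruction-method comparison,
# and the Gaussian-noise robustness sweep.

new_sweep_result <- function(kind, runs, reports) {
  structure(list(kind = kind, runs = runs, reports = reports),
            class = "sweep_result")
}

#' Aggregate sweep runs into mean (sd) per condition
#'
#' @param x a `sweep_result`.
#' @param ... unused.
#' @return data.frame with one row per condition and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
aggregate_sweep <- function(x, ...) {
  stopifnot(inherits(x, "sweep_result"))
  metrics <- intersect(c("top1", "top3", "precision", "recall", "roc_auc",
                         "degradation"), names(x$runs))
  keys <- intersect(c("condition", "sigma"), names(x$runs))
  agg <- do.call(rbind, lapply(split(x$runs, x$runs[keys], drop = TRUE),
    function(d) {
      out <- d[1, keys, drop = FALSE]
      for (m in metrics) {
        out[[paste0(m, "_mean")]] <- mean(d[[m]])
        out[[paste0(m, "_sd")]] <- if (nrow(d) > 1) sd(d[[m]]) else 0
      }
      out
    }))
  rownames(agg) <- NULL
  agg
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s: %d runs\n", x$kind, nrow(x$runs)))
  agg <- aggregate_sweep(x)
  fmt <- agg[intersect(c("condition", "sigma"), names(agg))]
  for (m in c("top1", "top3", "precision", "recall", "roc_auc", "degradation")) {
    mc <- paste0(m, "_mean"); sc <- paste0(m, "_sd")
    if (mc %in% names(agg))
      fmt[[m]] <- sprintf("%.4f (%.4f)", agg[[mc]], agg[[sc]])
  }
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write sweep results as CSV
#'
#' Writes the aggregate table (`<metric>_mean`, `<metric>_sd` columns,
#' matching the usual "mean (sd)" reporting) and, optionally, the raw
#' per-replicate runs.
#'
#' @param x a `sweep_result`.
#' @param path output CSV path for the aggregate table.
#' @param runs_path optional CSV path for the per-replicate table.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(x, path, runs_path = NULL) {
  write.csv(aggregate_sweep(x), path, row.names = FALSE)
  if (!is.null(runs_path)) write.csv(x$runs, runs_path, row.names = FALSE)
  invisible(path)
}

run_row <- function(condition, replicate, rep_report, extra = NULL) {
  out <- data.frame(condition = condition, replicate = replicate,
                    top1 = rep_report$top1_accuracy,
                    top3 = rep_report$top3_accuracy,
                    precision = rep_report$precision,
                    recall = rep_report$recall,
                    roc_auc = rep_report$roc_auc)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

#' Spectrogram window-size sweep
#'
#' Trains a single-branch spectrogram classifier for each STFT window size
#' (1, 2, 5 and 10 s by default, each with half-window overlap) and each
#' replicate, on a fixed subject-independent split, and aggregates the
#' metric suite as mean (sd) over replicates. Replicate r uses training
#' seed `base_seed + r - 1`.
#'
#' @param split a [split_by_subject()] result.
#' @param sizes window sizes in seconds.
#' @param replicates training repetitions per size.
#' @param base_seed integer; replicate seeds are consecutive from it.
#' @param cfg a [train_config()] (its `seed` is overridden per replicate).
#' @param branch a [branch_spec()].
#' @return A `sweep_result` with one condition per window size.
#' @export
window_size_sweep <- function(split, sizes = c(1, 2, 5, 10), replicates = 4,
                              base_seed = 1L, cfg = train_config(),
                              branch = branch_spec()) {
  runs <- list(); reports <- list()
  for (ws in sizes) {
    data <- prepare_har_data(split, spectrogram_config(window_seconds = ws),
                             methods = "spectrogram", with_series = FALSE)
    for (r in seq_len(replicates)) {
      cfg_r <- cfg; cfg_r$seed <- as.integer(base_seed + r - 1L)
      model <- fit_har_condition(data, "spectrogram", cfg_r, branch)
      rep <- evaluate_har_model(model, data, "test")
      key <- sprintf("window_%gs", ws)
      runs[[length(runs) + 1L]] <- run_row(key, r, rep)
      reports[[key]][[r]] <- rep
    }
  }
  new_sweep_result("window_size", do.call(rbind, runs), reports)
}

#' Reconstruction-method comparison
#'
#' Evaluates the five conditions — 1-D raw-series baseline, the three
#' single-reconstruction models, and the three-branch fusion model — on a
#' common subject-independent split, `replicates` times each with seeds
#' `base_seed + r - 1`. All conditions share identical train/validation/test
#' subject partitions and reconstruction inputs.
#'
#' @inheritParams window_size_sweep
#' @param spec_cfg a [spectrogram_config()].
#' @param rp_cfg an [rp_config()].
#' @param conditions subset of conditions to run.
#' @param keep_models return the trained models (last replicate of each
#'   condition) in the result.
#' @return A `sweep_result`; if `keep_models`, with `models` and `data`
#'   fields attached for reuse (e.g. by [noise_sweep()]).
#' @export
method_comparison <- function(split, replicates = 4, base_seed = 1L,
                              cfg = train_config(),
                              spec_cfg = spectrogram_config(),
                              rp_cfg = rp_config(), branch = branch_spec(),
                              conditions = c("baseline_1d", "spectrogram",
                                             "rp", "mp", "fusion"),
                              keep_models = FALSE) {
  data <- prepare_har_data(split, spec_cfg, rp_cfg)
  runs <- list(); reports <- list(); models <- list()
  for (cond in conditions) {
    for (r in seq_len(replicates)) {
      cfg_r <- cfg; cfg_r$seed <- as.integer(base_seed + r - 1L)
      model <- fit_har_condition(data, cond, cfg_r, branch)
      rep <- evaluate_har_model(model, data, "test")
      runs[[length(runs) + 1L]] <- run_row(cond, r, rep)
      reports[[cond]][[r]] <- rep
      if (keep_models) models[[cond]][[r]] <- model
    }
  }
  out <- new_sweep_result("method_comparison", do.call(rbind, runs), reports)
  if (keep_models) { out$models <- models; out$data <- data }
  out
}

#' Gaussian-noise robustness sweep
#'
#' Takes models trained on clean data, perturbs the raw test segments with
#' i.i.d. Gaussian noise of each standard deviation in `sigmas` (raw
#' counts), re-runs the image reconstructions on the noisy signals, and
#' evaluates every model at every noise level. Reports absolute top-1
#' accuracy and the degradation relative to each model's clean (sigma = 0)
#' accuracy. Sigma values are conventionally chosen as percentages of the
#' dataset's pooled standard deviation ([dataset_sigma()]).
#'
#' @param models named list of trained models from [fit_har_condition()].
#' @param split the [split_by_subject()] result the models were trained on.
#' @param sigmas noise standard deviations in raw counts (0 is always
#'   evaluated as the clean reference).
#' @param seed integer seed for the noise draws.
#' @param spec_cfg,rp_cfg reconstruction configurations (must match training).
#' @return A `sweep_result` with columns `condition` (model name), `sigma`,
#'   the metric suite and `degradation` = clean top-1 minus noisy top-1.
#' @export
noise_sweep <- function(models, split, sigmas, seed = 1L,
                        spec_cfg = spectrogram_config(), rp_cfg = rp_config()) {
  stopifnot(length(models) > 0, !is.null(names(models)))
  sigmas <- sort(unique(c(0, sigmas)))
  methods <- unique(unlist(lapply(models, function(m) m$input_methods)))
  img_methods <- setdiff(methods, "series")
  m1 <- models[[1]]
  classes <- m1$classes
  runs <- list(); reports <- list()
  clean_top1 <- list()
  for (sg in sigmas) {
    segs <- if (sg == 0) split$test else
      lapply(seq_along(split$test), function(i)
        add_gaussian_noise(split$test[[i]], sg, seed = derive_seed(seed, i)))
    y <- match(segment_labels(segs), classes)
    xs <- lapply(img_methods, function(m) {
      imgs <- lapply(segs, function(s) switch(m,
        spectrogram = spectrogram_image(s, spec_cfg),
        rp = rp_image(s, rp_cfg),
        mp = mp_image(s)))
      tensor_from_images(imgs)
    })
    names(xs) <- img_methods
    series <- if ("series" %in% methods)
      tensor_from_series(segs, m1$series_center, m1$series_scale)
    for (nm in names(models)) {
      mod <- models[[nm]]
      x <- if (identical(mod$input_methods, "series")) list(series)
      else xs[mod$input_methods]
      rep <- compute_metrics(y, predict_proba(mod, x), class_names = classes)
      if (sg == 0) clean_top1[[nm]] <- rep$top1_accuracy
      runs[[length(runs) + 1L]] <- run_row(
        nm, 1L, rep, extra = data.frame(
          sigma = sg, degradation = clean_top1[[nm]] - rep$top1_accuracy))
      reports[[nm]][[as.character(sg)]] <- rep
    }
  }
  new_sweep_result("noise", do.call(rbind, runs), reports)
}
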