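#' Branch and fusion architecture specifications
#'
#' A branch maps one 64 x 64 x 3 image to a 1024-dimensional feature vector
#' through five convolutional blocks (3 x 3 convolution, ReLU, factor-2 max
#' pooling) followed by a fully connected layer. After the five blocks the
#' feature map is 2 x 2 with 64 channels (a flattened vector of 256). The
#' per-block channel schedule is configurable; only its final entry (64) is
#' architecturally fixed.
#'
#' @param input_shape integer length-3, image height/width/channels.
#' @param block_channels integer vector of per-block output channels; the
#'   last entry must be 64.
#' @param kernel_size odd convolution kernel size (default 3).
#' @param feature_units width of the branch's fully connected layer
#'   (default 1024).
#' @return Object of class `branch_spec`.
#' @export
branch_spec <- function(input_shape = c(64, 64, 3),
                        block_channels = c(32, 64, 128, 128, 64),
                        kernel_size = 3, feature_units = 1024) {
  if (kernel_size %% 2 != 1) stop("`kernel_size` must be odd", call. = FALSE)
  n_blocks <- length(block_channels)
  if (block_channels[n_blocks] != 64)
    stop("the final block must have 64 channels", call. = FALSE)
  if (input_shape[1] %% 2^n_blocks != 0 || input_shape[2] %% 2^n_blocks != 0)
    stop("input size not divisible by the downsampling chain", call. = FALSE)
  structure(list(input_shape = as.integer(input_shape),
                 n_blocks = n_blocks,
                 block_channels = as.integer(block_channels),
                 kernel_size = as.integer(kernel_size),
                 feature_units = as.integer(feature_units)),
            class = "branch_spec")
}

#' @rdname branch_spec
#' @param n_branches number of image branches (3 for the fusion model).
#' @param head_units width of the first classification layer (default 256).
#' @param n_classes number of activity classes (>= 2).
#' @export
fusion_spec <- function(n_classes, n_branches = 3, head_units = 256) {
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  structure(list(n_branches = as.integer(n_branches),
                 head_units = as.integer(head_units),
                 n_classes = as.integer(n_classes)),
            class = "fusion_spec")
}

#' Training configuration
#'
#' Defaults mirror the published training protocol: 50 epochs, batch size 8,
#' Adam with learning rate 0.005, categorical cross-entropy, and a
#' reduce-on-plateau schedule (factor 0.7, patience 3, monitoring validation
#' loss).
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate initial Adam learning rate.
#' @param lr_factor plateau reduction factor in (0, 1).
#' @param lr_patience epochs of validation-loss stagnation before reduction.
#' @param seed integer seed driving weight initialisation and shuffling.
#' @param verbose print per-epoch progress.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 8, learning_rate = 0.005,
                         lr_factor = 0.7, lr_patience = 3, seed = 1L,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            lr_factor > 0, lr_factor < 1, lr_patience >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Build the layer list of one convolutional branch. `pools` gives the
# (ph, pw) downsampling factor of each block.
make_branch_layers <- function(in_shape, channels, ks, feature_units, pools) {
  layers <- list()
  h <- in_shape[1]; w <- in_shape[2]; cin <- in_shape[3]
  kh <- if (in_shape[1] == 1L) 1L else ks
  for (b in seq_along(channels)) {
    layers <- c(layers, list(new_conv_layer(kh, ks, cin, channels[b]),
                             new_relu_layer()))
    ph <- pools[[b]][1]; pw <- pools[[b]][2]
    if (ph > 1 || pw > 1) {
      if (h %% ph != 0 || w %% pw != 0)
        stop("input size not divisible by the downsampling chain", call. = FALSE)
      layers <- c(layers, list(new_pool_layer(ph, pw)))
      h <- h %/% ph; w <- w %/% pw
    }
    cin <- channels[b]
  }
  flat <- h * w * cin
  c(layers, list(new_flatten_layer(),
                 new_dense_layer(flat, feature_units),
                 new_relu_layer()))
}

#' Build the three-branch fusion classifier
#'
#' Three independent (non-weight-shared) convolutional branches, one per
#' reconstruction method, each producing a 1024-dimensional feature vector;
#' the vectors are concatenated (3072) and passed through dense layers of
#' 256 and `n_classes` units with a softmax output.
#'
#' @param spec a [fusion_spec()].
#' @param branch a [branch_spec()].
#' @param seed integer seed for weight initialisation.
#' @return Object of class `har_cnn` (untrained).
#' @export
build_fusion <- function(spec, branch = branch_spec(), seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"), inherits(branch, "branch_spec"))
  pools <- rep(list(c(2L, 2L)), branch$n_blocks)
  with_seed(seed, {
    branches <- lapply(seq_len(spec$n_branches), function(i)
      make_branch_layers(branch$input_shape, branch$block_channels,
                         branch$kernel_size, branch$feature_units, pools))
    head <- list(
      new_dense_layer(spec$n_branches * branch$feature_units, spec$head_units),
      new_relu_layer(),
      new_dense_layer(spec$head_units, spec$n_classes, out_layer = TRUE))
    structure(list(branches = branches, head = head, spec = spec,
                   branch_spec = branch, input_kind = "images",
                   n_classes = spec$n_classes, trained = FALSE,
                   init_seed = as.integer(seed)),
              class = "har_cnn")
  })
}

#' Build a single-branch classifier (one reconstruction method)
#'
#' Same branch topology and head sizes as the fusion model but with one
#' image input; used for the per-method ablation conditions.
#'
#' @inheritParams build_fusion
#' @param n_classes number of classes.
#' @export
build_single <- function(n_classes, branch = branch_spec(), seed = 1L) {
  build_fusion(fusion_spec(n_classes, n_branches = 1), branch, seed)
}

#' Build the 1-D convolutional baseline
#'
#' Mirrors the branch topology with 1-D convolutions applied directly to the
#' raw (2500, 3) segment (no image reconstruction, single input): five
#' blocks with channel schedule as in [branch_spec()], pooling factors
#' (5, 5, 5, 5, 1) so the final feature map is 4 samples x 64 channels
#' (flattened 256), then dense layers of 1024, 256 and `n_classes` units.
#'
#' @param n_classes number of classes.
#' @param segment_length samples per segment (default 2500); must be
#'   divisible by the product of the pooling factors.
#' @param pools integer vector of per-block pooling factors.
#' @param branch a [branch_spec()] (channel schedule / kernel / feature units).
#' @param seed integer seed for weight initialisation.
#' @return Object of class `har_cnn` (untrained).
#' @export
build_baseline_1d <- function(n_classes, segment_length = 2500,
                              pools = c(5, 5, 5, 5, 1),
                              branch = branch_spec(), seed = 1L) {
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  if (length(pools) != branch$n_blocks)
    stop("`pools` must have one factor per block", call. = FALSE)
  if (segment_length %% prod(pools) != 0)
    stop("input size not divisible by the downsampling chain", call. = FALSE)
  pl <- lapply(pools, function(p) c(1L, as.integer(p)))
  with_seed(seed, {
    branches <- list(make_branch_layers(c(1L, segment_length, 3L),
                                        branch$block_channels,
                                        branch$kernel_size,
                                        branch$feature_units, pl))
    head <- list(new_dense_layer(branch$feature_units, 256L),
                 new_relu_layer(),
                 new_dense_layer(256L, n_classes, out_layer = TRUE))
    structure(list(branches = branches, head = head,
                   spec = fusion_spec(n_classes, n_branches = 1),
                   branch_spec = branch, input_kind = "series",
                   segment_length = as.integer(segment_length),
                   n_classes = as.integer(n_classes), trained = FALSE,
                   init_seed = as.integer(seed)),
              class = "har_cnn")
  })
}

#' Branch feature extractor
#'
#' Runs one branch of a model and returns its feature vectors (the
#' 1024-unit fully connected output), one column per sample.
#'
#' @param model a `har_cnn`.
#' @param x input tensor `(H, W, C, N)` for that branch.
#' @param branch branch index.
#' @return `feature_units x N` matrix.
#' @export
branch_features <- function(model, x, branch = 1L) {
  stopifnot(inherits(model, "har_cnn"))
  check_input_shape(model, list(x))
  layers_forward(model$branches[[branch]], x, train = FALSE)
}

check_input_shape <- function(model, xs) {
  expected <- if (model$input_kind == "series")
    c(1L, model$segment_length, 3L) else model$branch_spec$input_shape
  for (x in xs) {
    d <- dim(x)
    if (length(d) != 4L || !all(d[1:3] == expected))
      stop(sprintf("input shape mismatch: expected (%s, N)",
                   paste(expected, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Number of trainable parameters
#'
#' @param model a `har_cnn`.
#' @return Integer count of all weights and biases.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "har_cnn"))
  sum(vapply(Filter(has_params, all_layers(model)),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Train a classifier
#'
#' Minimises categorical cross-entropy with Adam, shuffling each epoch, and
#' reduces the learning rate on validation-loss plateaus. Deterministic
#' given `cfg$seed` and a fixed BLAS thread configuration.
#'
#' @param model an untrained (or partially trained) `har_cnn`.
#' @param x list of per-branch input tensors `(H, W, C, N)`, values in
#'   \[0, 1\] for image inputs (a single tensor may be passed for
#'   single-input models).
#' @param y integer class labels in `1..n_classes`.
#' @param x_val,y_val validation inputs in the same format.
#' @param cfg a [train_config()].
#' @return The trained model, with a `history` data.frame (epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, x, y, x_val, y_val, cfg = train_config()) {
  stopifnot(inherits(model, "har_cnn"), inherits(cfg, "train_config"))
  if (!is.list(x)) x <- list(x)
  if (!is.list(x_val)) x_val <- list(x_val)
  if (length(x) != length(model$branches))
    stop("expected one input tensor per branch", call. = FALSE)
  check_input_shape(model, x)
  n <- dim(x[[1]])[4]
  if (n == 0L || length(y) != n) stop("empty or mismatched training set", call. = FALSE)
  if (any(y < 1 | y > model$n_classes))
    stop("label outside taxonomy", call. = FALSE)
  K <- model$n_classes
  lr <- cfg$learning_rate; best <- Inf; wait <- 0L; tstep <- 0L
  hist <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hits <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- lapply(x, function(t) t[, , , ids, drop = FALSE])
        yb <- y[ids]
        logits <- model_forward(model, xb, train = TRUE)
        p <- softmax_cols(logits)
        m <- length(ids)
        ep_loss <- ep_loss - sum(log(pmax(p[cbind(yb, seq_len(m))], 1e-12)))
        ep_hits <- ep_hits + sum(apply(p, 2, which.max) == yb)
        Y <- matrix(0, K, m); Y[cbind(yb, seq_len(m))] <- 1
        model_backward(model, (p - Y) / m)
        tstep <- tstep + 1L
        for (l in all_layers(model)) adam_step(l, lr, t = tstep)
      }
      val <- evaluate_loss(model, x_val, y_val)
      hist[[ep]] <- data.frame(epoch = ep, lr = lr,
                               train_loss = ep_loss / n, train_acc = ep_hits / n,
                               val_loss = val$loss, val_acc = val$acc)
      if (cfg$verbose)
        message(sprintf("epoch %2d  lr %.5f  loss %.4f acc %.3f  val %.4f/%.3f",
                        ep, lr, ep_loss / n, ep_hits / n, val$loss, val$acc))
      if (val$loss < best) { best <- val$loss; wait <- 0L }
      else { wait <- wait + 1L; if (wait >= cfg$lr_patience) { lr <- lr * cfg$lr_factor; wait <- 0L } }
    }
  })
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model$train_config <- cfg
  clear_caches(model)
  model
}

evaluate_loss <- function(model, x, y, batch = 64L) {
  p <- predict_proba(model, x, batch = batch)
  pick <- cbind(seq_along(y), y)
  list(loss = -mean(log(pmax(p[pick], 1e-12))),
       acc = mean(max.col(p, ties.method = "first") == y))
}

# Probability matrix (N x K) for a list of input tensors.
predict_proba <- function(model, x, batch = 64L) {
  if (!is.list(x)) x <- list(x)
  check_input_shape(model, x)
  n <- dim(x[[1]])[4]
  out <- matrix(0, n, model$n_classes)
  for (start in seq(1, n, by = batch)) {
    ids <- start:min(start + batch - 1L, n)
    xb <- lapply(x, function(t) t[, , , ids, drop = FALSE])
    out[ids, ] <- t(softmax_cols(model_forward(model, xb, train = FALSE)))
  }
  out
}

#' Predict class probabilities
#'
#' @param object a trained `har_cnn`.
#' @param newdata list of per-branch input tensors (or a single tensor for
#'   single-input models), scaled as at training time.
#' @param type `"prob"` for the N x n_classes probability matrix, `"class"`
#'   for top-1 integer labels (argmax, ties broken by lowest class index).
#' @param ... unused.
#' @return Matrix of probabilities (rows sum to 1) or integer vector.
#' @export
predict.har_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else max.col(p, ties.method = "first")
}

#' @export
print.har_cnn <- function(x, ...) {
  kind <- if (x$input_kind == "series") "1-D baseline"
  else if (length(x$branches) == 3L) "three-branch fusion"
  else sprintf("%d-branch", length(x$branches))
  cat(sprintf("<har_cnn> %s CNN, %d classes, %s parameters%s\n",
              kind, x$n_classes, format(count_params(x), big.mark = ","),
              if (isTRUE(x$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' @export
summary.har_cnn <- function(object, ...) {
  print(object)
  cat(sprintf("  channel schedule: %s; feature units: %d; head: %d -> %d\n",
              paste(object$branch_spec$block_channels, collapse = "-"),
              object$branch_spec$feature_units, object$spec$head_units,
              object$n_classes))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epochs; final val loss %.4f, val acc %.3f, lr %.5f\n",
                nrow(h), h$val_loss[nrow(h)], h$val_acc[nrow(h)], h$lr[nrow(h)]))
  }
  invisible(object)
}

#' @export
plot.har_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "cross-entropy", ...)
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "accuracy", ...)
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The model is serialized as RDS with a JSON sidecar recording the
#' architecture specification, training configuration and seeds.
#'
#' @param model a `har_cnn`.
#' @param path checkpoint path (`.rds`); the sidecar is `path` + `.json`.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "har_cnn"))
  saveRDS(model, path)
  side <- list(n_classes = model$n_classes, input_kind = model$input_kind,
               n_branches = length(model$branches),
               block_channels = model$branch_spec$block_channels,
               feature_units = model$branch_spec$feature_units,
               init_seed = model$init_seed,
               train_config = if (!is.null(model$train_config))
                 unclass(model$train_config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "har_cnn"))
  m
}
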