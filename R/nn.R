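# Internal layer engine for the fusion CNN.
#
# Layers are environments (mutable in place) holding parameters, Adam state
# and the forward cache needed by backprop. Batch tensors are R arrays with
# dims (H, W, C, N); flattened activations are (features x N) matrices.

new_conv_layer <- function(kh, kw, cin, cout) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"; l$kh <- kh; l$kw <- kw
  fan_in <- kh * kw * cin
  l$W <- matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
  l$b <- numeric(cout)
  l
}

new_dense_layer <- function(nin, nout, out_layer = FALSE) {
  l <- new.env(parent = emptyenv())
  l$type <- "dense"
  sdv <- if (out_layer) sqrt(1 / nin) else sqrt(2 / nin)
  l$W <- matrix(rnorm(nin * nout, 0, sdv), nin, nout)
  l$b <- numeric(nout)
  l
}

new_pool_layer <- function(ph, pw) {
  l <- new.env(parent = emptyenv())
  l$type <- "pool"; l$ph <- ph; l$pw <- pw
  l
}

new_relu_layer <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "relu"; l
}

new_flatten_layer <- function() {
  l <- new.env(parent = emptyenv()); l$type <- "flatten"; l
}

layer_forward <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = {
      if (train) l$x <- x
      .conv2d_fwd(x, l$W, l$b, l$kh, l$kw)
    },
    pool = {
      r <- .maxpool_fwd(x, l$ph, l$pw)
      if (train) { l$idx <- r$idx; l$xdim <- dim(x) }
      r$out
    },
    relu = {
      # conv/pool/dense outputs are engine-owned temporaries: safe to clip
      # in place (saves a full-size temporary per activation)
      .relu_fwd_inplace(x)
      if (train) l$out <- x
      x
    },
    flatten = {
      l$xdim <- dim(x)
      matrix(x, ncol = dim(x)[4])
    },
    dense = {
      if (train) l$x <- x
      crossprod(l$W, x) + l$b
    })
}

layer_backward <- function(l, dout) {
  switch(l$type,
    conv = {
      g <- .conv2d_bwd(l$x, l$W, dout, l$kh, l$kw)
      l$dW <- g$dw; l$db <- g$db
      g$dx
    },
    pool = .maxpool_bwd(dout, l$idx, l$xdim),
    relu = {
      .relu_bwd_inplace(dout, l$out)
      dout
    },
    flatten = array(dout, l$xdim),
    dense = {
      l$dW <- l$x %*% t(dout)
      l$db <- rowSums(dout)
      l$W %*% dout
    })
}

has_params <- function(l) l$type %in% c("conv", "dense")

adam_step <- function(l, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7, t = 1) {
  if (!has_params(l)) return(invisible())
  if (is.null(l$mW)) {
    l$mW <- l$W * 0; l$vW <- l$W * 0
    l$mb <- l$b * 0; l$vb <- l$b * 0
  }
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  .adam_update(l$W, l$mW, l$vW, l$dW, lr, beta1, beta2, eps, corr1, corr2)
  .adam_update(l$b, l$mb, l$vb, l$db, lr, beta1, beta2, eps, corr1, corr2)
  invisible()
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# Forward through a list of layers.
layers_forward <- function(layers, x, train = FALSE) {
  for (l in layers) x <- layer_forward(l, x, train)
  x
}

layers_backward <- function(layers, dout) {
  for (l in rev(layers)) dout <- layer_backward(l, dout)
  dout
}

all_layers <- function(model) {
  c(unlist(model$branches, recursive = FALSE), model$head)
}

# Forward pass of a model on a list of per-branch input tensors.
model_forward <- function(model, xs, train = FALSE) {
  feats <- lapply(seq_along(model$branches), function(i)
    layers_forward(model$branches[[i]], xs[[i]], train))
  fused <- if (length(feats) == 1L) feats[[1]] else do.call(rbind, feats)
  logits <- layers_forward(model$head, fused, train)
  logits
}

model_backward <- function(model, dlogits) {
  dfused <- layers_backward(model$head, dlogits)
  sizes <- vapply(model$branches, function(br) {
    # feature size = output units of last dense layer of the branch
    tail_dense <- Filter(function(l) l$type == "dense", br)
    ncol(tail_dense[[length(tail_dense)]]$W)
  }, numeric(1))
  off <- 0L
  for (i in seq_along(model$branches)) {
    di <- dfused[(off + 1):(off + sizes[i]), , drop = FALSE]
    layers_backward(model$branches[[i]], di)
    off <- off + sizes[i]
  }
  invisible()
}

# Clear forward caches (keeps serialized/finished models small).
clear_caches <- function(model) {
  for (l in all_layers(model)) {
    for (f in c("x", "out", "idx", "xdim", "dW", "db"))
      if (!is.null(l[[f]])) rm(list = f, envir = l)
  }
  invisible(model)
}

#' Learning-rate sequence of the reduce-on-plateau schedule
#'
#' Pure helper replicating the training schedule: starting from `lr0`, the
#' rate is multiplied by `factor` whenever the validation loss has failed to
#' improve for `patience` consecutive epochs (the wait counter resets after
#' each reduction and each improvement).
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param lr0 initial learning rate.
#' @param factor multiplicative reduction factor in (0, 1).
#' @param patience epochs of stagnation tolerated before reducing.
#' @return Numeric vector: the learning rate in force at each epoch.
#' @examples
#' # stagnant validation loss: two reductions after 3 and 6 epochs
#' plateau_lr_sequence(rep(1, 7), lr0 = 0.005, factor = 0.7, patience = 3)
#' @export
plateau_lr_sequence <- function(val_losses, lr0 = 0.005, factor = 0.7,
                                patience = 3) {
  lr <- lr0; best <- Inf; wait <- 0L
  out <- numeric(length(val_losses))
  for (i in seq_along(val_losses)) {
    out[i] <- lr
    if (val_losses[i] < best) {
      best <- val_losses[i]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { lr <- lr * factor; wait <- 0L }
    }
  }
  out
}
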