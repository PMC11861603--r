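#' Classification metric suite
#'
#' Computes the evaluation suite for one set of predictions: top-1 and top-3
#' accuracy, macro-averaged one-vs-rest precision and recall, macro
#' one-vs-rest ROC AUC, and the multiclass confusion matrix. Top-1 is the
#' argmax (ties broken by lowest class index); top-3 counts a hit when the
#' true class is among the three largest probabilities. Accuracy is the
#' confusion-matrix trace over the total. Per-class precision TP/(TP+FP)
#' and recall TP/(TP+FN) are macro-averaged unweighted; a class never
#' predicted contributes precision 0 (0/0 is taken as 0).
#'
#' @param true_labels integer labels in `1..K` (or a factor).
#' @param prob numeric `N x K` matrix; rows must sum to 1 within 1e-4.
#' @param class_names optional character vector of length K.
#' @return Object of class `metrics_report`: list with `top1_accuracy`,
#'   `top3_accuracy`, `precision`, `recall`, `roc_auc`, `confusion`
#'   (K x K count matrix, rows = true), `per_class` (data.frame of
#'   per-class precision/recall), `n_samples`.
#' @export
compute_metrics <- function(true_labels, prob, class_names = NULL) {
  if (is.factor(true_labels)) true_labels <- as.integer(true_labels)
  prob <- as.matrix(prob)
  K <- ncol(prob)
  n <- nrow(prob)
  if (length(true_labels) != n)
    stop("length of `true_labels` does not match rows of `prob`", call. = FALSE)
  if (any(abs(rowSums(prob) - 1) > 1e-4))
    stop("probability rows must sum to 1", call. = FALSE)
  if (any(true_labels < 1 | true_labels > K))
    stop("labels outside 1..K", call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("C", seq_len(K))

  pred <- max.col(prob, ties.method = "first")
  top1 <- mean(pred == true_labels)
  k3 <- min(3L, K)
  top3 <- mean(vapply(seq_len(n), function(i)
    true_labels[i] %in% order(prob[i, ], decreasing = TRUE)[seq_len(k3)],
    logical(1)))

  confusion <- matrix(0L, K, K, dimnames = list(true = class_names,
                                                predicted = class_names))
  for (i in seq_len(n))
    confusion[true_labels[i], pred[i]] <- confusion[true_labels[i], pred[i]] + 1L
  accuracy <- sum(diag(confusion)) / n

  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  prec_k <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec_k <- ifelse(tp + fn == 0, 0, tp / (tp + fn))

  pos_counts <- tabulate(true_labels, nbins = K)
  if (all(pos_counts == 0 | pos_counts == n))
    stop("degenerate single-class truth: ROC AUC undefined", call. = FALSE)
  aucs <- vapply(seq_len(K), function(k) {
    resp <- true_labels == k
    if (!any(resp) || all(resp)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = resp, predictor = prob[, k],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))

  structure(list(
    top1_accuracy = top1, top3_accuracy = top3, accuracy = accuracy,
    precision = mean(prec_k), recall = mean(rec_k),
    roc_auc = mean(aucs, na.rm = TRUE),
    per_class = data.frame(class = class_names, precision = prec_k,
                           recall = rec_k, auc = aucs, support = rowSums(confusion),
                           row.names = NULL),
    confusion = confusion, n_samples = n),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> n=%d\n  top-1 %.4f  top-3 %.4f  ",
                     "precision %.4f  recall %.4f  ROC AUC %.4f\n"),
              x$n_samples, x$top1_accuracy, x$top3_accuracy, x$precision,
              x$recall, x$roc_auc))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(top1 = x$top1_accuracy, top3 = x$top3_accuracy,
             precision = x$precision, recall = x$recall, roc_auc = x$roc_auc,
             n = x$n_samples)
}
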