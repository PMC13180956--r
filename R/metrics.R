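#' Confusion matrix
#'
#' Counts of true class (rows) versus predicted class (columns) for
#' 1-based integer labels.
#'
#' @param truth,estimate Equal-length vectors of class labels in `1..k`
#'   (integers or factors).
#' @param k Number of classes; defaults to the largest label seen.
#' @return A `k x k` integer matrix with `true`/`pred` dimnames.
#' @examples
#' confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), k = 2)
#' @export
confusion_matrix <- function(truth, estimate, k = NULL) {
  if (length(truth) == 0L || length(estimate) == 0L)
    abort_invalid_input("`truth` and `estimate` must be non-empty.")
  if (length(truth) != length(estimate))
    abort_invalid_input("`truth` and `estimate` must have equal length.")
  if (is.null(k)) {
    k <- max(if (is.factor(truth)) nlevels(truth) else as.integer(truth),
             if (is.factor(estimate)) nlevels(estimate) else as.integer(estimate))
  }
  truth <- as_class_labels(truth, k)
  estimate <- as_class_labels(estimate, k)
  cm <- matrix(0L, k, k, dimnames = list(true = seq_len(k), pred = seq_len(k)))
  for (i in seq_along(truth))
    cm[truth[i], estimate[i]] <- cm[truth[i], estimate[i]] + 1L
  cm
}

#' Multiclass evaluation report
#'
#' Accuracy plus one-vs-rest precision, recall, specificity and F1 per
#' class, macro-averaged (unweighted mean over classes). Zero
#' denominators follow the conservative convention: precision, recall
#' and F1 are 0 when undefined; specificity is 1 when a class has no
#' true negatives plus false positives. When class probabilities and the
#' per-sample truth are supplied, one-vs-rest ROC AUC (trapezoid rule)
#' is added per class.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @param probabilities Optional `N x K` matrix of class probabilities.
#' @param truth Per-sample true labels; required with `probabilities`.
#' @return A list of class `fusnet_metrics`: `accuracy`, `per_class`
#'   tibble, and macro-averaged scalars.
#' @export
metric_report <- function(cm, probabilities = NULL, truth = NULL) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    abort_invalid_input("`cm` must be a non-empty square confusion matrix.")
  if (any(cm < 0)) abort_invalid_input("confusion counts must be non-negative.")
  k <- nrow(cm)
  total <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  div0 <- function(num, den, default) ifelse(den > 0, num / ifelse(den > 0, den, 1), default)
  precision <- div0(tp, tp + fp, 0)
  recall <- div0(tp, tp + fn, 0)
  specificity <- div0(tn, tn + fp, 1)
  f1 <- div0(2 * precision * recall, precision + recall, 0)
  per_class <- tibble::tibble(
    class = seq_len(k), n = rowSums(cm), tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall,
    specificity = specificity, f1 = f1)
  if (!is.null(probabilities)) {
    if (is.null(truth))
      abort_invalid_input("`truth` is required when `probabilities` are supplied.")
    per_class$auc <- auc_ovr(truth, probabilities, k)
  }
  structure(list(
    accuracy = sum(tp) / total,
    per_class = per_class,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_specificity = mean(specificity),
    macro_f1 = mean(f1),
    confusion = cm), class = "fusnet_metrics")
}

#' @export
print.fusnet_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics over %d classes>\n",
    "  accuracy    %.4f\n  precision   %.4f (macro)\n",
    "  recall      %.4f (macro)\n  f1          %.4f (macro)\n",
    "  specificity %.4f (macro)\n"),
    nrow(x$per_class), x$accuracy, x$macro_precision, x$macro_recall,
    x$macro_f1, x$macro_specificity))
  invisible(x)
}

#' One-vs-rest ROC curves
#'
#' Threshold sweep over each class's predicted probability against the
#' binary one-vs-rest truth.
#'
#' @param truth Per-sample true labels in `1..K`.
#' @param probabilities `N x K` probability matrix.
#' @return A tibble with `class`, `threshold`, `fpr`, `tpr`, ordered for
#'   plotting.
#' @export
roc_ovr <- function(truth, probabilities) {
  prob <- check_probabilities(probabilities)
  k <- ncol(prob)
  truth <- as_class_labels(truth, k)
  purrr::map_dfr(seq_len(k), function(cl) {
    score <- prob[, cl]
    pos <- truth == cl
    ord <- order(score, decreasing = TRUE)
    score <- score[ord]
    pos <- pos[ord]
    np <- sum(pos)
    nn <- sum(!pos)
    tp <- cumsum(pos)
    fp <- cumsum(!pos)
    keep <- c(score[-1] != score[-length(score)], TRUE)
    tibble::tibble(
      class = cl,
      threshold = c(Inf, score[keep]),
      tpr = c(0, if (np > 0) tp[keep] / np else rep(0, sum(keep))),
      fpr = c(0, if (nn > 0) fp[keep] / nn else rep(0, sum(keep))))
  })
}

# Trapezoid-rule AUC per class from the ROC sweep; classes absent from
# `truth` get NA.
auc_ovr <- function(truth, probabilities, k) {
  roc <- roc_ovr(truth, probabilities)
  truth <- as_class_labels(truth, k)
  vapply(seq_len(k), function(cl) {
    if (!any(truth == cl) || all(truth == cl)) return(NA_real_)
    r <- roc[roc$class == cl, ]
    sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-length(r$tpr)]) / 2)
  }, numeric(1))
}

#' Write an evaluation report to disk
#'
#' Per-class metrics as CSV, the macro summary as JSON, and the
#' confusion matrix as CSV.
#'
#' @param metrics A [metric_report()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_metric_report <- function(metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort_io(sprintf("cannot create directory: %s", dir))
  paths <- c(
    per_class = file.path(dir, "metrics_per_class.csv"),
    summary = file.path(dir, "metrics_summary.json"),
    confusion = file.path(dir, "confusion_matrix.csv"))
  readr::write_csv(metrics$per_class, paths[["per_class"]])
  jsonlite::write_json(
    list(accuracy = metrics$accuracy,
         macro_precision = metrics$macro_precision,
         macro_recall = metrics$macro_recall,
         macro_f1 = metrics$macro_f1,
         macro_specificity = metrics$macro_specificity),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  utils::write.csv(metrics$confusion, paths[["confusion"]])
  invisible(paths)
}
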