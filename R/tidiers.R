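#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training fit
#'
#' @param x A `fusnet_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `train_accuracy`, `val_loss`, `val_accuracy`).
#' @export
tidy.fusnet_fit <- function(x, ...) {
  x$history
}

#' Summarize a training fit in one row
#'
#' @param x A `fusnet_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the final-epoch losses, the best
#'   validation accuracy, epoch count and parameter count.
#' @export
glance.fusnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs = nrow(x$history),
    train_loss = h$train_loss, train_accuracy = h$train_accuracy,
    val_loss = h$val_loss, val_accuracy = h$val_accuracy,
    best_val_accuracy = max(x$history$val_accuracy),
    parameters = count_parameters(x$model),
    gflops = count_flops(x$model) / 1e9)
}

#' Tidy a metric report
#'
#' @param x A `fusnet_metrics`.
#' @param ... Unused.
#' @return The per-class tibble of one-vs-rest metrics.
#' @export
tidy.fusnet_metrics <- function(x, ...) {
  x$per_class
}

#' Summarize a metric report in one row
#'
#' @param x A `fusnet_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of accuracy and the macro-averaged metrics.
#' @export
glance.fusnet_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1,
                 macro_specificity = x$macro_specificity)
}

#' Plot training curves
#'
#' Loss and accuracy per epoch for the train and validation splits.
#'
#' @param object A `fusnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusnet_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = c("split", "measure"),
                        names_sep = "_", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics
#'
#' One-vs-rest precision, recall, F1 and specificity per class.
#'
#' @param object A `fusnet_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusnet_metrics <- function(object, ...) {
  long <- object$per_class |>
    dplyr::select("class", "precision", "recall", "f1", "specificity") |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$class),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param roc A tibble from [roc_ovr()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = factor(.data$class))) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
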