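#' @useDynLib fusnetcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||%
#' @importFrom stats rnorm runif predict
NULL

abort_invalid_input <- function(msg) {
  abort(msg, class = c("fusnet_invalid_input", "fusnet_error"))
}

abort_invalid_parameter <- function(msg) {
  abort(msg, class = c("fusnet_invalid_parameter", "fusnet_error"))
}

abort_config <- function(msg) {
  abort(msg, class = c("fusnet_config_error", "fusnet_error"))
}

abort_io <- function(msg) {
  abort(msg, class = c("fusnet_io_error", "fusnet_error"))
}

# Coerce an image to an H x W x C array; matrices become single-channel.
as_image_array <- function(x, arg = "image") {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (!is.array(x) || length(dim(x)) != 3L)
    abort_invalid_input(sprintf("`%s` must be an H x W x C array or a matrix.", arg))
  if (any(dim(x) == 0L))
    abort_invalid_input(sprintf("`%s` is empty.", arg))
  if (!dim(x)[3] %in% c(1L, 3L))
    abort_invalid_input(sprintf("`%s` must have 1 or 3 channels, not %d.", arg, dim(x)[3]))
  if (!all(is.finite(x)))
    abort_invalid_input(sprintf("`%s` contains non-finite values.", arg))
  x
}

validate_raw_image <- function(x, arg = "image") {
  x <- as_image_array(x, arg)
  if (min(x) < 0 || max(x) > 255)
    abort_invalid_input(sprintf("`%s` intensities must lie in [0, 255].", arg))
  x
}

# Labels are 1-based class indices (or factors); returns integer vector.
as_class_labels <- function(labels, k) {
  if (is.factor(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || length(labels) == 0L)
    abort_invalid_input("labels must be a non-empty integer vector.")
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L) || any(labels > k))
    abort_invalid_input(sprintf("labels must be integers in 1..%d.", k))
  labels
}
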