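#' Loss configuration
#'
#' Bundles the loss family and its hyperparameters. The Huber-type
#' families switch from a quadratic to a linear penalty at residual
#' magnitude `delta`; `delta = 1` is the setting used throughout the
#' training harnesses. `focal_gamma` is the focusing exponent of the focal
#' loss.
#'
#' @param family One of `"improved_huber"`, `"huber"`, `"cross_entropy"`,
#'   `"focal"`, `"exponential"`.
#' @param delta Positive transition threshold for the Huber families.
#' @param focal_gamma Non-negative focusing exponent.
#' @param reduction `"mean"` or `"sum"` over the batch.
#' @return A list of class `fusnet_loss_config`.
#' @export
loss_config <- function(family = c("improved_huber", "huber", "cross_entropy",
                                   "focal", "exponential"),
                        delta = 1, focal_gamma = 2,
                        reduction = c("mean", "sum")) {
  family <- match.arg(family)
  reduction <- match.arg(reduction)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    abort_invalid_parameter("`delta` must be a positive finite number.")
  if (!is.numeric(focal_gamma) || length(focal_gamma) != 1L ||
      !is.finite(focal_gamma) || focal_gamma < 0)
    abort_invalid_parameter("`focal_gamma` must be non-negative.")
  structure(list(family = family, delta = delta, focal_gamma = focal_gamma,
                 reduction = reduction),
            class = "fusnet_loss_config")
}

check_errors_finite <- function(error) {
  if (length(error) == 0L) abort_invalid_input("empty residual vector.")
  if (!all(is.finite(error))) abort_invalid_input("residuals must be finite.")
  invisible(error)
}

check_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    abort_invalid_parameter("`delta` must be a positive finite number.")
  invisible(delta)
}

#' Huber loss, elementwise
#'
#' The classical robust penalty: `0.5 * error^2` for `|error| <= delta`,
#' and `delta * |error| - 0.5 * delta` beyond. Note the linear branch
#' subtracts `0.5 * delta` (not `0.5 * delta^2`), so the function has a
#' jump of `0.5 * delta * (delta - 1)` at the transition that vanishes
#' only at `delta = 1`; see [improved_huber_loss()] for the variant that
#' is continuous for every `delta`.
#'
#' @param error Numeric vector of residuals (predicted minus reference).
#' @param delta Positive transition threshold.
#' @return Numeric vector of per-element loss values.
#' @examples
#' huber_loss(c(0.5, 3), delta = 2)
#' @export
huber_loss <- function(error, delta = 1) {
  check_errors_finite(error)
  check_delta(delta)
  a <- abs(error)
  ifelse(a <= delta, 0.5 * error^2, delta * a - 0.5 * delta)
}

#' Improved Huber loss, elementwise
#'
#' Quadratic for `|error| <= delta`, `delta * |error| - 0.5 * delta^2`
#' beyond. Both the value and the first derivative are continuous at the
#' transition for every `delta > 0`, the gradient magnitude is bounded by
#' `delta` (outlier robustness), and the penalty never exceeds
#' `0.5 * error^2`. At `delta = 1` it coincides exactly with
#' [huber_loss()].
#'
#' @inheritParams huber_loss
#' @return Numeric vector of per-element loss values.
#' @examples
#' improved_huber_loss(c(0.5, 3), delta = 2)
#' @export
improved_huber_loss <- function(error, delta = 1) {
  check_errors_finite(error)
  check_delta(delta)
  a <- abs(error)
  ifelse(a <= delta, 0.5 * error^2, delta * a - 0.5 * delta^2)
}

# dL/derror; identical for both Huber families (the linear-branch constants
# do not affect the derivative): error on the quadratic branch, clipped to
# +/- delta beyond.
huber_grad <- function(error, delta) {
  pmin(pmax(error, -delta), delta)
}

#' Reduce per-element losses to a scalar
#'
#' @param per_element Non-empty numeric vector of per-element losses.
#' @param reduction `"mean"` or `"sum"`.
#' @return A list of class `fusnet_loss_value` with elements `value` and
#'   `per_element`.
#' @export
reduce_loss <- function(per_element, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (length(per_element) == 0L)
    abort_invalid_input("`per_element` must be non-empty.")
  value <- if (reduction == "mean") mean(per_element) else sum(per_element)
  structure(list(value = value, per_element = per_element),
            class = "fusnet_loss_value")
}

#' @export
print.fusnet_loss_value <- function(x, ...) {
  cat(sprintf("<loss value: %.6g over %d elements>\n",
              x$value, length(x$per_element)))
  invisible(x)
}

check_probabilities <- function(prob, tol = 1e-6) {
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
  if (!is.matrix(prob) || nrow(prob) == 0L)
    abort_invalid_input("`probabilities` must be a non-empty N x K matrix.")
  if (!all(is.finite(prob)) || any(prob < -tol))
    abort_invalid_input("probabilities must be finite and non-negative.")
  if (any(abs(rowSums(prob) - 1) > tol))
    abort_invalid_input("each probability row must sum to 1.")
  prob
}

one_hot <- function(labels, k) {
  y <- matrix(0, length(labels), k)
  y[cbind(seq_along(labels), labels)] <- 1
  y
}

#' Classification loss over a batch of probability rows
#'
#' Evaluates the configured loss family on softmax probabilities against
#' integer class labels. The Huber families operate on the elementwise
#' residuals between the probability vector and the one-hot label vector,
#' averaged over classes per sample; cross-entropy and focal use the true
#' class probability (clamped to `[1e-12, 1]` before the log); the
#' exponential loss is `exp(-margin)` on the `+/-1`-encoded one-vs-rest
#' margin `t * (2p - 1)`, averaged over classes.
#'
#' @param probabilities `N x K` matrix of class probabilities (rows sum
#'   to 1).
#' @param labels Integer class labels in `1..K` (or a factor).
#' @param config A [loss_config()].
#' @return A `fusnet_loss_value`: the batch-reduced `value` plus the
#'   per-sample losses.
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' classification_loss(p, 1L, loss_config("improved_huber"))$value # 0.125
#' @export
classification_loss <- function(probabilities, labels, config = loss_config()) {
  out <- classification_loss_grad(probabilities, labels, config)
  reduce_loss(out$per_sample, config$reduction)
}

# Returns per-sample losses and dL/dprobabilities for the *mean* batch
# reduction (training always uses mean); grad rows are scaled by 1/N.
classification_loss_grad <- function(probabilities, labels, config) {
  prob <- check_probabilities(probabilities)
  k <- ncol(prob)
  n <- nrow(prob)
  labels <- as_class_labels(labels, k)
  if (length(labels) != n)
    abort_invalid_input("length(labels) must equal nrow(probabilities).")
  y <- one_hot(labels, k)
  grad <- matrix(0, n, k)
  eps <- 1e-12
  per <- switch(config$family,
    huber = ,
    improved_huber = {
      r <- prob - y
      fn <- if (config$family == "huber") huber_loss else improved_huber_loss
      lv <- matrix(fn(as.numeric(r), config$delta), n, k)
      grad <- huber_grad(r, config$delta) / k
      rowMeans(lv)
    },
    cross_entropy = {
      py <- pmax(prob[cbind(seq_len(n), labels)], eps)
      grad[cbind(seq_len(n), labels)] <- -1 / py
      -log(py)
    },
    focal = {
      g <- config$focal_gamma
      py <- pmax(prob[cbind(seq_len(n), labels)], eps)
      grad[cbind(seq_len(n), labels)] <-
        g * (1 - py)^(pmax(g - 1, 0)) * log(py) - (1 - py)^g / py
      -(1 - py)^g * log(py)
    },
    exponential = {
      tt <- 2 * y - 1
      m <- tt * (2 * prob - 1)
      e <- exp(-m)
      grad <- -2 * tt * e / k
      rowMeans(e)
    }
  )
  list(per_sample = per, grad = grad / n)
}

#' Mean absolute (L1) reconstruction loss
#'
#' The mean absolute elementwise difference between a reconstructed
#' feature map or image and its reference,
#' \eqn{\frac{1}{nm}\sum_{i,j} |SR(i,j) - y(i,j)|}, averaged over
#' channels (and batch, if present).
#'
#' @param sr,reference Arrays of identical dimensions.
#' @return A `fusnet_loss_value`.
#' @export
l1_reconstruction <- function(sr, reference) {
  if (!identical(dim(sr) %||% length(sr), dim(reference) %||% length(reference)))
    abort_invalid_input("`sr` and `reference` must have identical dimensions.")
  d <- abs(sr - reference)
  reduce_loss(as.numeric(d), "mean")
}

l1_reconstruction_grad <- function(sr, reference) {
  sign(sr - reference) / length(sr)
}

#' Fit a slope by gradient descent under a chosen penalty
#'
#' Minimizes `sum(rho(b * x - y))` over the scalar slope `b` by plain
#' gradient descent, for `rho` squared error or a Huber-type penalty.
#' A small demonstration utility for the robustness of the bounded-gradient
#' losses: with heavy-tailed outliers in `y` the Huber-type estimate is far
#' less biased than the least-squares one.
#'
#' @param x,y Numeric vectors of equal length.
#' @param loss `"improved_huber"`, `"huber"` or `"squared"`.
#' @param delta Transition threshold for the Huber families.
#' @param lr Gradient-descent step size.
#' @param iters Number of iterations.
#' @param init Starting slope.
#' @return The fitted slope (numeric scalar).
#' @export
fit_slope_gd <- function(x, y, loss = c("improved_huber", "huber", "squared"),
                         delta = 1, lr = 0.01, iters = 1000, init = 0) {
  loss <- match.arg(loss)
  if (length(x) != length(y) || length(x) == 0L)
    abort_invalid_input("`x` and `y` must be non-empty and of equal length.")
  psi <- if (loss == "squared") function(r) r else function(r) huber_grad(r, delta)
  b <- init
  for (i in seq_len(iters)) {
    b <- b - lr * mean(psi(b * x - y) * x)
  }
  b
}
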