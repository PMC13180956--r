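# Tensor layout convention: feature maps are (H, W, C, N) arrays,
# column-major. Internal nn_*_fwd functions return list(out, cache);
# nn_*_bwd take the upstream gradient and return gradients with respect
# to inputs and parameters. Exported wrappers expose the forward maps.

batch4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L)
    abort_invalid_input("expected an (H, W, C, N) feature map.")
  x
}

## ---- convolution ----------------------------------------------------------

nn_conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x)
  kd <- dim(W)
  cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], d[4],
                     kd[1], kd[2], stride, pad)
  Wm <- matrix(W, nrow = kd[1] * kd[2] * kd[3])
  out_mat <- crossprod(Wm, cols) + b        # Cout x M
  ho <- (d[1] + 2 * pad - kd[1]) %/% stride + 1L
  wo <- (d[2] + 2 * pad - kd[2]) %/% stride + 1L
  out <- cpp_mat2feat(out_mat, ho, wo, kd[4], d[4])
  list(out = out, cache = list(x = x, stride = stride, pad = pad, kd = kd))
}

nn_conv_bwd <- function(dout, W, cache) {
  d <- dim(cache$x)
  kd <- cache$kd
  dmat <- cpp_feat2mat(dout, dim(dout)[1], dim(dout)[2], kd[4], d[4])
  cols <- cpp_im2col(as.numeric(cache$x), d[1], d[2], d[3], d[4],
                     kd[1], kd[2], cache$stride, cache$pad)
  dW <- cols %*% t(dmat)
  dim(dW) <- kd
  db <- rowSums(dmat)
  Wm <- matrix(W, nrow = kd[1] * kd[2] * kd[3])
  dcols <- Wm %*% dmat
  dx <- cpp_col2im(dcols, d[1], d[2], d[3], d[4],
                   kd[1], kd[2], cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

## ---- batch normalization --------------------------------------------------

#' Batch normalization over the channel dimension
#'
#' Standardizes each channel of a mini-batch to zero mean and unit
#' variance, \eqn{\hat x = (x - \mu_B)/\sqrt{\sigma_B^2 + \epsilon_B}},
#' then applies the trainable affine map \eqn{y = \gamma_B \hat x +
#' \beta_B}. In training mode the batch statistics are used and the
#' running statistics updated (momentum 0.1, population variance); in
#' inference mode the running statistics are used. A training batch must
#' contain at least two samples.
#'
#' @param x An `(H, W, C, N)` feature-map batch (or `(H, W, C)` single map).
#' @param gamma,beta Per-channel scale and shift (length `C`).
#' @param running_mean,running_var Per-channel running statistics.
#' @param epsilon Variance floor, default `1e-5`.
#' @param training Logical; use batch statistics and update running ones.
#' @return A list: `out` (normalized batch), `running_mean`, `running_var`.
#' @export
batch_norm <- function(x, gamma, beta, running_mean = NULL, running_var = NULL,
                       epsilon = 1e-5, training = TRUE) {
  x <- batch4(x)
  C <- dim(x)[3]
  running_mean <- running_mean %||% numeric(C)
  running_var <- running_var %||% rep(1, C)
  st <- list(gamma = gamma, beta = beta, mean = running_mean,
             var = running_var, eps = epsilon, momentum = 0.1)
  f <- nn_bn_fwd(x, st, training = training)
  list(out = f$out, running_mean = f$state$mean, running_var = f$state$var)
}

nn_bn_fwd <- function(x, st, training) {
  d <- dim(x)
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  if (training && d[4] < 2L)
    abort_invalid_input("batch normalization in training mode needs a batch of >= 2.")
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(xp) <- c(m, C)
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2L, mu)
    v <- colMeans(xc^2)
    st$mean <- (1 - st$momentum) * st$mean + st$momentum * mu
    st$var <- (1 - st$momentum) * st$var + st$momentum * v
  } else {
    mu <- st$mean
    v <- st$var
    xc <- sweep(xp, 2L, mu)
  }
  invstd <- 1 / sqrt(v + st$eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  yp <- sweep(sweep(xhat, 2L, st$gamma, `*`), 2L, st$beta, `+`)
  dim(yp) <- c(d[1], d[2], d[4], C)
  out <- aperm(yp, c(1L, 2L, 4L, 3L))
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, d = d, training = training),
       state = st)
}

nn_bn_bwd <- function(dout, st, cache) {
  d <- cache$d
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  dp <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(dp) <- c(m, C)
  dgamma <- colSums(dp * cache$xhat)
  dbeta <- colSums(dp)
  if (cache$training) {
    # dx = gamma*invstd * (dp - mean(dp) - xhat * mean(dp * xhat))
    dxp <- sweep(dp, 2L, dbeta / m) - sweep(cache$xhat, 2L, dgamma / m, `*`)
    dxp <- sweep(dxp, 2L, st$gamma * cache$invstd, `*`)
  } else {
    dxp <- sweep(dp, 2L, st$gamma * cache$invstd, `*`)
  }
  dim(dxp) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dxp, c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations / pooling ------------------------------------------------

#' Rectified linear unit
#'
#' Elementwise `max(0, z)`; shape-preserving.
#'
#' @param z Numeric vector, matrix or array of finite values.
#' @return Same shape as `z`.
#' @export
relu <- function(z) {
  if (!all(is.finite(z))) abort_invalid_input("`z` must be finite.")
  pmax(z, 0)
}

nn_relu_fwd <- function(x) {
  list(out = pmax(x, 0), cache = x > 0)
}

nn_relu_bwd <- function(dout, mask) {
  dout * mask
}

#' 2x2 stride-2 max pooling
#'
#' Replaces each non-overlapping 2x2 block by its maximum, per channel,
#' halving both spatial dimensions. Height and width must be even.
#'
#' @param map An `(H, W, C, N)` or `(H, W, C)` feature map.
#' @return The pooled map (batch dimension preserved if supplied).
#' @export
max_pool <- function(map) {
  had_batch <- length(dim(map)) == 4L
  x <- batch4(map)
  out <- nn_pool_fwd(x)$out
  if (!had_batch) dim(out) <- dim(out)[1:3]
  out
}

nn_pool_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    abort_invalid_input("max pooling requires even height and width.")
  r <- cpp_maxpool(as.numeric(x), d[1], d[2], d[3], d[4])
  list(out = r$out, cache = list(idx = r$idx, d = d))
}

nn_pool_bwd <- function(dout, cache) {
  d <- cache$d
  cpp_maxpool_bwd(as.numeric(dout), cache$idx, d[1], d[2], d[3], d[4])
}

# Global average pool (H, W, C, N) -> C x N matrix.
nn_gap_fwd <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(xm), d[3], d[4])
  list(out = out, cache = d)
}

nn_gap_bwd <- function(dout, d) {
  hw <- d[1] * d[2]
  dx <- rep(as.numeric(dout) / hw, each = hw)
  dim(dx) <- d
  dx
}

## ---- fully connected ------------------------------------------------------

# x: Cin x N; W: Cout x Cin; out: Cout x N.
nn_fc_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = x)
}

nn_fc_bwd <- function(dout, W, x) {
  list(dx = crossprod(W, dout), dW = tcrossprod(dout, x), db = rowSums(dout))
}

nn_sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- pixel shuffle --------------------------------------------------------

# 0-based index map from output plane positions to input plane positions.
pixel_shuffle_map <- function(H, W, Cin, a) {
  C <- Cin %/% (a * a)
  Ha <- H * a
  Wa <- W * a
  i <- rep(0:(Ha - 1L), times = Wa * C)
  j <- rep(rep(0:(Wa - 1L), each = Ha), times = C)
  cc <- rep(0:(C - 1L), each = Ha * Wa)
  ci <- C * a * (i %% a) + C * (j %% a) + cc
  (i %/% a) + H * (j %/% a) + H * W * ci + 1L
}

#' Sub-pixel (pixel shuffle) rearrangement
#'
#' Losslessly rearranges an `H x W x (C a^2)` feature map into an
#' `(a H) x (a W) x C` map: `out[i, j, c] = in[floor(i/a), floor(j/a),
#' C*a*(i mod a) + C*(j mod a) + c]` (0-based indices). The map is a
#' bijection, so the multiset of values is conserved; `a = 1` is the
#' identity.
#'
#' @param input An `(H, W, Cin, N)` or `(H, W, Cin)` feature map with
#'   `Cin` divisible by `a^2`.
#' @param a Integer upscale factor, `a >= 1`.
#' @return The rearranged map.
#' @export
pixel_shuffle <- function(input, a) {
  if (length(a) != 1L || a < 1 || a != as.integer(a))
    abort_invalid_parameter("`a` must be a positive integer.")
  a <- as.integer(a)
  had_batch <- length(dim(input)) == 4L
  x <- batch4(input)
  d <- dim(x)
  if (d[3] %% (a * a) != 0L)
    abort_invalid_input(sprintf("channels (%d) not divisible by a^2 = %d.", d[3], a * a))
  out <- nn_ps_fwd(x, a)$out
  if (!had_batch) dim(out) <- dim(out)[1:3]
  out
}

nn_ps_fwd <- function(x, a) {
  d <- dim(x)
  map <- pixel_shuffle_map(d[1], d[2], d[3], a)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  out <- xm[map, , drop = FALSE]
  dim(out) <- c(d[1] * a, d[2] * a, d[3] %/% (a * a), d[4])
  list(out = out, cache = list(map = map, d = d))
}

nn_ps_bwd <- function(dout, cache) {
  d <- cache$d
  dm <- dout
  dim(dm) <- c(d[1] * d[2] * d[3], d[4])
  dx <- dm
  dx[cache$map, ] <- dm
  dim(dx) <- d
  dx
}
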