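#' Network configuration
#'
#' Collects every architecture hyperparameter of the multipath residual
#' channel-attention classifier. The stem is fixed at three
#' conv-BN-ReLU-pool stages with 16/32/64 kernels and 2x2 stride-2
#' pooling; the residual trunk width equals the stem output (64
#' channels); `rca_per_rg` residual channel-attention blocks sit inside
#' each residual group; pixel-shuffle fusion upsamples by `scale_factor`
#' into `fusion_channels` channels.
#'
#' @param input_size Integer `(H, W)` input resolution; both divisible
#'   by 8. Default `c(128, 128)`.
#' @param input_channels Number of input channels (3 for RGB).
#' @param num_classes Number of output classes (default 38, the Plant
#'   Village class count).
#' @param stem_kernels Convolution filter counts of the three stem
#'   stages; must be exactly `c(16, 32, 64)`.
#' @param conv_kernel Spatial kernel size of all convolutions (the
#'   attention bottleneck uses 1x1 fully connected maps).
#' @param bn_epsilon Batch-normalization variance floor, default `1e-5`.
#' @param rca_per_rg Number of residual channel-attention blocks per
#'   residual group, `N >= 1`.
#' @param attention_reduction Channel-attention bottleneck reduction
#'   ratio.
#' @param rg_channels Residual-trunk width; must equal
#'   `stem_kernels[3]`.
#' @param scale_factor Pixel-shuffle upscale factor `a >= 1`.
#' @param fusion_channels Channel count of the fused map.
#' @param sr_head Enable the auxiliary reconstruction head.
#' @param recon_weight Weight `lambda >= 0` of the L1 reconstruction
#'   loss in the training objective.
#' @param variant Architecture variant for ablations: `"stem"` (plain
#'   CNN), `"rg"` (one residual group), `"multipath"` (three groups,
#'   two-path sum), `"full"` (adds pixel-shuffle fusion).
#' @return A list of class `fusnet_config`.
#' @export
net_config <- function(input_size = c(128L, 128L), input_channels = 3L,
                       num_classes = 38L, stem_kernels = c(16L, 32L, 64L),
                       conv_kernel = 3L, bn_epsilon = 1e-5,
                       rca_per_rg = 2L, attention_reduction = 4L,
                       rg_channels = 64L, scale_factor = 2L,
                       fusion_channels = 32L, sr_head = FALSE,
                       recon_weight = 0,
                       variant = c("full", "stem", "rg", "multipath")) {
  variant <- match.arg(variant)
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  input_size <- as.integer(input_size)
  if (any(input_size < 8L) || any(input_size %% 8L != 0L))
    abort_config("`input_size` must be at least 8 and divisible by 8 (three 2x2 pools).")
  if (!identical(as.integer(stem_kernels), c(16L, 32L, 64L)))
    abort_config("`stem_kernels` must be exactly c(16, 32, 64).")
  if (rca_per_rg < 1L) abort_config("`rca_per_rg` must be >= 1.")
  if (scale_factor < 1L) abort_config("`scale_factor` must be >= 1.")
  if (num_classes < 2L) abort_config("`num_classes` must be >= 2.")
  if (rg_channels != stem_kernels[3])
    abort_config("`rg_channels` must equal the last stem width (64).")
  if (attention_reduction < 1L || rg_channels %% attention_reduction != 0L)
    abort_config("`attention_reduction` must divide `rg_channels`.")
  if (bn_epsilon <= 0) abort_config("`bn_epsilon` must be positive.")
  if (recon_weight < 0) abort_config("`recon_weight` must be >= 0.")
  structure(list(
    input_size = input_size, input_channels = as.integer(input_channels),
    num_classes = as.integer(num_classes),
    stem_kernels = as.integer(stem_kernels),
    conv_kernel = as.integer(conv_kernel), bn_epsilon = bn_epsilon,
    rca_per_rg = as.integer(rca_per_rg),
    attention_reduction = as.integer(attention_reduction),
    rg_channels = as.integer(rg_channels),
    scale_factor = as.integer(scale_factor),
    fusion_channels = as.integer(fusion_channels),
    sr_head = isTRUE(sr_head), recon_weight = recon_weight,
    variant = variant), class = "fusnet_config")
}

#' @export
print.fusnet_config <- function(x, ...) {
  cat(sprintf("<fusnet config: %dx%dx%d -> %d classes, variant '%s'>\n",
              x$input_size[1], x$input_size[2], x$input_channels,
              x$num_classes, x$variant))
  invisible(x)
}

## ---- weight constructors --------------------------------------------------

init_conv <- function(kh, kw, cin, cout, init) {
  W <- if (init == "zero") array(0, c(kh, kw, cin, cout)) else
    array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  list(W = W, b = numeric(cout))
}

init_fc <- function(cin, cout, init, gain = 2) {
  W <- if (init == "zero") matrix(0, cout, cin) else
    matrix(rnorm(cout * cin, sd = sqrt(gain / cin)), cout, cin)
  list(W = W, b = numeric(cout))
}

#' Weights for a residual channel-attention block
#'
#' Two `kernel x kernel` convolutions with a ReLU between them, plus the
#' squeeze-excitation style attention bottleneck. `init = "zero"` gives
#' the all-zero weights under which the block is exactly the identity.
#'
#' @param channels Trunk width.
#' @param reduction Bottleneck reduction ratio.
#' @param kernel Convolution kernel size.
#' @param init `"kaiming"` or `"zero"`.
#' @return A nested weight list (`conv1`, `conv2`, `att`).
#' @export
rca_weights <- function(channels, reduction = 4L, kernel = 3L,
                        init = c("kaiming", "zero")) {
  init <- match.arg(init)
  mid <- channels %/% reduction
  list(conv1 = init_conv(kernel, kernel, channels, channels, init),
       conv2 = init_conv(kernel, kernel, channels, channels, init),
       att = c(stats::setNames(init_fc(channels, mid, init), c("W1", "b1")),
               stats::setNames(init_fc(mid, channels, init, gain = 1), c("W2", "b2"))))
}

#' Weights for a residual group
#'
#' `n_rca` chained residual channel-attention blocks followed by a tail
#' convolution, wrapped in a long skip connection.
#'
#' @inheritParams rca_weights
#' @param n_rca Number of chained RCA blocks, `>= 1`.
#' @return A nested weight list (`rca` list, `tail`).
#' @export
rg_weights <- function(channels, n_rca = 2L, reduction = 4L, kernel = 3L,
                       init = c("kaiming", "zero")) {
  init <- match.arg(init)
  if (n_rca < 1L) abort_config("`n_rca` must be >= 1.")
  list(rca = lapply(seq_len(n_rca), function(i)
         rca_weights(channels, reduction, kernel, init)),
       tail = init_conv(kernel, kernel, channels, channels, init))
}

## ---- block forward / backward ---------------------------------------------

bcast_mul <- function(x, g) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  xm <- xm * rep(as.numeric(g), each = d[1] * d[2])
  dim(xm) <- d
  xm
}

spat_colsums <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  matrix(colSums(xm), d[3], d[4])
}

rca_fwd <- function(x, w) {
  c1 <- nn_conv_fwd(x, w$conv1$W, w$conv1$b)
  r1 <- nn_relu_fwd(c1$out)
  c2 <- nn_conv_fwd(r1$out, w$conv2$W, w$conv2$b)
  tt <- c2$out
  gp <- nn_gap_fwd(tt)
  f1 <- nn_fc_fwd(gp$out, w$att$W1, w$att$b1)
  a1 <- nn_relu_fwd(f1$out)
  f2 <- nn_fc_fwd(a1$out, w$att$W2, w$att$b2)
  g <- nn_sigmoid(f2$out)
  out <- bcast_mul(tt, g) + x
  list(out = out,
       cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                    gp = gp$cache, f1 = f1$cache, a1 = a1$cache,
                    f2 = f2$cache, g = g, t = tt),
       gate = g)
}

rca_bwd <- function(dout, w, cache) {
  g <- cache$g
  dt <- bcast_mul(dout, g)
  dg <- spat_colsums(dout * cache$t)
  dsig <- dg * g * (1 - g)
  f2b <- nn_fc_bwd(dsig, w$att$W2, cache$f2)
  da1 <- nn_relu_bwd(f2b$dx, cache$a1)
  f1b <- nn_fc_bwd(da1, w$att$W1, cache$f1)
  dt <- dt + nn_gap_bwd(f1b$dx, cache$gp)
  c2b <- nn_conv_bwd(dt, w$conv2$W, cache$c2)
  dr1 <- nn_relu_bwd(c2b$dx, cache$r1)
  c1b <- nn_conv_bwd(dr1, w$conv1$W, cache$c1)
  list(dx = c1b$dx + dout,
       grads = list(conv1 = list(W = c1b$dW, b = c1b$db),
                    conv2 = list(W = c2b$dW, b = c2b$db),
                    att = list(W1 = f1b$dW, b1 = f1b$db,
                               W2 = f2b$dW, b2 = f2b$db)))
}

rg_fwd <- function(x, w) {
  h <- x
  caches <- vector("list", length(w$rca))
  for (i in seq_along(w$rca)) {
    r <- rca_fwd(h, w$rca[[i]])
    h <- r$out
    caches[[i]] <- r$cache
  }
  tl <- nn_conv_fwd(h, w$tail$W, w$tail$b)
  list(out = x + tl$out, cache = list(rca = caches, tail = tl$cache))
}

rg_bwd <- function(dout, w, cache) {
  tlb <- nn_conv_bwd(dout, w$tail$W, cache$tail)
  dh <- tlb$dx
  grads <- list(rca = vector("list", length(w$rca)),
                tail = list(W = tlb$dW, b = tlb$db))
  for (i in rev(seq_along(w$rca))) {
    rb <- rca_bwd(dh, w$rca[[i]], cache$rca[[i]])
    dh <- rb$dx
    grads$rca[[i]] <- rb$grads
  }
  list(dx = dh + dout, grads = grads)
}

multipath_fwd <- function(x, wlist) {
  r1 <- rg_fwd(x, wlist[[1]])
  r2 <- rg_fwd(r1$out, wlist[[2]])
  r3 <- rg_fwd(x, wlist[[3]])
  list(out = r2$out + r3$out,
       cache = list(r1 = r1$cache, r2 = r2$cache, r3 = r3$cache))
}

multipath_bwd <- function(dout, wlist, cache) {
  b2 <- rg_bwd(dout, wlist[[2]], cache$r2)
  b1 <- rg_bwd(b2$dx, wlist[[1]], cache$r1)
  b3 <- rg_bwd(dout, wlist[[3]], cache$r3)
  list(dx = b1$dx + b3$dx, grads = list(b1$grads, b2$grads, b3$grads))
}

fusion_fwd <- function(omr, fl, w, a, low_stride) {
  mr <- nn_conv_fwd(omr, w$mr$W, w$mr$b)
  p1 <- nn_ps_fwd(mr$out, a)
  lo <- nn_conv_fwd(fl, w$low$W, w$low$b, stride = low_stride)
  if (!identical(dim(lo$out)[1:2], dim(mr$out)[1:2]))
    abort_invalid_input("fusion branches disagree in spatial size after projection.")
  p2 <- nn_ps_fwd(lo$out, a)
  list(out = p1$out + p2$out,
       cache = list(mr = mr$cache, p1 = p1$cache, lo = lo$cache, p2 = p2$cache))
}

fusion_bwd <- function(dout, w, cache) {
  dmr <- nn_conv_bwd(nn_ps_bwd(dout, cache$p1), w$mr$W, cache$mr)
  dlo <- nn_conv_bwd(nn_ps_bwd(dout, cache$p2), w$low$W, cache$lo)
  list(domr = dmr$dx, dfl = dlo$dx,
       grads = list(mr = list(W = dmr$dW, b = dmr$db),
                    low = list(W = dlo$dW, b = dlo$db)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

head_fwd <- function(feat, w) {
  gp <- nn_gap_fwd(feat)
  fc <- nn_fc_fwd(gp$out, w$W, w$b)
  logits <- t(fc$out)
  list(probabilities = softmax_rows(logits), logits = logits,
       cache = list(gp = gp$cache, fc = fc$cache))
}

head_bwd <- function(dlogits, w, cache) {
  fb <- nn_fc_bwd(t(dlogits), w$W, cache$fc)
  list(dfeat = nn_gap_bwd(fb$dx, cache$gp),
       grads = list(W = fb$dW, b = fb$db))
}

## ---- exported block operations --------------------------------------------

#' Residual channel-attention block
#'
#' Two convolutions with a ReLU between them, channel attention (global
#' average pool, bottleneck with ReLU, sigmoid gate, channelwise
#' multiply), and a short skip connection adding the block input. With
#' all-zero weights the block is exactly the identity.
#'
#' @param input `(H, W, C, N)` or `(H, W, C)` feature map.
#' @param weights Weight list from [rca_weights()].
#' @return The block output, same shape as `input`.
#' @export
rca_block <- function(input, weights) {
  had_batch <- length(dim(input)) == 4L
  x <- batch4(input)
  if (dim(x)[3] != dim(weights$conv1$W)[3])
    abort_invalid_input("channel count does not match the block weights.")
  out <- rca_fwd(x, weights)$out
  if (!had_batch) dim(out) <- dim(out)[1:3]
  out
}

#' Residual group
#'
#' `N >= 1` chained residual channel-attention blocks, a tail
#' convolution, and a long skip connection:
#' `O = I + W_tail(RCA_N(... RCA_1(I)))`.
#'
#' @inheritParams rca_block
#' @param weights Weight list from [rg_weights()].
#' @return The group output, same shape as `input`.
#' @export
rg_block <- function(input, weights) {
  if (length(weights$rca) < 1L) abort_config("a residual group needs >= 1 RCA block.")
  had_batch <- length(dim(input)) == 4L
  x <- batch4(input)
  out <- rg_fwd(x, weights)$out
  if (!had_batch) dim(out) <- dim(out)[1:3]
  out
}

#' Multipath residual trunk
#'
#' Two parallel residual paths over the same input: path one applies two
#' stacked residual groups, path two applies a single group; the outputs
#' are summed elementwise. Widens rather than deepens the network.
#'
#' @inheritParams rca_block
#' @param weights List of three [rg_weights()] lists (stacked pair, then
#'   the single-group path).
#' @return Elementwise sum of the two path outputs, same shape as
#'   `input`.
#' @export
multipath <- function(input, weights) {
  had_batch <- length(dim(input)) == 4L
  x <- batch4(input)
  out <- multipath_fwd(x, weights)$out
  if (!had_batch) dim(out) <- dim(out)[1:3]
  out
}

#' Pixel-shuffle fusion of trunk and low-level features
#'
#' Projects the multipath output through a convolution to
#' `fusion_channels * a^2` channels and the early low-level feature map
#' through a strided convolution to the same grid, pixel-shuffles both
#' by `a`, and sums them.
#'
#' @param o_mr Multipath output at the trunk resolution.
#' @param f_l Low-level (first-stage, pre-pool) feature map.
#' @param weights List with `mr` and `low` convolution weights.
#' @param config A [net_config()] (supplies the scale factor).
#' @return The fused map at `a` times the trunk resolution.
#' @export
pixel_shuffle_fusion <- function(o_mr, f_l, weights, config) {
  o_mr <- batch4(o_mr)
  f_l <- batch4(f_l)
  stride <- dim(f_l)[1] %/% dim(o_mr)[1]
  if (stride < 1L || dim(f_l)[1] != stride * dim(o_mr)[1])
    abort_invalid_input("low-level map size must be a multiple of the trunk size.")
  fusion_fwd(o_mr, f_l, weights, config$scale_factor, stride)$out
}

#' Classification head
#'
#' Global average pooling over space, one fully connected layer, and a
#' softmax over classes.
#'
#' @param fused Feature map `(H, W, C, N)` or `(H, W, C)`.
#' @param weights List with `W` (`num_classes x C`) and `b`.
#' @param num_classes Number of classes, `>= 2`.
#' @return `N x num_classes` matrix of class probabilities.
#' @export
classification_head <- function(fused, weights, num_classes) {
  if (num_classes < 2L) abort_config("`num_classes` must be >= 2.")
  if (nrow(weights$W) != num_classes)
    abort_config("weight rows must equal `num_classes`.")
  head_fwd(batch4(fused), weights)$probabilities
}

#' Auxiliary reconstruction head
#'
#' A final convolution from the fused map to 3 channels. Only available
#' when the configuration enables it; its output is compared against the
#' (downsampled) input through the L1 reconstruction loss when
#' `recon_weight > 0`.
#'
#' @param fused Fused feature map.
#' @param weights Convolution weights (`W`, `b`).
#' @param enabled Whether the head is enabled in the configuration.
#' @return The reconstructed 3-channel map at the fused resolution.
#' @export
sr_head <- function(fused, weights, enabled = TRUE) {
  if (!isTRUE(enabled)) abort_config("the reconstruction head is disabled.")
  nn_conv_fwd(batch4(fused), weights$W, weights$b)$out
}

#' Build the three-stage convolutional stem
#'
#' Three stages of convolution, batch normalization, ReLU and 2x2
#' stride-2 max pooling with 16, 32 and 64 kernels. The returned object
#' carries the initialized stage weights and a table of stage output
#' shapes and batch-normalization parameter counts (32, 64, 128); the
#' first-stage activation before pooling is the low-level map `F_L`
#' exposed for fusion.
#'
#' @param config A [net_config()].
#' @return A list of class `fusnet_stem` with `params` and `stages`
#'   (a tibble with `out_h`, `out_w`, `channels`, `bn_params`).
#' @export
build_stem <- function(config) {
  if (!inherits(config, "fusnet_config")) abort_config("`config` must be a net_config().")
  p <- init_stem_params(config)
  h <- config$input_size[1]
  w <- config$input_size[2]
  ks <- config$stem_kernels
  stages <- tibble::tibble(
    stage = 1:3,
    out_h = h %/% c(2L, 4L, 8L), out_w = w %/% c(2L, 4L, 8L),
    channels = ks, bn_params = 2L * ks)
  structure(list(params = p, stages = stages, config = config),
            class = "fusnet_stem")
}

init_stem_params <- function(config) {
  k <- config$conv_kernel
  cs <- c(config$input_channels, config$stem_kernels)
  lapply(1:3, function(i) list(
    conv = init_conv(k, k, cs[i], cs[i + 1], "kaiming"),
    bn = list(gamma = rep(1, cs[i + 1]), beta = numeric(cs[i + 1]))))
}

## ---- full model -----------------------------------------------------------

#' Build the full classifier
#'
#' Composes the stem, the residual trunk selected by the configuration's
#' `variant`, pixel-shuffle fusion with the low-level bypass, the
#' classification head and (optionally) the reconstruction head, with
#' seeded Kaiming-style initialization (`gamma = 1`, `beta = 0` for
#' batch normalization).
#'
#' @param config A [net_config()].
#' @param seed Integer seed controlling initialization; the same seed
#'   gives bit-identical weights.
#' @return A list of class `fusnet_model` with `config`, `params` and
#'   `bn_state`.
#' @export
build_model <- function(config = net_config(), seed = 1L) {
  if (!inherits(config, "fusnet_config")) abort_config("`config` must be a net_config().")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  k <- config$conv_kernel
  ch <- config$rg_channels
  params <- list(stem = init_stem_params(config))
  n_rg <- switch(config$variant, stem = 0L, rg = 1L, multipath = 3L, full = 3L)
  if (n_rg > 0L)
    params$rg <- lapply(seq_len(n_rg), function(i)
      rg_weights(ch, config$rca_per_rg, config$attention_reduction, k))
  if (config$variant == "full") {
    a2 <- config$scale_factor^2
    params$fusion <- list(
      mr = init_conv(k, k, ch, config$fusion_channels * a2, "kaiming"),
      low = init_conv(k, k, config$stem_kernels[1],
                      config$fusion_channels * a2, "kaiming"))
  }
  head_in <- if (config$variant == "full") config$fusion_channels else ch
  params$head <- init_fc(head_in, config$num_classes, "kaiming", gain = 1)
  if (config$sr_head) {
    if (config$variant != "full")
      abort_config("the reconstruction head requires the full variant.")
    params$sr <- init_conv(k, k, config$fusion_channels, 3L, "kaiming")
  }
  bn_state <- lapply(config$stem_kernels, function(c)
    list(mean = numeric(c), var = rep(1, c)))
  structure(list(config = config, params = params, bn_state = bn_state),
            class = "fusnet_model")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' @export
print.fusnet_model <- function(x, ...) {
  cat(sprintf("<fusnet model: %s variant, %dx%d input, %d classes, %s parameters>\n",
              x$config$variant, x$config$input_size[1], x$config$input_size[2],
              x$config$num_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass
#'
#' Runs a batch of normalized images through the model. In training mode
#' batch statistics are used for normalization and the returned
#' `bn_state` carries the updated running statistics; assign it back to
#' the model to persist them.
#'
#' @param model A [build_model()] object.
#' @param x `(H, W, C, N)` array of unit-interval images (a single
#'   `(H, W, C)` image is promoted to a batch of one).
#' @param training Logical.
#' @param want_cache Keep intermediate activations for a backward pass.
#' @return A list with `probabilities` (`N x K`), `logits`, `sr` (or
#'   `NULL`), `bn_state`, and `cache` when requested.
#' @export
model_forward <- function(model, x, training = FALSE, want_cache = FALSE) {
  cfg <- model$config
  x <- batch4(x)
  if (!identical(dim(x)[1:3],
                 c(cfg$input_size, cfg$input_channels)))
    abort_invalid_input("input dimensions do not match the model configuration.")
  p <- model$params
  bn <- model$bn_state
  cc <- list(stem = vector("list", 3L))
  h <- x
  fl <- NULL
  for (i in 1:3) {
    cv <- nn_conv_fwd(h, p$stem[[i]]$conv$W, p$stem[[i]]$conv$b)
    st <- list(gamma = p$stem[[i]]$bn$gamma, beta = p$stem[[i]]$bn$beta,
               mean = bn[[i]]$mean, var = bn[[i]]$var,
               eps = cfg$bn_epsilon, momentum = 0.1)
    b <- nn_bn_fwd(cv$out, st, training)
    bn[[i]] <- list(mean = b$state$mean, var = b$state$var)
    r <- nn_relu_fwd(b$out)
    if (i == 1L) fl <- r$out
    pl <- nn_pool_fwd(r$out)
    cc$stem[[i]] <- list(conv = cv$cache, bn = b$cache, relu = r$cache,
                         pool = pl$cache)
    h <- pl$out
  }
  feat <- h
  if (cfg$variant == "rg") {
    r <- rg_fwd(h, p$rg[[1]])
    cc$rg <- r$cache
    feat <- r$out
  } else if (cfg$variant %in% c("multipath", "full")) {
    mp <- multipath_fwd(h, p$rg)
    cc$mp <- mp$cache
    feat <- mp$out
  }
  sr <- NULL
  if (cfg$variant == "full") {
    stride <- dim(fl)[1] %/% dim(feat)[1]
    fu <- fusion_fwd(feat, fl, p$fusion, cfg$scale_factor, stride)
    cc$fusion <- fu$cache
    feat <- fu$out
    if (cfg$sr_head) {
      sv <- nn_conv_fwd(feat, p$sr$W, p$sr$b)
      cc$sr <- sv$cache
      sr <- sv$out
    }
  }
  hd <- head_fwd(feat, p$head)
  cc$head <- hd$cache
  out <- list(probabilities = hd$probabilities, logits = hd$logits,
              sr = sr, bn_state = bn)
  if (want_cache) out$cache <- cc
  out
}

# Gradient of all trainable parameters given dL/dlogits (N x K) and,
# optionally, dL/dSR for the reconstruction head. Returns a nested list
# shaped like model$params.
model_backward <- function(model, cache, dlogits, dsr = NULL) {
  cfg <- model$config
  p <- model$params
  g <- list()
  hb <- head_bwd(dlogits, p$head, cache$head)
  g$head <- hb$grads
  dfeat <- hb$dfeat
  dfl <- NULL
  if (cfg$variant == "full") {
    if (!is.null(dsr)) {
      sb <- nn_conv_bwd(dsr, p$sr$W, cache$sr)
      g$sr <- list(W = sb$dW, b = sb$db)
      dfeat <- dfeat + sb$dx
    } else if (cfg$sr_head) {
      g$sr <- list(W = p$sr$W * 0, b = p$sr$b * 0)
    }
    fb <- fusion_bwd(dfeat, p$fusion, cache$fusion)
    g$fusion <- fb$grads
    dfeat <- fb$domr
    dfl <- fb$dfl
  }
  if (cfg$variant == "rg") {
    rb <- rg_bwd(dfeat, p$rg[[1]], cache$rg)
    g$rg <- list(rb$grads)
    dfeat <- rb$dx
  } else if (cfg$variant %in% c("multipath", "full")) {
    mb <- multipath_bwd(dfeat, p$rg, cache$mp)
    g$rg <- mb$grads
    dfeat <- mb$dx
  }
  dh <- dfeat
  g$stem <- vector("list", 3L)
  for (i in 3:1) {
    sc <- cache$stem[[i]]
    dr <- nn_pool_bwd(dh, sc$pool)
    if (i == 1L && !is.null(dfl)) dr <- dr + dfl
    drelu <- nn_relu_bwd(dr, sc$relu)
    st <- list(gamma = p$stem[[i]]$bn$gamma)
    bb <- nn_bn_bwd(drelu, st, sc$bn)
    cb <- nn_conv_bwd(bb$dx, p$stem[[i]]$conv$W, sc$conv)
    g$stem[[i]] <- list(conv = list(W = cb$dW, b = cb$db),
                        bn = list(gamma = bb$dgamma, beta = bb$dbeta))
    dh <- cb$dx
  }
  g
}

#' @export
predict.fusnet_model <- function(object, newdata,
                                 type = c("prob", "class"), ...) {
  type <- match.arg(type)
  fwd <- model_forward(object, newdata, training = FALSE)
  if (type == "prob") return(fwd$probabilities)
  max.col(fwd$probabilities, ties.method = "first")
}

## ---- complexity accounting ------------------------------------------------

# One row per parameterized layer; single source of truth for parameter
# and MAC counting.
model_layers <- function(config) {
  if (inherits(config, "fusnet_model")) config <- config$config
  k <- config$conv_kernel
  h <- config$input_size[1]
  w <- config$input_size[2]
  ks <- config$stem_kernels
  cs <- c(config$input_channels, ks)
  rows <- list()
  add <- function(name, type, cin, cout, kh, kw, oh, ow) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, type = type, cin = cin, cout = cout, kh = kh, kw = kw,
      out_h = oh, out_w = ow,
      params = switch(type,
        conv = kh * kw * cin * cout + cout,
        fc = cin * cout + cout,
        bn = 2 * cout),
      macs = switch(type,
        conv = as.numeric(oh) * ow * cout * kh * kw * cin,
        fc = as.numeric(cin) * cout,
        bn = 0))
  }
  hh <- h; ww <- w
  for (i in 1:3) {
    add(sprintf("stem%d.conv", i), "conv", cs[i], cs[i + 1], k, k, hh, ww)
    add(sprintf("stem%d.bn", i), "bn", cs[i + 1], cs[i + 1], 0, 0, hh, ww)
    hh <- hh %/% 2L; ww <- ww %/% 2L
  }
  ch <- config$rg_channels
  n_rg <- switch(config$variant, stem = 0L, rg = 1L, multipath = 3L, full = 3L)
  mid <- ch %/% config$attention_reduction
  for (r in seq_len(n_rg)) {
    for (j in seq_len(config$rca_per_rg)) {
      add(sprintf("rg%d.rca%d.conv1", r, j), "conv", ch, ch, k, k, hh, ww)
      add(sprintf("rg%d.rca%d.conv2", r, j), "conv", ch, ch, k, k, hh, ww)
      add(sprintf("rg%d.rca%d.att1", r, j), "fc", ch, mid, 1, 1, 1, 1)
      add(sprintf("rg%d.rca%d.att2", r, j), "fc", mid, ch, 1, 1, 1, 1)
    }
    add(sprintf("rg%d.tail", r), "conv", ch, ch, k, k, hh, ww)
  }
  head_in <- ch
  fh <- hh; fw <- ww
  if (config$variant == "full") {
    a2 <- config$scale_factor^2
    cf <- config$fusion_channels
    add("fusion.mr", "conv", ch, cf * a2, k, k, hh, ww)
    add("fusion.low", "conv", ks[1], cf * a2, k, k, hh, ww)
    head_in <- cf
    fh <- hh * config$scale_factor
    fw <- ww * config$scale_factor
    if (config$sr_head) add("sr", "conv", cf, 3L, k, k, fh, fw)
  }
  add("head", "fc", head_in, config$num_classes, 1, 1, 1, 1)
  dplyr::bind_rows(rows)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution kernels and biases,
#' batch-normalization scales and shifts, fully connected weights);
#' running batch-normalization statistics are not trainable and are not
#' counted.
#'
#' @param model A `fusnet_model` or a [net_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "fusnet_model")) {
    n <- 0L
    walk <- function(x) {
      if (is.numeric(x)) n <<- n + length(x)
      else if (is.list(x)) lapply(x, walk)
      invisible(NULL)
    }
    walk(model$params)
    return(n)
  }
  as.integer(sum(model_layers(model)$params))
}

#' Count forward-pass multiply-accumulates
#'
#' One operation per multiply-accumulate in convolution and fully
#' connected layers (the MAC convention): `output_elements *
#' kernel_elements` per convolution, `in_features * out_features` per
#' fully connected layer. Pooling, activations, batch normalization and
#' bias additions are not counted. Divide by `1e9` for GFLOPs.
#'
#' @param model A `fusnet_model` or a [net_config()].
#' @param input_size Optional `(H, W)` override of the configured input
#'   resolution.
#' @return Total MAC count (double).
#' @export
count_flops <- function(model, input_size = NULL) {
  cfg <- if (inherits(model, "fusnet_model")) model$config else model
  if (!is.null(input_size)) {
    cfg$input_size <- as.integer(rep(input_size, length.out = 2L))
  }
  sum(model_layers(cfg)$macs)
}
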