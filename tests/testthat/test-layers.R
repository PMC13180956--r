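test_that("relu clamps negatives elementwise", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  expect_equal(relu(0), 0)
  expect_equal(relu(c(-1, 0.5)), c(0, 0.5))
  expect_error(relu(NaN), class = "fusnet_invalid_input")
})

test_that("batch normalization standardizes per channel then shifts/scales", {
  x <- array(rep(c(1, 2, 3), each = 4), c(2, 2, 1, 3))
  out <- batch_norm(x, gamma = 1, beta = 0, epsilon = 1e-5)$out
  expect_equal(mean(out), 0, tolerance = 1e-8)
  expect_equal(mean(out^2), 1, tolerance = 1e-4)  # within epsilon effect
  # affine transform: gamma doubles the spread, beta shifts the mean
  out2 <- batch_norm(x, gamma = 2, beta = 5, epsilon = 1e-5)$out
  expect_equal(mean(out2), 5, tolerance = 1e-8)
  expect_equal(sd(out2) / sd(out), 2, tolerance = 1e-8)
  # constant channel collapses to beta
  cc <- array(4, c(2, 2, 1, 2))
  expect_equal(as.numeric(batch_norm(cc, 1, 7)$out), rep(7, 8))
})

test_that("batch normalization needs two samples in training mode", {
  x <- array(rnorm(8), c(2, 2, 2, 1))
  expect_error(batch_norm(x, c(1, 1), c(0, 0), training = TRUE),
               class = "fusnet_invalid_input")
  # inference mode accepts a single sample and uses running statistics
  out <- batch_norm(x, c(1, 1), c(0, 0), running_mean = c(0, 0),
                    running_var = c(1, 1), training = FALSE)$out
  expect_equal(out, x, tolerance = 1e-4)
})

test_that("max pooling halves dimensions and takes blockwise maxima", {
  x <- array(c(1, 5, 3, 2), c(2, 2, 1, 1))
  expect_equal(as.numeric(max_pool(x)), 5)
  const <- array(3, c(4, 6, 2, 1))
  expect_equal(max_pool(const), array(3, c(2, 3, 2, 1)))
  expect_error(max_pool(array(0, c(3, 4, 1, 1))),
               class = "fusnet_invalid_input")
  set.seed(12)
  for (rep in 1:10) {
    x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    expect_equal(max_pool(x), oracle_maxpool(x))
  }
})

test_that("pixel shuffle implements the sub-pixel index mapping", {
  x <- array(c(1, 2, 3, 4), c(1, 1, 4))
  expect_equal(pixel_shuffle(x, 2), array(c(1, 3, 2, 4), c(2, 2, 1)))
  set.seed(13)
  x <- array(rnorm(3 * 4 * 8), c(3, 4, 8))
  expect_equal(pixel_shuffle(x, 1), x)
  expect_equal(pixel_shuffle(x, 2), oracle_pixel_shuffle(x, 2))
  # conservation: a bijective rearrangement preserves the value multiset
  expect_equal(sort(as.numeric(pixel_shuffle(x, 2))), sort(as.numeric(x)))
  expect_error(pixel_shuffle(array(0, c(2, 2, 6)), 2),
               class = "fusnet_invalid_input")
})

test_that("pixel shuffle round-trips through its inverse", {
  set.seed(14)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  f <- fusnetcnn:::nn_ps_fwd(x, 2)
  back <- fusnetcnn:::nn_ps_bwd(f$out, f$cache)
  expect_identical(back, x)
})

test_that("RCA block is the identity under zero weights", {
  set.seed(15)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  w0 <- rca_weights(8, reduction = 4, init = "zero")
  expect_equal(rca_block(x, w0), x)
  # attention gate values lie strictly inside (0, 1)
  w <- rca_weights(8, reduction = 4)
  g <- fusnetcnn:::rca_fwd(x, w)$gate
  expect_true(all(g > 0 & g < 1))
  expect_error(rca_block(array(0, c(4, 4, 5, 1)), w),
               class = "fusnet_invalid_input")
})

test_that("a saturated attention gate reduces RCA to a plain residual block", {
  set.seed(16)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
  w <- rca_weights(8, reduction = 4)
  w$att$W1[] <- 0; w$att$b1[] <- 0
  w$att$W2[] <- 0; w$att$b2[] <- 40    # sigmoid(40) == 1 in double precision
  got <- rca_block(x, w)
  # plain residual: conv2(relu(conv1(x))) + x, computed via the conv layers
  c1 <- fusnetcnn:::nn_conv_fwd(x, w$conv1$W, w$conv1$b)$out
  c2 <- fusnetcnn:::nn_conv_fwd(pmax(c1, 0), w$conv2$W, w$conv2$b)$out
  expect_equal(got, c2 + x, tolerance = 1e-12)
})

test_that("residual group reduces to identity and chains RCA blocks", {
  set.seed(18)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  expect_equal(rg_block(x, rg_weights(8, n_rca = 2, init = "zero")), x)
  # appending a zero (identity) RCA stage leaves the group unchanged
  w1 <- rg_weights(8, n_rca = 1)
  w2 <- w1
  w2$rca <- c(w1$rca, list(rca_weights(8, init = "zero")))
  expect_equal(rg_block(x, w1), rg_block(x, w2))
  # deterministic under identical weights
  expect_identical(rg_block(x, w1), rg_block(x, w1))
})

test_that("multipath sums a stacked two-group path and a single-group path", {
  set.seed(19)
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  w0 <- lapply(1:3, function(i) rg_weights(8, init = "zero"))
  expect_equal(multipath(x, w0), 2 * x)
  w <- lapply(1:3, function(i) rg_weights(8))
  got <- multipath(x, w)
  path1 <- rg_block(rg_block(x, w[[1]]), w[[2]])
  path2 <- rg_block(x, w[[3]])
  expect_equal(got, path1 + path2, tolerance = 1e-12)
  # zeroing the single-group path leaves only the stacked path
  wz <- w
  wz[[3]] <- rg_weights(8, init = "zero")
  # a zero-weight group is the identity, so the sum becomes path1 + x
  expect_equal(multipath(x, wz), path1 + x, tolerance = 1e-12)
})

test_that("pixel-shuffle fusion is additive over its branches", {
  set.seed(20)
  cfg <- net_config(input_size = c(32, 32), num_classes = 3)
  m <- build_model(cfg, seed = 2)
  omr <- array(rnorm(4 * 4 * 64 * 2), c(4, 4, 64, 2))
  fl <- array(rnorm(32 * 32 * 16 * 2), c(32, 32, 16, 2))
  w <- m$params$fusion
  full <- pixel_shuffle_fusion(omr, fl, w, cfg)
  w_mr_only <- w; w_mr_only$low$W[] <- 0; w_mr_only$low$b[] <- 0
  w_low_only <- w; w_low_only$mr$W[] <- 0; w_low_only$mr$b[] <- 0
  a <- pixel_shuffle_fusion(omr, fl, w_mr_only, cfg)
  b <- pixel_shuffle_fusion(omr, fl, w_low_only, cfg)
  expect_equal(full, a + b, tolerance = 1e-12)
  # both branches zero: a zero map at the fused resolution
  w0 <- w_mr_only; w0$mr$W[] <- 0; w0$mr$b[] <- 0
  z <- pixel_shuffle_fusion(omr, fl, w0, cfg)
  expect_equal(dim(z), c(8, 8, 32, 2))
  expect_true(all(z == 0))
})

test_that("classification head is a softmax over pooled features", {
  set.seed(22)
  feat <- array(rnorm(4 * 4 * 8 * 3), c(4, 4, 8, 3))
  w <- list(W = matrix(rnorm(5 * 8, sd = 0.3), 5, 8), b = rnorm(5))
  p <- classification_head(feat, w, 5)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # zero weights give uniform probabilities
  p0 <- classification_head(feat, list(W = matrix(0, 5, 8), b = numeric(5)), 5)
  expect_equal(as.numeric(p0), rep(0.2, 15))
  # shifting all logits by a constant leaves probabilities unchanged
  w2 <- w; w2$b <- w$b + 3.7
  expect_equal(classification_head(feat, w2, 5), p, tolerance = 1e-12)
  expect_error(classification_head(feat, w, 1), class = "fusnet_config_error")
})

test_that("reconstruction head obeys its enable flag and shape contract", {
  set.seed(23)
  fused <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  w <- list(W = array(rnorm(3 * 3 * 32 * 3, sd = 0.1), c(3, 3, 32, 3)),
            b = numeric(3))
  out <- sr_head(fused, w, enabled = TRUE)
  expect_equal(dim(out), c(8, 8, 3, 2))
  expect_error(sr_head(fused, w, enabled = FALSE),
               class = "fusnet_config_error")
  w0 <- list(W = array(0, c(3, 3, 32, 3)), b = numeric(3))
  z <- sr_head(fused, w0)
  expect_true(all(z == 0))
  ref <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  expect_equal(l1_reconstruction(z, ref)$value, mean(abs(ref)))
})
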