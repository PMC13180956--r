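test_that("configuration invariants are enforced", {
  expect_error(net_config(input_size = c(1, 1)), class = "fusnet_config_error")
  expect_error(net_config(input_size = c(12, 12)), class = "fusnet_config_error")
  expect_error(net_config(stem_kernels = c(8, 16, 32)),
               class = "fusnet_config_error")
  expect_error(net_config(rca_per_rg = 0), class = "fusnet_config_error")
  expect_error(net_config(num_classes = 1), class = "fusnet_config_error")
  expect_error(net_config(scale_factor = 0), class = "fusnet_config_error")
  expect_error(rg_weights(8, n_rca = 0), class = "fusnet_config_error")
})

test_that("the stem halves resolution per stage with 16/32/64 kernels", {
  stem <- build_stem(net_config(input_size = c(128, 128)))
  expect_equal(stem$stages$out_h, c(64, 32, 16))
  expect_equal(stem$stages$out_w, c(64, 32, 16))
  expect_equal(stem$stages$channels, c(16, 32, 64))
  expect_equal(stem$stages$bn_params, c(32, 64, 128))
  # the realized parameters agree with the table
  bn_lens <- vapply(stem$params, function(s)
    length(s$bn$gamma) + length(s$bn$beta), integer(1))
  expect_equal(bn_lens, c(32L, 64L, 128L))
})

test_that("model building is deterministic under a fixed seed", {
  cfg <- net_config(input_size = c(16, 16), num_classes = 3)
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 12)
  expect_false(identical(m1$params, m3$params))
})

test_that("the default model emits one probability row per sample over 38 classes", {
  cfg <- net_config(input_size = c(16, 16))   # default num_classes = 38
  m <- build_model(cfg, seed = 1)
  x <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  fwd <- model_forward(m, x)
  expect_equal(dim(fwd$probabilities), c(4L, 38L))
  expect_equal(rowSums(fwd$probabilities), rep(1, 4), tolerance = 1e-6)
  # bit-stable across repeated forward passes
  expect_identical(fwd$probabilities, model_forward(m, x)$probabilities)
  expect_error(model_forward(m, array(0, c(8, 8, 3, 1))),
               class = "fusnet_invalid_input")
})

test_that("every architecture variant runs forward and predicts", {
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  for (v in c("stem", "rg", "multipath", "full")) {
    cfg <- net_config(input_size = c(16, 16), num_classes = 3, variant = v)
    m <- build_model(cfg, seed = 3)
    p <- predict(m, x)
    expect_equal(dim(p), c(2L, 3L))
    cl <- predict(m, x, type = "class")
    expect_true(all(cl %in% 1:3))
  }
})

test_that("parameter counts match closed forms on single layers", {
  layers <- fusnetcnn:::model_layers(net_config(input_size = c(128, 128)))
  conv1 <- layers[layers$name == "stem1.conv", ]
  expect_equal(conv1$params, 3 * 9 * 16 + 16)        # 448
  expect_equal(layers$params[layers$name == "stem1.bn"], 32)
  expect_equal(layers$params[layers$name == "stem2.bn"], 64)
  expect_equal(layers$params[layers$name == "stem3.bn"], 128)
  rca_conv <- layers[layers$name == "rg1.rca1.conv1", ]
  expect_equal(rca_conv$params, 64 * 9 * 64 + 64)
  head <- layers[layers$name == "head", ]
  expect_equal(head$params, 32 * 38 + 38)
  # model-level count equals the manifest total
  m <- build_model(net_config(input_size = c(16, 16), num_classes = 3), seed = 1)
  expect_equal(count_parameters(m),
               sum(fusnetcnn:::model_layers(m$config)$params))
})

test_that("MAC counts match closed forms and scale linearly with area", {
  layers <- fusnetcnn:::model_layers(net_config(input_size = c(128, 128)))
  conv1 <- layers[layers$name == "stem1.conv", ]
  expect_equal(conv1$macs, 128 * 128 * 16 * 27)
  expect_equal(layers$macs[layers$name == "head"], 32 * 38)
  expect_equal(layers$macs[layers$name == "rg1.rca1.att1"], 64 * 16)
  stem_at <- function(h, w) {
    l <- fusnetcnn:::model_layers(net_config(input_size = c(h, w)))
    sum(l$macs[grepl("^stem", l$name)])
  }
  expect_equal(stem_at(128, 256), 2 * stem_at(128, 128))
  # input-size override on count_flops
  expect_equal(count_flops(net_config(), input_size = c(64, 64)),
               sum(fusnetcnn:::model_layers(net_config(input_size = c(64, 64)))$macs))
})

test_that("analytic gradients match finite differences through the full model", {
  cfg <- net_config(input_size = c(16, 16), num_classes = 3)
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  n <- 3
  xb <- array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
  yb <- c(1L, 2L, 3L)
  lcfg <- loss_config("improved_huber")
  loss_of <- function(model) {
    fwd <- model_forward(model, xb, training = TRUE)
    mean(fusnetcnn:::classification_loss_grad(
      fwd$probabilities, yb, lcfg)$per_sample)
  }
  fwd <- model_forward(m, xb, training = TRUE, want_cache = TRUE)
  lg <- fusnetcnn:::classification_loss_grad(fwd$probabilities, yb, lcfg)
  prob <- fwd$probabilities
  dlogits <- prob * (lg$grad - rowSums(lg$grad * prob))
  grads <- fusnetcnn:::model_backward(m, fwd$cache, dlogits)
  probes <- list(
    c("stem", "1", "conv", "W"), c("stem", "2", "bn", "gamma"),
    c("stem", "3", "bn", "beta"), c("rg", "1", "rca", "1", "conv1", "W"),
    c("rg", "2", "rca", "2", "att", "W2"), c("rg", "3", "tail", "b"),
    c("fusion", "mr", "W"), c("fusion", "low", "W"), c("head", "W"))
  get_leaf <- function(p, path) {
    for (k in path) {
      ki <- suppressWarnings(as.integer(k))
      p <- if (!is.na(ki)) p[[ki]] else p[[k]]
    }
    p
  }
  set_leaf <- function(p, path, v) {
    k <- path[1]
    ki <- suppressWarnings(as.integer(k))
    key <- if (!is.na(ki)) ki else k
    if (length(path) == 1L) p[[key]] <- v
    else p[[key]] <- set_leaf(p[[key]], path[-1], v)
    p
  }
  eps <- 1e-5
  for (path in probes) {
    leaf <- get_leaf(m$params, path)
    j <- sample(length(leaf), 1)
    mp <- m; lf <- leaf; lf[j] <- lf[j] + eps
    mp$params <- set_leaf(mp$params, path, lf)
    mm <- m; lf[j] <- lf[j] - 2 * eps
    mm$params <- set_leaf(mm$params, path, lf)
    num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
    ana <- get_leaf(grads, path)[j]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- net_config(input_size = c(16, 16), num_classes = 3)
  m <- build_model(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predict(m, x), predict(back, x))
  expect_error(load_model(tempfile()), class = "fusnet_io_error")
})
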