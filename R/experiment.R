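#' Experiment configuration
#'
#' Settings of the desk-scale training harness: data split, optimizer,
#' loss and network configuration. The defaults (Adam with learning rate
#' `1e-3`, batch size 32, stratified 0.8/0.1/0.1 split, improved Huber
#' loss at `delta = 1`) are the package's standard training conditions.
#'
#' @param net A [net_config()], or `NULL` to derive input size and class
#'   count from the data at training time.
#' @param loss A [loss_config()].
#' @param split Train/validation/test fractions summing to 1.
#' @param lr Adam learning rate.
#' @param warmup_steps Linear learning-rate warmup over this many initial
#'   mini-batch updates (0 disables). Guards the early optimization phase
#'   against softmax saturation, under which the bounded-gradient losses
#'   receive vanishing updates.
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs, `>= 1`.
#' @param seed Integer seed governing the split, initialization and
#'   batch shuffling.
#' @param median_window Median-filter window used in preprocessing.
#' @param out_dir Optional directory where evaluation reports are
#'   written.
#' @return A list of class `fusnet_experiment_config`.
#' @export
experiment_config <- function(net = NULL, loss = loss_config(),
                              split = c(0.8, 0.1, 0.1), lr = 1e-3,
                              warmup_steps = 30L, batch_size = 32L,
                              epochs = 10L, seed = 1L,
                              median_window = 3L, out_dir = NULL) {
  if (length(split) != 3L || any(split < 0) || abs(sum(split) - 1) > 1e-8)
    abort_config("`split` must be three non-negative fractions summing to 1.")
  if (epochs < 1L) abort_config("`epochs` must be >= 1.")
  if (batch_size < 1L) abort_config("`batch_size` must be >= 1.")
  if (lr < 0) abort_config("`lr` must be >= 0.")
  if (warmup_steps < 0) abort_config("`warmup_steps` must be >= 0.")
  structure(list(net = net, loss = loss, split = split, lr = lr,
                 warmup_steps = as.integer(warmup_steps),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 median_window = as.integer(median_window),
                 out_dir = out_dir),
            class = "fusnet_experiment_config")
}

#' Stratified three-way split
#'
#' Seeded, disjoint, exhaustive partition of sample indices into
#' train/validation/test, stratified by class; every class contributes
#' to each subset.
#'
#' @param labels Class labels (1-based integers or factors).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  k <- if (is.factor(labels)) nlevels(labels) else max(as.integer(labels))
  labels <- as_class_labels(labels, k)
  if (any(tabulate(labels, k) < 3L))
    abort_invalid_input("every class needs at least 3 samples to split.")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in seq_len(k)) {
    idx <- sample(which(labels == cl))
    n <- length(idx)
    n_tr <- max(1L, round(fractions[1] * n))
    n_va <- max(1L, round(fractions[2] * n))
    if (n_tr + n_va >= n) n_tr <- n - n_va - 1L
    out$train <- c(out$train, idx[seq_len(n_tr)])
    out$val <- c(out$val, idx[n_tr + seq_len(n_va)])
    out$test <- c(out$test, idx[(n_tr + n_va + 1L):n])
  }
  lapply(out, sort)
}

# Preprocess a list of raw images into a normalized (H, W, C, N) array.
prep_batch_array <- function(images, window = 3L) {
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images))
    x[, , , i] <- preprocess_image(images[[i]], window)
  x
}

## ---- nested parameter-tree helpers (Adam) ---------------------------------

# Trees are aligned by name where names exist (gradient lists may order
# their components differently from the parameter list), else by position.
mapn_params <- function(trees, f) {
  if (is.numeric(trees[[1]])) return(do.call(f, trees))
  nms <- names(trees[[1]])
  out <- vector("list", length(trees[[1]]))
  names(out) <- nms
  for (i in seq_along(trees[[1]])) {
    key <- if (!is.null(nms) && !is.na(nms[i]) && nzchar(nms[i])) nms[i] else i
    out[[i]] <- mapn_params(lapply(trees, `[[`, key), f)
  }
  out
}

adam_init <- function(params) {
  zeros <- mapn_params(list(params), function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapn_params(list(state$m, grads),
                         function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- mapn_params(list(state$v, grads),
                         function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- mapn_params(list(params, state$m, state$v),
                        function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps))
  list(params = params, state = state)
}

block_mean_downsample <- function(x, factor) {
  d <- dim(x)
  out <- 0
  for (a in seq_len(factor))
    for (b in seq_len(factor))
      out <- out + x[seq(a, d[1], factor), seq(b, d[2], factor), , , drop = FALSE]
  out / factor^2
}

## ---- training -------------------------------------------------------------

batch_predict <- function(model, x, chunk = 64L) {
  n <- dim(x)[4]
  probs <- NULL
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    p <- model_forward(model, x[, , , s:e, drop = FALSE])$probabilities
    probs <- rbind(probs, p)
  }
  probs
}

#' Train the classifier on a labeled image set
#'
#' The full training loop: per-image preprocessing (median filter +
#' min-max normalization), stratified split, seeded initialization,
#' mini-batch Adam updates of the configured loss, per-epoch train and
#' validation curves, and best-validation-accuracy checkpointing. Fully
#' reproducible from `config$seed`.
#'
#' @param data A `fusnet_leaf_set` (from [generate_leaf_set()] or
#'   [read_leaf_set()]) or a dataset directory path.
#' @param config An [experiment_config()].
#' @return A list of class `fusnet_fit`: `model` (best checkpoint),
#'   `history` (per-epoch tibble), `split` (index lists), `config`.
#' @export
train_model <- function(data, config = experiment_config()) {
  if (is.character(data)) data <- read_leaf_set(data)
  if (!inherits(data, "fusnet_leaf_set"))
    abort_invalid_input("`data` must be a leaf set or a dataset directory.")
  d1 <- dim(data$images[[1]])
  netcfg <- config$net %||%
    net_config(input_size = d1[1:2], num_classes = data$num_classes)
  if (netcfg$num_classes < data$num_classes)
    abort_invalid_input("model class count is smaller than the data's.")
  sp <- split_dataset(data$labels, config$split, config$seed)
  if (length(sp$train) == 0L) abort_invalid_input("empty training split.")
  x_all <- prep_batch_array(data$images, config$median_window)
  y_all <- as_class_labels(data$labels, netcfg$num_classes)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  model <- build_model(netcfg, seed = config$seed)
  opt <- adam_init(model$params)
  use_sr <- netcfg$sr_head && netcfg$recon_weight > 0
  warm <- config$warmup_steps %||% 0L
  step_n <- 0L
  history <- vector("list", config$epochs)
  best <- list(acc = -Inf, loss = Inf, params = model$params,
               bn = model$bn_state)
  for (ep in seq_len(config$epochs)) {
    idx <- sample(sp$train)
    ep_loss <- 0
    ep_hits <- 0
    for (s in seq(1L, length(idx), by = config$batch_size)) {
      b <- idx[s:min(s + config$batch_size - 1L, length(idx))]
      if (length(b) < 2L) next  # training-mode BN needs >= 2 samples
      xb <- x_all[, , , b, drop = FALSE]
      yb <- y_all[b]
      fwd <- model_forward(model, xb, training = TRUE, want_cache = TRUE)
      model$bn_state <- fwd$bn_state
      lg <- classification_loss_grad(fwd$probabilities, yb, config$loss)
      prob <- fwd$probabilities
      dprob <- lg$grad
      dlogits <- prob * (dprob - rowSums(dprob * prob))
      loss_val <- mean(lg$per_sample)
      dsr <- NULL
      if (use_sr) {
        fct <- dim(xb)[1] %/% dim(fwd$sr)[1]
        ref <- block_mean_downsample(xb, fct)
        loss_val <- loss_val +
          netcfg$recon_weight * mean(abs(fwd$sr - ref))
        dsr <- netcfg$recon_weight * l1_reconstruction_grad(fwd$sr, ref)
      }
      grads <- model_backward(model, fwd$cache, dlogits, dsr)
      step_n <- step_n + 1L
      lr_t <- if (warm > 0L) config$lr * min(1, step_n / warm) else config$lr
      upd <- adam_step(model$params, grads, opt, lr_t)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss_val * length(b)
      ep_hits <- ep_hits + sum(max.col(prob, ties.method = "first") == yb)
    }
    val_prob <- batch_predict(model, x_all[, , , sp$val, drop = FALSE])
    val_pred <- max.col(val_prob, ties.method = "first")
    val_loss <- classification_loss(val_prob, y_all[sp$val], config$loss)$value
    val_acc <- mean(val_pred == y_all[sp$val])
    # accuracy decides; ties (common once the small validation split
    # saturates) resolve to the epoch with the lower validation loss
    if (val_acc > best$acc || (val_acc == best$acc && val_loss < best$loss))
      best <- list(acc = val_acc, loss = val_loss, params = model$params,
                   bn = model$bn_state)
    history[[ep]] <- tibble::tibble(
      epoch = ep,
      train_loss = ep_loss / length(sp$train),
      train_accuracy = ep_hits / length(sp$train),
      val_loss = val_loss, val_accuracy = val_acc)
  }
  best_model <- model
  best_model$params <- best$params
  best_model$bn_state <- best$bn
  structure(list(model = best_model, final_model = model,
                 history = dplyr::bind_rows(history), split = sp,
                 config = config, net = netcfg),
            class = "fusnet_fit")
}

#' @export
print.fusnet_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<fusnet fit: %d epochs; final train acc %.3f, ",
                     "best val acc %.3f>\n"),
              nrow(x$history), h$train_accuracy, max(x$history$val_accuracy)))
  invisible(x)
}

#' Evaluate a trained model
#'
#' Computes the full metric report (accuracy, macro precision / recall /
#' F1 / specificity, per-class breakdown, one-vs-rest ROC and AUC), the
#' confusion matrix, and the model's complexity summary (parameter and
#' MAC counts). For a `fusnet_fit` the held-out split recorded at
#' training time is used by default.
#'
#' @param object A `fusnet_fit` or `fusnet_model`.
#' @param data A `fusnet_leaf_set`; required for a bare model.
#' @param split Which recorded split to evaluate a fit on (`"test"`,
#'   `"val"` or `"train"`); ignored with an explicit `indices`.
#' @param indices Optional explicit sample indices into `data`.
#' @param out_dir Optional directory to write CSV/JSON reports into.
#' @return A list of class `fusnet_evaluation`: `metrics`, `confusion`,
#'   `roc`, `complexity`, `predictions`.
#' @export
evaluate_model <- function(object, data, split = "test", indices = NULL,
                           out_dir = NULL) {
  if (inherits(object, "fusnet_fit")) {
    model <- object$model
    if (is.null(indices)) indices <- object$split[[split]]
    window <- object$config$median_window
  } else if (inherits(object, "fusnet_model")) {
    model <- object
    window <- 3L
    if (is.null(indices)) indices <- seq_along(data$images)
  } else abort_invalid_input("`object` must be a fusnet_fit or fusnet_model.")
  if (data$num_classes > model$config$num_classes)
    abort_invalid_input("data has more classes than the model predicts.")
  x <- prep_batch_array(data$images[indices], window)
  y <- as_class_labels(data$labels[indices], model$config$num_classes)
  prob <- batch_predict(model, x)
  pred <- max.col(prob, ties.method = "first")
  cm <- confusion_matrix(y, pred, k = model$config$num_classes)
  metrics <- metric_report(cm, probabilities = prob, truth = y)
  roc <- roc_ovr(y, prob)
  complexity <- list(parameters = count_parameters(model),
                     macs = count_flops(model),
                     gflops = count_flops(model) / 1e9)
  out <- structure(list(metrics = metrics, confusion = cm, roc = roc,
                        complexity = complexity,
                        predictions = tibble::tibble(
                          index = indices, truth = y, estimate = pred)),
                   class = "fusnet_evaluation")
  if (!is.null(out_dir)) {
    write_metric_report(metrics, out_dir)
    readr::write_csv(roc, file.path(out_dir, "roc.csv"))
    jsonlite::write_json(complexity, file.path(out_dir, "complexity.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.fusnet_evaluation <- function(x, ...) {
  cat(sprintf("<evaluation: accuracy %.4f over %d samples; %s parameters, %.4f GFLOPs>\n",
              x$metrics$accuracy, nrow(x$predictions),
              format(x$complexity$parameters, big.mark = ","),
              x$complexity$gflops))
  invisible(x)
}

eval_metric_row <- function(ev) {
  tibble::tibble(accuracy = ev$metrics$accuracy,
                 precision = ev$metrics$macro_precision,
                 recall = ev$metrics$macro_recall,
                 f1 = ev$metrics$macro_f1,
                 specificity = ev$metrics$macro_specificity)
}

#' Compare loss families under identical conditions
#'
#' Trains one model per loss family on the same seeded data, split and
#' initialization, and reports the five evaluation metrics per family on
#' the held-out test split. At `delta = 1` the `huber` and
#' `improved_huber` rows are identical by construction.
#'
#' @param data A `fusnet_leaf_set` or dataset directory.
#' @param config An [experiment_config()]; its loss family is overridden
#'   per run.
#' @param families Character vector of two or more loss families.
#' @return A tibble with one row per family.
#' @export
compare_losses <- function(data, config = experiment_config(),
                           families = c("improved_huber", "huber",
                                        "cross_entropy", "focal",
                                        "exponential")) {
  if (length(families) < 2L)
    abort_invalid_input("supply at least two loss families.")
  if (is.character(data)) data <- read_leaf_set(data)
  purrr::map_dfr(families, function(fam) {
    cfg <- config
    cfg$loss <- loss_config(fam, delta = config$loss$delta,
                            focal_gamma = config$loss$focal_gamma)
    fit <- train_model(data, cfg)
    dplyr::bind_cols(tibble::tibble(loss = fam),
                     eval_metric_row(evaluate_model(fit, data)))
  })
}

ablation_variants <- function() {
  tibble::tibble(
    model = c("cnn", "cnn_rg", "cnn_multipath", "cnn_pixel_shuffle_fusion",
              "cnn_improved_huber", "multifusnet_full"),
    variant = c("stem", "rg", "multipath", "full", "stem", "full"),
    loss = c("cross_entropy", "cross_entropy", "cross_entropy",
             "cross_entropy", "improved_huber", "improved_huber"))
}

#' Ablation study over architecture components
#'
#' Trains the six variants of the component ablation — plain stem CNN,
#' plus residual groups, plus the multipath trunk, plus pixel-shuffle
#' fusion (all with cross-entropy), the stem CNN with the improved Huber
#' loss, and the full model with the improved Huber loss — each over
#' `seeds`, on identically generated splits, and reports mean and
#' standard deviation of the five metrics.
#'
#' @param data A `fusnet_leaf_set` or dataset directory.
#' @param config An [experiment_config()]; variant and loss are
#'   overridden per row, the seed is overridden per replicate.
#' @param seeds Integer vector of training seeds (default `1:3`).
#' @return A wide tibble (one row per variant) of `"mean ± sd"` cells,
#'   with the long numeric table in `attr(, "raw")`.
#' @export
ablate <- function(data, config = experiment_config(), seeds = 1:3) {
  if (is.character(data)) data <- read_leaf_set(data)
  variants <- ablation_variants()
  d1 <- dim(data$images[[1]])
  base_net <- config$net %||%
    net_config(input_size = d1[1:2], num_classes = data$num_classes)
  raw <- purrr::map_dfr(seq_len(nrow(variants)), function(i) {
    purrr::map_dfr(seeds, function(sd) {
      cfg <- config
      cfg$seed <- as.integer(sd)
      net <- base_net
      net$variant <- variants$variant[i]
      cfg$net <- net
      cfg$loss <- loss_config(variants$loss[i], delta = config$loss$delta)
      fit <- train_model(data, cfg)
      dplyr::bind_cols(
        tibble::tibble(model = variants$model[i], seed = sd,
                       parameters = count_parameters(fit$model)),
        eval_metric_row(evaluate_model(fit, data)))
    })
  })
  long <- raw |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1",
                          "specificity"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  wide <- long |>
    dplyr::mutate(cell = sprintf("%.4f ± %.4f", .data$mean,
                                 ifelse(is.na(.data$sd), 0, .data$sd))) |>
    dplyr::select("model", "metric", "cell") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "cell")
  wide <- wide[match(variants$model, wide$model), ]
  attr(wide, "raw") <- long
  attr(wide, "runs") <- raw
  wide
}

## ---- config and checkpoint IO ---------------------------------------------

#' Read an experiment configuration from a flat YAML file
#'
#' Recognized keys: `input_size`, `num_classes`, `variant`, `loss`,
#' `delta`, `focal_gamma`, `lr`, `batch_size`, `epochs`, `seed`,
#' `split`, `median_window`, `out_dir`. Missing keys fall back to the
#' package defaults.
#'
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  net <- NULL
  if (!is.null(y$input_size) || !is.null(y$num_classes) || !is.null(y$variant))
    net <- net_config(input_size = y$input_size %||% c(128L, 128L),
                      num_classes = y$num_classes %||% 38L,
                      variant = y$variant %||% "full")
  experiment_config(
    net = net,
    loss = loss_config(y$loss %||% "improved_huber",
                       delta = y$delta %||% 1,
                       focal_gamma = y$focal_gamma %||% 2),
    split = unlist(y$split %||% c(0.8, 0.1, 0.1)),
    lr = y$lr %||% 1e-3, batch_size = y$batch_size %||% 32L,
    epochs = y$epochs %||% 10L, seed = y$seed %||% 1L,
    median_window = y$median_window %||% 3L, out_dir = y$out_dir)
}

#' Write an experiment configuration to a flat YAML file
#'
#' @param config An [experiment_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
config_to_yaml <- function(config, path) {
  net <- config$net
  y <- list(
    input_size = if (!is.null(net)) net$input_size,
    num_classes = if (!is.null(net)) net$num_classes,
    variant = if (!is.null(net)) net$variant,
    loss = config$loss$family, delta = config$loss$delta,
    focal_gamma = config$loss$focal_gamma,
    split = config$split, lr = config$lr,
    batch_size = config$batch_size, epochs = config$epochs,
    seed = config$seed, median_window = config$median_window,
    out_dir = config$out_dir)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration, all
#' weights, and the running batch-normalization statistics.
#'
#' @param model A `fusnet_model` (or `fusnet_fit`, whose best model is
#'   saved).
#' @param path Checkpoint path.
#' @return `save_model` invisibly returns `path`; `load_model` returns
#'   the restored `fusnet_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "fusnet_fit")) model <- model$model
  if (!inherits(model, "fusnet_model"))
    abort_invalid_input("`model` must be a fusnet_model or fusnet_fit.")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("checkpoint not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "fusnet_model")) abort_io("not a fusnet model checkpoint.")
  m
}
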