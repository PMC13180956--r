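#' Synthetic leaf-dataset configuration
#'
#' Parameters of the seeded generator that emulates class-per-directory
#' leaf-disease datasets: each image is an elliptical green leaf on a
#' textured soil-like background, with class-dependent lesion spots,
#' an optional linear illumination gradient, and salt-and-pepper impulse
#' noise. Label corruption reassigns an exact number of labels
#' (`round(label_noise_rate * total)`) uniformly to a wrong class, so
#' corruption counts are deterministic.
#'
#' @param num_classes Number of classes, `>= 2`. Default 4 (class 1 is
#'   lesion-free, emulating a healthy class).
#' @param images_per_class Images generated per class.
#' @param image_size Square image side in pixels.
#' @param lesion_params Optional list (length `num_classes`) of per-class
#'   lesion descriptions, each with `count` (range), `radius` (range, as
#'   a fraction of `image_size`) and `color` (RGB in 0..255). Defaults to
#'   a palette of visually distinct lesion types.
#' @param impulse_noise_rate Fraction of pixels replaced by salt or
#'   pepper values. Default 0.02.
#' @param illumination_gradient Apply a random linear illumination ramp
#'   (0.75x to 1.25x). Default TRUE.
#' @param label_noise_rate Fraction of labels deliberately corrupted.
#'   Default 0.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `fusnet_synth_config`.
#' @export
synth_config <- function(num_classes = 4L, images_per_class = 25L,
                         image_size = 128L, lesion_params = NULL,
                         impulse_noise_rate = 0.02,
                         illumination_gradient = TRUE,
                         label_noise_rate = 0, seed = 1L) {
  if (num_classes < 2L) abort_config("`num_classes` must be >= 2.")
  if (images_per_class < 1L) abort_config("`images_per_class` must be positive.")
  if (image_size < 16L) abort_config("`image_size` must be at least 16.")
  for (r in c(impulse_noise_rate, label_noise_rate))
    if (!is.numeric(r) || r < 0 || r > 1)
      abort_config("noise rates must lie in [0, 1].")
  lesion_params <- lesion_params %||% default_lesion_params(num_classes)
  if (length(lesion_params) != num_classes)
    abort_config("`lesion_params` must have one entry per class.")
  structure(list(
    num_classes = as.integer(num_classes),
    images_per_class = as.integer(images_per_class),
    image_size = as.integer(image_size), lesion_params = lesion_params,
    impulse_noise_rate = impulse_noise_rate,
    illumination_gradient = isTRUE(illumination_gradient),
    label_noise_rate = label_noise_rate, seed = as.integer(seed)),
    class = "fusnet_synth_config")
}

# Distinct lesion phenotypes; class 1 is healthy (no lesions). The
# palette recycles with jittered counts beyond 7 classes.
default_lesion_params <- function(num_classes) {
  palette <- list(
    list(count = c(0L, 0L), radius = c(0.03, 0.05), color = c(60, 120, 50)),
    list(count = c(4L, 7L), radius = c(0.035, 0.06), color = c(120, 66, 30)),
    list(count = c(8L, 14L), radius = c(0.025, 0.045), color = c(210, 186, 50)),
    list(count = c(2L, 4L), radius = c(0.07, 0.11), color = c(45, 34, 26)),
    list(count = c(5L, 9L), radius = c(0.03, 0.055), color = c(183, 65, 14)),
    list(count = c(10L, 16L), radius = c(0.02, 0.035), color = c(230, 228, 215)),
    list(count = c(3L, 6L), radius = c(0.05, 0.08), color = c(96, 60, 104)))
  lapply(seq_len(num_classes), function(i) palette[[(i - 1L) %% length(palette) + 1L]])
}

# Smooth random field: coarse uniform noise bilinearly upsampled to s x s.
# Keeps the rendered scene low-frequency, so impulse noise is the only
# high-frequency content and the median filter's denoising role is cleanly
# separable from the scene itself.
smooth_noise <- function(s, amp, cells = 6L, quantum = 8) {
  coarse <- matrix(runif((cells + 1L)^2, -amp, amp), cells + 1L)
  t <- seq(0, cells, length.out = s)
  i0 <- pmin(floor(t), cells - 1L)
  fr <- t - i0
  i0 <- i0 + 1L
  rows <- coarse[i0, , drop = FALSE] * (1 - fr) +
    coarse[i0 + 1L, , drop = FALSE] * fr
  field <- rows[, i0, drop = FALSE] * rep(1 - fr, each = s) +
    rows[, i0 + 1L, drop = FALSE] * rep(fr, each = s)
  # quantize into terraces: flat plateaus separated by step edges, which a
  # median filter leaves essentially untouched
  round(field / quantum) * quantum
}

render_leaf_image <- function(cfg, class_idx) {
  s <- cfg$image_size
  lp <- cfg$lesion_params[[class_idx]]
  xg <- matrix(rep(seq_len(s), each = s), s)      # column index grid
  yg <- matrix(rep(seq_len(s), times = s), s)     # row index grid
  # smoothly textured background
  base_bg <- c(112, 88, 62) + runif(3, -12, 12)
  img <- array(0, c(s, s, 3))
  for (ch in 1:3)
    img[, , ch] <- base_bg[ch] + smooth_noise(s, 24)
  # elliptical leaf silhouette, jittered and rotated
  cx <- s / 2 + runif(1, -s / 16, s / 16)
  cy <- s / 2 + runif(1, -s / 16, s / 16)
  rx <- runif(1, 0.30, 0.42) * s
  ry <- runif(1, 0.22, 0.34) * s
  th <- runif(1, 0, pi)
  xr <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
  yr <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
  r2 <- (xr / rx)^2 + (yr / ry)^2
  mask <- r2 <= 1
  leaf_col <- c(58, 125, 48) + runif(3, -14, 14)
  shade <- round((1 - 0.25 * pmin(r2, 1)) / 0.1) * 0.1  # terraced rim shading
  for (ch in 1:3) {
    plane <- img[, , ch]
    tex <- leaf_col[ch] + smooth_noise(s, 18)
    plane[mask] <- tex[mask] * shade[mask]
    img[, , ch] <- plane
  }
  # class-dependent lesion spots, only on the leaf
  n_spot <- if (lp$count[2] > 0L)
    sample(lp$count[1]:lp$count[2], 1L) else 0L
  inside <- which(mask)
  for (sp in seq_len(n_spot)) {
    ctr <- inside[sample.int(length(inside), 1L)]
    scy <- (ctr - 1L) %% s + 1L
    scx <- (ctr - 1L) %/% s + 1L
    rad <- runif(1, lp$radius[1], lp$radius[2]) * s
    d2 <- (xg - scx)^2 + (yg - scy)^2
    spot <- mask & d2 <= rad^2
    core <- mask & d2 <= (0.6 * rad)^2            # two-tone hard-edged lesion
    if (!any(spot)) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[spot] <- 0.3 * plane[spot] + 0.7 * lp$color[ch]
      plane[core] <- lp$color[ch]
      img[, , ch] <- plane
    }
  }
  # linear illumination ramp
  if (cfg$illumination_gradient) {
    phi <- runif(1, 0, 2 * pi)
    t <- (xg - 1) / (s - 1) * cos(phi) + (yg - 1) / (s - 1) * sin(phi)
    t <- (t - min(t)) / max(max(t) - min(t), 1e-12)
    ramp <- round((0.75 + 0.5 * t) / 0.05) * 0.05  # terraced ramp
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
  }
  # salt-and-pepper impulse noise, whole-pixel
  n_noise <- round(cfg$impulse_noise_rate * s * s)
  if (n_noise > 0) {
    pix <- sample.int(s * s, n_noise)
    val <- sample(c(0, 255), n_noise, replace = TRUE)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pix] <- val
      img[, , ch] <- plane
    }
  }
  array(pmin(pmax(round(img), 0), 255), c(s, s, 3))
}

#' Generate a labeled synthetic leaf-image set
#'
#' Renders `images_per_class` images for each class under the given
#' configuration, applies exact-count label corruption, and returns the
#' images with a manifest. The same seed always yields byte-identical
#' output.
#'
#' @param config A [synth_config()].
#' @return A list of class `fusnet_leaf_set`: `images` (list of
#'   `H x W x 3` integer arrays), `labels` (assigned, possibly corrupted,
#'   1-based integers), and `manifest` (tibble with `filename`,
#'   `class_index`, `class_name`, `true_class`, `corrupted`).
#' @export
generate_leaf_set <- function(config) {
  if (!inherits(config, "fusnet_synth_config"))
    abort_config("`config` must be a synth_config().")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  k <- config$num_classes
  n <- k * config$images_per_class
  true_class <- rep(seq_len(k), each = config$images_per_class)
  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- render_leaf_image(config, true_class[i])
  labels <- true_class
  n_bad <- round(config$label_noise_rate * n)
  corrupted <- rep(FALSE, n)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    corrupted[bad] <- TRUE
    for (i in bad)
      labels[i] <- sample(setdiff(seq_len(k), true_class[i]), 1L)
  }
  class_name <- sprintf("class_%02d", labels)
  manifest <- tibble::tibble(
    filename = sprintf("%s/img_%05d.png", class_name, seq_len(n)),
    class_index = labels, class_name = class_name,
    true_class = true_class, corrupted = corrupted)
  structure(list(images = images, labels = labels, manifest = manifest,
                 num_classes = k),
            class = "fusnet_leaf_set")
}

#' @export
print.fusnet_leaf_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<leaf set: %d images, %d classes, %dx%d, %d corrupted labels>\n",
              length(x$images), x$num_classes, d[1], d[2],
              sum(x$manifest$corrupted)))
  invisible(x)
}

#' Write a leaf set as a class-per-directory tree
#'
#' One subdirectory per assigned class, PNG files inside, plus a
#' `manifest.csv` at the root.
#'
#' @param set A [generate_leaf_set()] result.
#' @param root Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_leaf_set <- function(set, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) abort_io(sprintf("cannot create directory: %s", root))
  for (cn in unique(set$manifest$class_name))
    dir.create(file.path(root, cn), showWarnings = FALSE)
  for (i in seq_along(set$images))
    png::writePNG(set$images[[i]] / 255,
                  file.path(root, set$manifest$filename[i]))
  path <- file.path(root, "manifest.csv")
  readr::write_csv(set$manifest, path)
  invisible(path)
}

#' Read a class-per-directory leaf dataset
#'
#' Reads back a tree written by [write_leaf_set()] (or any
#' class-per-directory PNG/JPEG layout); the manifest is used when
#' present, otherwise labels are taken from the directory names in
#' sorted order.
#'
#' @param root Dataset root directory.
#' @return A `fusnet_leaf_set`.
#' @export
read_leaf_set <- function(root) {
  if (!dir.exists(root)) abort_io(sprintf("directory not found: %s", root))
  mpath <- file.path(root, "manifest.csv")
  if (file.exists(mpath)) {
    manifest <- readr::read_csv(mpath, show_col_types = FALSE)
    files <- file.path(root, manifest$filename)
    labels <- as.integer(manifest$class_index)
  } else {
    dirs <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
    if (length(dirs) == 0L) abort_io("no class directories found.")
    files <- character(0)
    labels <- integer(0)
    for (i in seq_along(dirs)) {
      f <- list.files(file.path(root, dirs[i]),
                      pattern = "\\.(png|jpe?g)$", full.names = TRUE)
      files <- c(files, f)
      labels <- c(labels, rep(i, length(f)))
    }
    manifest <- tibble::tibble(
      filename = sub(paste0("^", root, "/?"), "", files),
      class_index = labels,
      class_name = sprintf("class_%02d", labels),
      true_class = labels, corrupted = FALSE)
  }
  images <- lapply(files, read_leaf_image)
  structure(list(images = images, labels = labels, manifest = manifest,
                 num_classes = max(labels)),
            class = "fusnet_leaf_set")
}
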