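# Brute-force reference implementations, written independently of the
# package internals: plain loops, sort-and-pick medians, direct index
# arithmetic. Used wherever a fast implementation must match an obvious one.

reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_median_filter <- function(img, window) {
  d <- dim(img)
  r <- (window - 1) / 2
  out <- img
  for (ch in seq_len(d[3])) {
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        vals <- numeric(0)
        for (di in -r:r) {
          for (dj in -r:r) {
            vals <- c(vals, img[reflect1(i + di, d[1]),
                                reflect1(j + dj, d[2]), ch])
          }
        }
        out[i, j, ch] <- sort(vals)[(window^2 + 1) / 2]
      }
    }
  }
  out
}

oracle_maxpool <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3]))
    for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2))
      out[i, j, c, n] <- max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n])
  out
}

# Direct translation of the sub-pixel index mapping (0-based indices).
oracle_pixel_shuffle <- function(x, a) {
  d <- dim(x)
  C <- d[3] / (a * a)
  out <- array(0, c(d[1] * a, d[2] * a, C))
  for (i in 0:(d[1] * a - 1)) for (j in 0:(d[2] * a - 1)) for (cc in 0:(C - 1)) {
    ci <- C * a * (i %% a) + C * (j %% a) + cc
    out[i + 1, j + 1, cc + 1] <- x[i %/% a + 1, j %/% a + 1, ci + 1]
  }
  out
}

# Per-sample classification losses evaluated one element at a time.
oracle_class_loss <- function(prob, labels, family, delta = 1, gamma = 2) {
  n <- nrow(prob)
  k <- ncol(prob)
  per <- numeric(n)
  for (i in seq_len(n)) {
    if (family %in% c("huber", "improved_huber")) {
      acc <- 0
      for (c in seq_len(k)) {
        e <- prob[i, c] - as.numeric(c == labels[i])
        acc <- acc + if (abs(e) <= delta) 0.5 * e^2 else
          if (family == "huber") delta * abs(e) - 0.5 * delta else
            delta * abs(e) - 0.5 * delta^2
      }
      per[i] <- acc / k
    } else if (family == "cross_entropy") {
      per[i] <- -log(max(prob[i, labels[i]], 1e-12))
    } else if (family == "focal") {
      p <- max(prob[i, labels[i]], 1e-12)
      per[i] <- -(1 - p)^gamma * log(p)
    } else if (family == "exponential") {
      acc <- 0
      for (c in seq_len(k)) {
        t <- if (c == labels[i]) 1 else -1
        acc <- acc + exp(-t * (2 * prob[i, c] - 1))
      }
      per[i] <- acc / k
    }
  }
  per
}

oracle_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  res <- data.frame(precision = numeric(k), recall = numeric(k),
                    specificity = numeric(k), f1 = numeric(k))
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$precision[c] <- p
    res$recall[c] <- r
    res$specificity[c] <- if (tn + fp > 0) tn / (tn + fp) else 1
    res$f1[c] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  res
}

random_raw_image <- function(h, w, c = 3) {
  array(sample(0:255, h * w * c, replace = TRUE), c(h, w, c))
}

random_prob_rows <- function(n, k) {
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}

# Small labeled set for fast training tests.
tiny_leaf_set <- function(num_classes = 3, images_per_class = 20, size = 32,
                          label_noise = 0, seed = 5) {
  generate_leaf_set(synth_config(
    num_classes = num_classes, images_per_class = images_per_class,
    image_size = size, label_noise_rate = label_noise, seed = seed))
}
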