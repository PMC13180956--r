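test_that("Huber branch values match the printed formulas", {
  expect_equal(huber_loss(0.5, 1), 0.125)
  expect_equal(huber_loss(3, 2), 5)        # 2*3 - 0.5*2
  expect_equal(huber_loss(0, 1), 0)
  expect_equal(improved_huber_loss(3, 2), 4)   # 2*3 - 0.5*4
  expect_equal(improved_huber_loss(0, 1), 0)
  # continuity at the transition from either branch
  expect_equal(improved_huber_loss(2, 2), 2)
  expect_equal(0.5 * 2^2, 2 * 2 - 0.5 * 2^2)
  # the two families coincide at delta = 1
  e <- seq(-4, 4, by = 0.25)
  expect_identical(huber_loss(e, 1), improved_huber_loss(e, 1))
})

test_that("improved Huber is C1-continuous; printed Huber has the known jump", {
  for (delta in c(0.5, 1, 2, 5)) {
    eps <- 1e-7
    below <- improved_huber_loss(delta - eps, delta)
    above <- improved_huber_loss(delta + eps, delta)
    expect_lt(abs(above - below), 1e-6)
    # exact value continuity at the boundary
    expect_equal(0.5 * delta^2, delta * delta - 0.5 * delta^2,
                 tolerance = 1e-12)
    # derivative continuity (both one-sided slopes equal delta)
    d_lo <- (improved_huber_loss(delta, delta) -
             improved_huber_loss(delta - eps, delta)) / eps
    d_hi <- (improved_huber_loss(delta + eps, delta) -
             improved_huber_loss(delta, delta)) / eps
    expect_lt(abs(d_lo - delta), 1e-5)
    expect_lt(abs(d_hi - delta), 1e-5)
    # printed Huber jump: 0.5 * delta * (delta - 1), vanishing only at 1
    jump <- (delta * delta - 0.5 * delta) - 0.5 * delta^2
    expect_equal(jump, 0.5 * delta * (delta - 1), tolerance = 1e-12)
    if (delta != 1) expect_gt(abs(jump), 0)
  }
})

test_that("improved Huber has bounded gradient and never exceeds squared error", {
  e <- seq(-10, 10, by = 0.01)
  for (delta in c(0.5, 1, 3)) {
    grad <- diff(improved_huber_loss(e, delta)) / diff(e)
    expect_true(all(abs(grad) <= delta + 1e-6))
    expect_true(all(improved_huber_loss(e, delta) <= 0.5 * e^2 + 1e-12))
    expect_true(all(improved_huber_loss(e, delta) >= 0))
  }
})

test_that("loss inputs are validated", {
  expect_error(huber_loss(Inf, 1), class = "fusnet_invalid_input")
  expect_error(huber_loss(NA_real_, 1), class = "fusnet_invalid_input")
  expect_error(huber_loss(1, 0), class = "fusnet_invalid_parameter")
  expect_error(improved_huber_loss(1, -2), class = "fusnet_invalid_parameter")
  expect_error(loss_config(delta = 0), class = "fusnet_invalid_parameter")
  expect_error(loss_config(focal_gamma = -1),
               class = "fusnet_invalid_parameter")
})

test_that("reduce_loss computes the configured reduction", {
  expect_equal(reduce_loss(c(1, 2, 3), "mean")$value, 2)
  expect_equal(reduce_loss(c(1, 2, 3), "sum")$value, 6)
  expect_equal(reduce_loss(0, "mean")$value, 0)
  expect_error(reduce_loss(numeric(0)), class = "fusnet_invalid_input")
})

test_that("classification losses vanish (or are minimal) at perfect predictions", {
  k <- 4
  prob <- diag(k)
  labels <- 1:4
  for (fam in c("huber", "improved_huber", "cross_entropy", "focal")) {
    v <- classification_loss(prob, labels, loss_config(fam))$value
    expect_equal(v, 0, tolerance = 1e-10)
  }
  # the exponential loss is strictly positive everywhere; the perfect
  # prediction attains its minimum exp(-1)
  v_perfect <- classification_loss(prob, labels, loss_config("exponential"))$value
  expect_equal(v_perfect, exp(-1))
  v_other <- classification_loss(random_prob_rows(10, k), sample(k, 10, TRUE),
                                 loss_config("exponential"))$value
  expect_gt(v_other, v_perfect)
})

test_that("Huber classification adapter reproduces the hand-worked example", {
  v <- classification_loss(matrix(c(0.5, 0.5), 1), 1L,
                           loss_config("improved_huber", delta = 1))$value
  expect_equal(v, 0.125)
})

test_that("classification losses match the per-element oracle on seeded batches", {
  set.seed(99)
  for (fam in c("huber", "improved_huber", "cross_entropy", "focal",
                "exponential")) {
    prob <- random_prob_rows(16, 5)
    labels <- sample(5, 16, replace = TRUE)
    got <- classification_loss(prob, labels, loss_config(fam, delta = 0.7))
    want <- oracle_class_loss(prob, labels, fam, delta = 0.7)
    expect_equal(got$per_element, want, tolerance = 1e-12)
    expect_equal(got$value, mean(want), tolerance = 1e-12)
  }
})

test_that("classification loss gradient matches finite differences", {
  set.seed(17)
  prob <- random_prob_rows(6, 4)
  labels <- sample(4, 6, replace = TRUE)
  for (fam in c("huber", "improved_huber", "focal", "exponential")) {
    lg <- fusnetcnn:::classification_loss_grad(prob, labels, loss_config(fam))
    eps <- 1e-6
    for (probe in 1:6) {
      i <- sample(6, 1); j <- sample(4, 1)
      # probe the unnormalized surface: perturb one entry only
      pp <- prob; pp[i, j] <- pp[i, j] + eps
      pm <- prob; pm[i, j] <- pm[i, j] - eps
      fp <- mean(oracle_class_loss(pp, labels, fam))
      fm <- mean(oracle_class_loss(pm, labels, fam))
      expect_equal(lg$grad[i, j], (fp - fm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("classification loss validates labels and probability rows", {
  prob <- random_prob_rows(4, 3)
  expect_error(classification_loss(prob, c(1, 2, 3, 4)),
               class = "fusnet_invalid_input")
  expect_error(classification_loss(prob, c(1, 2, 0, 1)),
               class = "fusnet_invalid_input")
  expect_error(classification_loss(matrix(c(0.7, 0.6), 1), 1L),
               class = "fusnet_invalid_input")
})

test_that("L1 reconstruction loss is the mean absolute difference", {
  a <- array(runif(24), c(2, 2, 3, 2))
  expect_equal(l1_reconstruction(a, a)$value, 0)
  expect_equal(l1_reconstruction(array(1, c(3, 4)), array(0, c(3, 4)))$value, 1)
  sr <- matrix(c(0, 1, 2, 3), 2)
  ref <- matrix(1, 2, 2)
  expect_equal(l1_reconstruction(sr, ref)$value, 1)
  expect_error(l1_reconstruction(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "fusnet_invalid_input")
})

test_that("improved Huber slope fitting resists gross outliers", {
  set.seed(31)
  wins <- 0
  for (r in 1:8) {
    x <- runif(150, 0, 10)
    y <- 2 * x + rnorm(150, sd = 0.5)
    out <- sample(150, 30)
    y[out] <- y[out] + 50
    b_h <- fit_slope_gd(x, y, "improved_huber", lr = 0.01, iters = 2000)
    b_s <- fit_slope_gd(x, y, "squared", lr = 0.01, iters = 2000)
    wins <- wins + (abs(b_h - 2) < abs(b_s - 2))
  }
  expect_gte(wins, 7)
})
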