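one_hot <- function(y, n_classes = 4) {
  p <- matrix(0, length(y), n_classes)
  p[cbind(seq_along(y), y + 1L)] <- 1
  p
}

test_that("perfect predictions give zero loss in every term", {
  y <- sample(0:3, 64, replace = TRUE)
  p <- one_hot(y)
  expect_lt(weighted_cross_entropy(p, y, c(1, 5, 2, 3)), 1e-6)
  expect_lt(focal_tversky(p, y), 1e-6)
  expect_lt(combined_loss(p, y, loss_config(class_weights = c(1, 5, 2, 3))), 1e-6)
})

test_that("uniform probabilities give cross-entropy log 4", {
  y <- sample(0:3, 50, replace = TRUE)
  p <- matrix(0.25, 50, 4)
  expect_equal(weighted_cross_entropy(p, y), log(4), tolerance = 1e-9)
})

test_that("cross-entropy is linear in the class weights", {
  y <- rep(2L, 20)
  set.seed(1)
  p <- matrix(runif(80, 0.1, 0.9), 20, 4)
  p <- p / rowSums(p)
  w1 <- c(1, 1, 1, 1); w2 <- c(1, 1, 2, 1)
  expect_equal(weighted_cross_entropy(p, y, w2),
               2 * weighted_cross_entropy(p, y, w1), tolerance = 1e-12)
})

test_that("the Tversky index reproduces a hand-computed fixture", {
  # 8 pixels of class 1 with p = 0.75 (TP = 6, FN = 2) and 4 background
  # pixels with p1 = 0.5 (FP = 2): TI = 6 / (6 + 0.7*2 + 0.3*2) = 0.75
  y <- c(rep(1L, 8), rep(0L, 4))
  p <- matrix(0, 12, 4)
  p[1:8, 2] <- 0.75; p[1:8, 1] <- 0.25
  p[9:12, 2] <- 0.5; p[9:12, 1] <- 0.5
  cfg <- loss_config(smooth = 1e-12)
  expect_equal(focal_tversky(p, y, cfg, foreground_classes = 1),
               0.25^(3 / 4), tolerance = 1e-6)
})

test_that("Tversky with alpha = beta = 0.5 and unit focal exponent is soft Dice", {
  set.seed(2)
  y <- sample(0:3, 40, replace = TRUE)
  p <- matrix(runif(160), 40, 4); p <- p / rowSums(p)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, gamma_ft = 1, smooth = 0)
  got <- focal_tversky(p, y, cfg)
  expected <- sum(vapply(1:3, function(cl) {
    t <- as.numeric(y == cl); pc <- p[, cl + 1]
    1 - 2 * sum(pc * t) / (sum(pc) + sum(t))
  }, 0))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("combination weights degenerate to the individual terms", {
  set.seed(3)
  y <- sample(0:3, 30, replace = TRUE)
  p <- matrix(runif(120), 30, 4); p <- p / rowSums(p)
  w <- c(1, 2, 3, 4)
  cfg_ce <- loss_config(class_weights = w, lambda_ft = 0)
  expect_equal(combined_loss(p, y, cfg_ce),
               weighted_cross_entropy(p, y, w), tolerance = 1e-12)
  cfg_ft <- loss_config(class_weights = w, lambda_ce = 0)
  expect_equal(combined_loss(p, y, cfg_ft), focal_tversky(p, y, cfg_ft),
               tolerance = 1e-12)
  expect_error(loss_config(alpha = 0.6, beta = 0.5), "alpha")
  expect_error(loss_config(gamma_ft = 0.5), "gamma")
})

test_that("the learning rate decays exponentially from 1e-4", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-4)
  expect_equal(lr_schedule(1, cfg), 9.6e-5)
  lrs <- lr_schedule(0:60, cfg)
  expect_true(all(diff(lrs) < 0))
})

test_that("analytic loss gradients match finite differences on a 4x4 fixture", {
  set.seed(4)
  n <- 16
  y <- sample(0:3, n, replace = TRUE)
  z <- matrix(rnorm(n * 4), n, 4)  # logits
  cfg <- loss_config(class_weights = c(0.5, 2, 1, 1.5))
  lossz <- function(z) combined_loss(cardunet:::softmax_rows(z), y, cfg)
  p <- cardunet:::softmax_rows(z)
  an <- cardunet:::combined_loss_grad_logits(p, y, cfg)
  for (i in sample(length(z), 12)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    fd <- (lossz(zp) - lossz(zm)) / 2e-6
    expect_lt(abs(fd - an[i]) / max(abs(an[i]), abs(fd), 1e-8), 1e-3)
  }
})

test_that("loss decreases monotonically toward the true labels", {
  set.seed(5)
  y <- sample(0:3, 64, replace = TRUE)
  target <- one_hot(y)
  p0 <- matrix(0.25, 64, 4)
  cfg <- loss_config()
  losses <- vapply(seq(0, 1, length.out = 5), function(t) {
    combined_loss((1 - t) * p0 + t * (0.999 * target + 0.001 * p0), y, cfg)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("model selection picks the epoch with the highest validation DSC", {
  expect_equal(best_epoch(c(0.2, 0.9, 0.5)), 2L)
  expect_equal(best_epoch(c(0.3, 0.3, 0.3)), 1L)  # earliest wins ties
})

test_that("median-frequency weights up-weight rare classes with mean one", {
  masks <- list(matrix(c(rep(0L, 90), rep(1L, 6), rep(2L, 3), rep(3L, 1)), 10))
  w <- median_frequency_weights(masks, 4)
  expect_equal(mean(w), 1)
  expect_true(w[1] < w[2] && w[2] < w[3] && w[3] < w[4])
})
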