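test_that("encoder channel widths double at every stage", {
  spec <- model_spec(depth = 4, base_channels = 32)
  expect_equal(cardunet:::stage_channels(spec), c(32L, 64L, 128L, 256L))
  m <- build_model(model_spec(depth = 3, base_channels = 4), seed = 1)
  # packed conv weights are c_in x 9*c_out
  expect_equal(dim(m$params[["enc1a.W"]]), c(1L, 9L * 4L))
  expect_equal(dim(m$params[["enc2a.W"]]), c(4L, 9L * 8L))
  expect_equal(dim(m$params[["enc3a.W"]]), c(8L, 9L * 16L))
  expect_equal(dim(m$params[["botta.W"]]), c(16L, 9L * 32L))
})

test_that("output grid matches input grid and probabilities sum to one", {
  for (depth in 2:3) {
    for (size in c(32L, 48L)) {
      m <- build_model(model_spec(depth = depth, base_channels = 2), seed = 1)
      img <- matrix(runif(size * size), size)
      out <- predict(m, img)
      expect_equal(dim(out$labels), c(size, size))
      expect_equal(dim(out$prob), c(size, size, 4L))
      sums <- apply(out$prob, c(1, 2), sum)
      expect_lt(max(abs(sums - 1)), 1e-5)
      expect_true(all(out$labels %in% 0:3))
    }
  }
})

test_that("model building and inference are deterministic", {
  m1 <- build_model(model_spec(depth = 2, base_channels = 2), seed = 42)
  m2 <- build_model(model_spec(depth = 2, base_channels = 2), seed = 42)
  expect_identical(m1$params, m2$params)
  img <- matrix(runif(32 * 32), 32)
  expect_identical(predict(m1, img), predict(m2, img))
})

test_that("argmax ties break toward the lowest class index", {
  m <- build_model(model_spec(depth = 2, base_channels = 2), seed = 1)
  m$params[["out.W"]][] <- 0
  m$params[["out.b"]][] <- 0   # logits all equal -> uniform probabilities
  out <- predict(m, matrix(runif(32 * 32), 32))
  expect_true(all(out$labels == 0L))
  expect_equal(max(abs(out$prob - 0.25)), 0, tolerance = 1e-12)
})

test_that("a saturated-open attention gate passes skip features through", {
  set.seed(1)
  skip <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  gating <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  par <- list(theta = list(W = matrix(0, 4, 2), b = c(0, 0)),
              phi = list(W = matrix(0, 8, 2), b = c(0, 0)),
              psi = list(W = matrix(0, 2, 1), b = 20))
  out <- attention_gate(skip, gating, 2, par = par)
  expect_lt(max(abs(out$out - skip)), 1e-6)
  par$psi$b <- -20
  out <- attention_gate(skip, gating, 2, par = par)
  expect_lt(max(abs(out$out)), 1e-6)
})

test_that("attention coefficients lie in [0, 1] and attenuate the skip", {
  set.seed(2)
  for (i in 1:5) {
    skip <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    gating <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
    out <- attention_gate(skip, gating, 2, seed = i)
    expect_true(all(out$alpha >= 0 & out$alpha <= 1))
    expect_true(all(abs(out$out) <= abs(skip) + 1e-12))
  }
})

test_that("the gate-free ablation variant builds and runs", {
  spec <- model_spec(depth = 3, base_channels = 2,
                     ag_levels = integer(0), conv_skip_levels = 1:3)
  m <- build_model(spec, seed = 1)
  out <- predict(m, matrix(runif(32 * 32), 32))
  expect_equal(dim(out$labels), c(32L, 32L))
  expect_error(model_spec(depth = 3, ag_levels = c(1, 2), conv_skip_levels = c(2, 3)),
               "partition")
  expect_error(model_spec(depth = 1), "depth")
})

test_that("compiled conv and batch-norm kernels match the reference implementation", {
  set.seed(5)
  gc_ <- cardunet:::new_geom_cache()
  g <- cardunet:::tensor_geometry(gc_, 6L, 8L, 3L)
  par <- cardunet:::conv3_init(5L, 4L)
  x <- matrix(rnorm(g$n * 5), g$n, 5)
  f_ref <- cardunet:::conv3_fwd_ref(x, par, g)
  f_cpp <- cardunet:::conv3_fwd(x, par, g)
  expect_equal(f_cpp$out, f_ref$out, tolerance = 1e-12)
  dy <- matrix(rnorm(g$n * 4), g$n, 4)
  b_ref <- cardunet:::conv3_bwd_ref(dy, par, f_ref, g)
  b_cpp <- cardunet:::conv3_bwd(dy, par, f_cpp, g)
  expect_equal(b_cpp$dx, b_ref$dx, tolerance = 1e-12)
  expect_equal(b_cpp$dW, b_ref$dW, tolerance = 1e-12)
  expect_equal(as.numeric(b_cpp$db), b_ref$db, tolerance = 1e-12)
  bn <- cardunet:::bn_init(5L)
  r_ref <- cardunet:::bn_fwd_ref(x, bn$par, bn$state, TRUE)
  r_cpp <- cardunet:::bn_fwd(x, bn$par, bn$state, TRUE)
  expect_equal(r_cpp$out, r_ref$out, tolerance = 1e-12)
  expect_equal(r_cpp$state$mean, r_ref$state$mean, tolerance = 1e-12)
  dyb <- matrix(rnorm(g$n * 5), g$n)
  d_ref <- cardunet:::bn_bwd_ref(dyb, bn$par, r_ref)
  d_cpp <- cardunet:::bn_bwd(dyb, bn$par, r_cpp)
  expect_equal(d_cpp$dx, d_ref$dx, tolerance = 1e-12)
  expect_equal(d_cpp$dgamma, d_ref$dgamma, tolerance = 1e-12)
  # pooling and upsampling kernels against the index-based reference
  p_ref <- cardunet:::pool_fwd(x, g)
  p_cpp <- cardunet:::pool_fwd_cpp(x, g$h, g$w, g$b)
  expect_equal(p_cpp$out, p_ref$out, tolerance = 1e-12)
  dyp <- matrix(rnorm(nrow(p_ref$out) * 5), nrow(p_ref$out))
  expect_equal(cardunet:::pool_bwd_cpp(dyp, p_cpp$arg, g$h, g$w, g$b),
               cardunet:::pool_bwd(dyp, p_ref, g), tolerance = 1e-12)
  expect_equal(cardunet:::up_fwd_cpp(x, g$h, g$w, g$b),
               cardunet:::up_fwd(x, g), tolerance = 1e-12)
  dyu <- matrix(rnorm(4 * g$n * 5), 4 * g$n)
  u_ref <- cardunet:::up_bwd(dyu, cardunet:::tensor_geometry(gc_, 6L, 8L, 3L))
  expect_equal(cardunet:::up_bwd_cpp(dyu, g$h, g$w, g$b),
               matrix(u_ref, nrow(u_ref)), tolerance = 1e-12)
})

test_that("backpropagated network gradients match finite differences", {
  spec <- model_spec(depth = 2, base_channels = 2)
  m <- build_model(spec, seed = 7)
  h <- w <- 8L
  set.seed(1)
  x <- matrix(runif(h * w), h * w, 1)
  y <- sample(0:3, h * w, replace = TRUE)
  lc <- loss_config(class_weights = c(1, 2, 1.5, 1))
  netloss <- function(model) {
    fwd <- cardunet:::unet_forward(model, x, h, w, 1L, training = TRUE)
    combined_loss(fwd$probs, y, lc)
  }
  fwd <- cardunet:::unet_forward(m, x, h, w, 1L, training = TRUE)
  dlog <- cardunet:::combined_loss_grad_logits(fwd$probs, y, lc)
  G <- cardunet:::unet_backward(m, fwd, dlog)
  set.seed(99)
  for (nm in sample(names(G), 8)) {
    i <- sample(length(m$params[[nm]]), 1)
    an <- G[[nm]][i]
    if (abs(an) < 1e-6) next  # bias-into-BN parameters are exactly inert
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + 1e-5
    mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - 1e-5
    fd <- (netloss(mp) - netloss(mm)) / 2e-5
    expect_lt(abs(fd - an) / max(abs(an), abs(fd)), 1e-3)
  }
})
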