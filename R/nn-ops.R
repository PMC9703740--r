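# Low-level neural-network primitives.
#
# No deep-learning framework is used: every layer is expressed as dense
# matrix algebra so the heavy lifting lands in BLAS.  A feature tensor for a
# batch of B images of size H x W with C channels is stored as a numeric
# matrix with B*H*W rows (image-major, column-major within each image) and C
# columns.  3x3 convolutions are evaluated by im2col: the nine shifted copies
# of the input are bound into an N x 9C matrix and multiplied by a 9C x Cout
# weight matrix.  Each forward function returns a cache carrying what its
# hand-derived backward pass needs.

# offsets for the 3x3 stencil; row k and row 10-k are opposite shifts,
# which is exactly the adjoint relationship used in conv backward
.conv_offsets <- expand.grid(dy = -1:1, dx = -1:1)

new_geom_cache <- function() new.env(parent = emptyenv())

# index vectors for one (H, W, B) geometry: conv shifts, 2x2 max-pool
# positions and nearest-neighbour 2x upsampling
tensor_geometry <- function(cache, h, w, b) {
  key <- sprintf("g_%d_%d_%d", h, w, b)
  g <- cache[[key]]
  if (!is.null(g)) return(g)
  n <- h * w * b
  zero_row <- n + 1L  # conv inputs are padded with one all-zero row
  batch_off <- rep((seq_len(b) - 1L) * (h * w), each = h * w)
  shifts <- lapply(seq_len(9), function(k) {
    dy <- .conv_offsets$dy[k]; dx <- .conv_offsets$dx[k]
    m <- matrix(NA_integer_, h, w)
    sy <- seq_len(h) + dy; sx <- seq_len(w) + dx
    oy <- sy >= 1L & sy <= h; ox <- sx >= 1L & sx <= w
    if (any(oy) && any(ox))
      m[oy, ox] <- outer(sy[oy], (sx[ox] - 1L) * h, "+")
    idx <- rep(as.integer(m), b) + batch_off
    idx[is.na(idx)] <- zero_row
    idx
  })
  pool <- NULL
  if (h %% 2L == 0L && w %% 2L == 0L) {
    ho <- h %/% 2L; wo <- w %/% 2L
    off_o <- rep((seq_len(b) - 1L) * (h * w), each = ho * wo)
    pool <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
      m <- outer(2L * seq_len(ho) - 1L + d[1], (2L * seq_len(wo) - 2L + d[2]) * h, "+")
      rep(as.integer(m), b) + off_o
    })
  }
  iy <- ceiling(seq_len(2L * h) / 2); ix <- ceiling(seq_len(2L * w) / 2)
  up <- rep(as.integer(outer(iy, (ix - 1L) * h, "+")), b) + rep((seq_len(b) - 1L) * (h * w), each = 4L * h * w)
  g <- list(h = h, w = w, b = b, n = n, shifts = shifts, pool = pool, up = up)
  cache[[key]] <- g
  g
}

## ---- 3x3 convolution (same padding) ----

conv3_init <- function(c_in, c_out, rng_sd = NULL) {
  fan_in <- 9 * c_in
  sd <- rng_sd %||% sqrt(2 / fan_in)
  # weights stored as c_in x 9*c_out, column block k = W_k (see src/)
  list(W = matrix(rnorm(9 * c_in * c_out, sd = sd), c_in, 9 * c_out),
       b = numeric(c_out))
}

# reshape the packed weight matrix to the im2col layout (9*c_in x c_out)
# used by the reference implementation
conv3_weights_im2col <- function(W) {
  c_in <- nrow(W); c_out <- ncol(W) %/% 9L
  W9 <- matrix(0, 9L * c_in, c_out)
  for (k in seq_len(9))
    W9[(k - 1L) * c_in + seq_len(c_in), ] <-
      W[, (k - 1L) * c_out + seq_len(c_out), drop = FALSE]
  W9
}

conv3_fwd_ref <- function(x, par, g) {
  n <- g$n
  xp <- rbind(x, 0)
  xcol <- do.call(cbind, lapply(g$shifts, function(ix) xp[ix, , drop = FALSE]))
  y <- xcol %*% conv3_weights_im2col(par$W)
  y <- y + rep(par$b, each = n)
  list(out = y, xcol = xcol, x = x)
}

conv3_bwd_ref <- function(dy, par, cache, g) {
  W9 <- conv3_weights_im2col(par$W)
  c_in <- nrow(W9) %/% 9L
  dW <- crossprod(cache$xcol, dy)
  db <- colSums(dy)
  dxcol <- tcrossprod(dy, W9)  # N x 9Cin
  dx <- matrix(0, g$n, c_in)
  for (k in seq_len(9)) {
    blk <- dxcol[, ((k - 1L) * c_in + 1L):(k * c_in), drop = FALSE]
    blkp <- rbind(blk, 0)
    dx <- dx + blkp[g$shifts[[10L - k]], , drop = FALSE]
  }
  # repack dW into the c_in x 9*c_out layout
  c_out <- ncol(dy)
  dWp <- matrix(0, c_in, 9L * c_out)
  for (k in seq_len(9))
    dWp[, (k - 1L) * c_out + seq_len(c_out)] <-
      dW[(k - 1L) * c_in + seq_len(c_in), , drop = FALSE]
  list(dx = dx, dW = dWp, db = db)
}

## ---- 1x1 convolution ----

conv1_init <- function(c_in, c_out, rng_sd = NULL) {
  sd <- rng_sd %||% sqrt(2 / c_in)
  list(W = matrix(rnorm(c_in * c_out, sd = sd), c_in, c_out),
       b = numeric(c_out))
}

conv1_fwd <- function(x, par) {
  y <- x %*% par$W
  list(out = y + rep(par$b, each = nrow(x)), x = x)
}

conv1_bwd <- function(dy, par, cache) {
  list(dx = tcrossprod(dy, par$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## ---- batch normalization (per channel over batch x space) ----

bn_init <- function(c_out) {
  list(par = list(gamma = rep(1, c_out), beta = numeric(c_out)),
       state = list(mean = numeric(c_out), var = rep(1, c_out)))
}

bn_fwd_ref <- function(x, par, state, training, eps = 1e-5, momentum = 0.1) {
  n <- nrow(x)
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = n)
    v <- colSums(xc * xc) / n
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * rep(istd, each = n)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    istd <- 1 / sqrt(state$var + eps)
    xhat <- (x - rep(state$mean, each = n)) * rep(istd, each = n)
  }
  y <- xhat * rep(par$gamma, each = n) + rep(par$beta, each = n)
  list(out = y, xhat = xhat, istd = istd, state = state)
}

bn_bwd_ref <- function(dy, par, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(par$gamma, each = n)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- rep(cache$istd, each = n) *
    (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- ReLU / sigmoid ----

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bwd <- function(dy, cache) dy * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- 2x2 max pooling ----

pool_fwd <- function(x, g) {
  if (is.null(g$pool)) stop_cfg("spatial size %dx%d is not divisible by 2", g$h, g$w)
  a1 <- x[g$pool[[1]], , drop = FALSE]
  best <- a1
  arg <- matrix(1L, nrow(a1), ncol(a1))
  for (j in 2:4) {
    aj <- x[g$pool[[j]], , drop = FALSE]
    upd <- aj > best
    best[upd] <- aj[upd]
    arg[upd] <- j
  }
  list(out = best, arg = arg)
}

pool_bwd <- function(dy, cache, g) {
  dx <- matrix(0, g$n, ncol(dy))
  for (j in 1:4) dx[g$pool[[j]], ] <- dy * (cache$arg == j)
  dx
}

## ---- nearest-neighbour 2x upsampling ----

up_fwd <- function(x, g) x[g$up, , drop = FALSE]

up_bwd <- function(dy, g) rowsum(dy, g$up, reorder = TRUE)

## ---- softmax over channels ----

softmax_rows <- function(z) {
  m <- as.numeric(do.call(pmax, lapply(seq_len(ncol(z)), function(j) z[, j])))
  e <- exp(z - m)
  e / rowSums(e)
}

# given dL/dP and P, return dL/dZ for row-wise softmax
softmax_bwd <- function(dp, p) p * (dp - rowSums(dp * p))

## compiled fast paths (reference R implementations above are kept as
## oracles for the correctness tests)

conv3_fwd <- function(x, par, g) {
  list(out = conv3_fwd_cpp(x, par$W, par$b, g$h, g$w, g$b), x = x)
}

conv3_bwd <- function(dy, par, cache, g) {
  conv3_bwd_cpp(cache$x, dy, par$W, g$h, g$w, g$b)
}

bn_fwd <- function(x, par, state, training, eps = 1e-5, momentum = 0.1) {
  r <- bn_fwd_cpp(x, par$gamma, par$beta, state$mean, state$var,
                  training, eps, momentum)
  list(out = r$out, xhat = r$xhat, istd = r$istd,
       state = list(mean = as.numeric(r$mean), var = as.numeric(r$var)))
}

bn_bwd <- function(dy, par, cache) {
  r <- bn_bwd_cpp(dy, par$gamma, cache$xhat, cache$istd)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}
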