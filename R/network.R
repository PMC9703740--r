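# Attention-gated encoder-decoder segmentation network.
#
# Encoder: `depth` stages of two (3x3 conv -> batch norm -> ReLU) blocks
# followed by 2x2 max pooling; channels double at each stage.  A bottleneck
# doubles channels once more.  Decoder: nearest-neighbour 2x upsampling, a
# 3x3 conv block halving channels, a skip-connection merge (attention gate on
# the deepest levels, 1x1 conv adapter on the shallowest), concatenation and
# two further conv blocks.  A final 1x1 convolution and per-pixel softmax
# yield 4-class probabilities (background, LV cavity, LV myocardium, RV
# cavity).

#' Architecture hyperparameters for the segmentation network
#'
#' @param depth number of down-sampling stages (default 4). Skip levels are
#'   numbered 1 (full resolution, "top") to `depth` ("bottom").
#' @param base_channels channels at the first stage; doubled at every stage.
#' @param n_classes number of output classes (4: background, LV cavity,
#'   LV myocardium, RV cavity).
#' @param ag_levels skip levels carrying attention gates; default the two
#'   deepest levels. May be `integer(0)` to disable all gates (the 1x1-conv
#'   ablation variant).
#' @param conv_skip_levels skip levels carrying 1x1 convolution adapters;
#'   default all remaining levels. Together with `ag_levels` this must
#'   partition `1:depth`.
#' @param ag_intermediate_channels channel width of the gate's internal
#'   projection; default half the skip channels at each gated level.
#' @return an object of class `unet_spec`.
#' @export
model_spec <- function(depth = 4, base_channels = 32, n_classes = 4,
                       ag_levels = NULL, conv_skip_levels = NULL,
                       ag_intermediate_channels = NULL) {
  if (depth < 2) stop_cfg("depth must be at least 2")
  if (is.null(ag_levels)) ag_levels <- c(depth - 1L, depth)
  ag_levels <- as.integer(ag_levels)
  if (is.null(conv_skip_levels)) conv_skip_levels <- setdiff(seq_len(depth), ag_levels)
  conv_skip_levels <- as.integer(conv_skip_levels)
  lev <- sort(c(ag_levels, conv_skip_levels))
  if (!identical(lev, seq_len(depth)) || anyDuplicated(c(ag_levels, conv_skip_levels)))
    stop_cfg("ag_levels and conv_skip_levels must partition 1:depth exactly")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 ag_levels = ag_levels,
                 conv_skip_levels = conv_skip_levels,
                 ag_intermediate_channels = ag_intermediate_channels),
            class = "unet_spec")
}

stage_channels <- function(spec) spec$base_channels * 2L^(seq_len(spec$depth) - 1L)

pn <- function(name, field) paste0(name, ".", field)

add_conv_block <- function(store, name, c_in, c_out) {
  cv <- conv3_init(c_in, c_out)
  bn <- bn_init(c_out)
  store$params[[pn(name, "W")]] <- cv$W
  store$params[[pn(name, "b")]] <- cv$b
  store$params[[pn(name, "gamma")]] <- bn$par$gamma
  store$params[[pn(name, "beta")]] <- bn$par$beta
  store$state[[name]] <- bn$state
  store
}

add_conv1 <- function(store, name, c_in, c_out, with_bn = FALSE,
                      rng_sd = NULL) {
  cv <- conv1_init(c_in, c_out, rng_sd)
  store$params[[pn(name, "W")]] <- cv$W
  store$params[[pn(name, "b")]] <- cv$b
  if (with_bn) {
    bn <- bn_init(c_out)
    store$params[[pn(name, "gamma")]] <- bn$par$gamma
    store$params[[pn(name, "beta")]] <- bn$par$beta
    store$state[[name]] <- bn$state
  }
  store
}

#' Build a segmentation model with freshly initialized weights
#'
#' Weights are drawn from a zero-mean normal distribution scaled by fan-in
#' (He initialization); identical seeds give identical parameters.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for weight initialization.
#' @param in_channels input channels (1 for grayscale cine frames).
#' @return an object of class `unet_model`.
#' @export
build_model <- function(spec = model_spec(), seed = 1L, in_channels = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  ch <- stage_channels(spec)
  d <- spec$depth
  st <- list(params = list(), state = list())
  c_prev <- in_channels
  for (s in seq_len(d)) {
    st <- add_conv_block(st, sprintf("enc%da", s), c_prev, ch[s])
    st <- add_conv_block(st, sprintf("enc%db", s), ch[s], ch[s])
    c_prev <- ch[s]
  }
  cb <- ch[d] * 2L
  st <- add_conv_block(st, "botta", ch[d], cb)
  st <- add_conv_block(st, "bottb", cb, cb)
  for (s in rev(seq_len(d))) {
    c_s <- ch[s]
    st <- add_conv_block(st, sprintf("up%d", s), 2L * c_s, c_s)
    if (s %in% spec$ag_levels) {
      f_int <- spec$ag_intermediate_channels %||% max(1L, c_s %/% 2L)
      st <- add_conv1(st, sprintf("ag%d_theta", s), c_s, f_int)
      st <- add_conv1(st, sprintf("ag%d_phi", s), 2L * c_s, f_int)
      st <- add_conv1(st, sprintf("ag%d_psi", s), f_int, 1L)
    } else {
      st <- add_conv1(st, sprintf("skip%d", s), c_s, c_s, with_bn = TRUE)
    }
    st <- add_conv_block(st, sprintf("dec%da", s), 2L * c_s, c_s)
    st <- add_conv_block(st, sprintf("dec%db", s), c_s, c_s)
  }
  # classifier head at small scale: initial class probabilities start near
  # uniform, so early gradients (not the random head) assign classes --
  # guards against initialization-dependent basins where a structure
  # "captures" the image periphery
  st <- add_conv1(st, "out", ch[1], spec$n_classes,
                  rng_sd = 0.3 * sqrt(2 / ch[1]))
  structure(list(spec = spec, params = st$params, state = st$state,
                 in_channels = as.integer(in_channels), seed = seed,
                 geom = new_geom_cache()),
            class = "unet_model")
}

# Forward pass over a batch matrix x (B*H*W rows, in_channels cols).
# Returns logits/probabilities plus caches for backprop and (in training
# mode) updated batch-norm running statistics.
unet_forward <- function(model, x, h, w, b, training = FALSE) {
  spec <- model$spec
  if (h %% 2L^spec$depth != 0L || w %% 2L^spec$depth != 0L)
    stop_cfg("input size %dx%d not divisible by 2^depth = %d", h, w, 2L^spec$depth)
  P <- model$params
  S <- model$state
  if (is.null(model$geom)) model$geom <- new_geom_cache()
  gc_ <- model$geom
  caches <- list()

  block_fwd <- function(x, name, g) {
    cv <- conv3_fwd(x, list(W = P[[pn(name, "W")]], b = P[[pn(name, "b")]]), g)
    st <- S[[name]]
    bn <- bn_relu_fwd_cpp(cv$out, P[[pn(name, "gamma")]], P[[pn(name, "beta")]],
                          st$mean, st$var, training, 1e-5, 0.1)
    S[[name]] <<- list(mean = as.numeric(bn$mean), var = as.numeric(bn$var))
    caches[[name]] <<- list(conv = cv, bn = bn)
    bn$out
  }

  d <- spec$depth
  ch <- stage_channels(spec)
  gs <- lapply(0:d, function(k) tensor_geometry(gc_, h %/% 2L^k, w %/% 2L^k, b))
  skips <- vector("list", d)
  cur <- x
  for (s in seq_len(d)) {
    cur <- block_fwd(cur, sprintf("enc%da", s), gs[[s]])
    cur <- block_fwd(cur, sprintf("enc%db", s), gs[[s]])
    skips[[s]] <- cur
    pl <- pool_fwd_cpp(cur, gs[[s]]$h, gs[[s]]$w, b)
    caches[[sprintf("pool%d", s)]] <- pl
    cur <- pl$out
  }
  cur <- block_fwd(cur, "botta", gs[[d + 1L]])
  cur <- block_fwd(cur, "bottb", gs[[d + 1L]])

  for (s in rev(seq_len(d))) {
    gating <- cur                      # coarse features, resolution of level s+1
    gsl <- gs[[s + 1L]]
    u <- up_fwd_cpp(gating, gsl$h, gsl$w, b)  # back to level-s resolution
    uc <- block_fwd(u, sprintf("up%d", s), gs[[s]])
    if (s %in% spec$ag_levels) {
      th <- conv1_fwd(skips[[s]], list(W = P[[pn(sprintf("ag%d_theta", s), "W")]],
                                       b = P[[pn(sprintf("ag%d_theta", s), "b")]]))
      ph <- conv1_fwd(gating, list(W = P[[pn(sprintf("ag%d_phi", s), "W")]],
                                   b = P[[pn(sprintf("ag%d_phi", s), "b")]]))
      ph_up <- up_fwd_cpp(ph$out, gsl$h, gsl$w, b)
      q <- relu_fwd(th$out + ph_up)
      ps <- conv1_fwd(q$out, list(W = P[[pn(sprintf("ag%d_psi", s), "W")]],
                                  b = P[[pn(sprintf("ag%d_psi", s), "b")]]))
      alpha <- sigmoid(ps$out)
      sk <- skips[[s]] * alpha[, 1L]
      caches[[sprintf("ag%d", s)]] <- list(theta = th, phi = ph, q = q, psi = ps,
                                           alpha = alpha, skip = skips[[s]])
    } else {
      nm <- sprintf("skip%d", s)
      a1 <- conv1_fwd(skips[[s]], list(W = P[[pn(nm, "W")]], b = P[[pn(nm, "b")]]))
      bn <- bn_fwd(a1$out, list(gamma = P[[pn(nm, "gamma")]], beta = P[[pn(nm, "beta")]]),
                   S[[nm]], training)
      S[[nm]] <- bn$state
      rl <- relu_fwd(bn$out)
      sk <- rl$out
      caches[[nm]] <- list(conv = a1, bn = bn, relu = rl)
    }
    cat_in <- cbind(sk, uc)
    cur <- block_fwd(cat_in, sprintf("dec%da", s), gs[[s]])
    cur <- block_fwd(cur, sprintf("dec%db", s), gs[[s]])
  }
  outc <- conv1_fwd(cur, list(W = P[[pn("out", "W")]], b = P[[pn("out", "b")]]))
  probs <- softmax_rows(outc$out)
  caches[["out"]] <- outc
  list(logits = outc$out, probs = probs, caches = caches, state = S,
       geoms = gs, h = h, w = w, b = b)
}

# Backward pass from dL/dlogits; returns gradients named like model$params.
unet_backward <- function(model, fwd, dlogits) {
  spec <- model$spec
  P <- model$params
  caches <- fwd$caches
  gs <- fwd$geoms
  G <- list()

  block_bwd <- function(dy, name, g) {
    cc <- caches[[name]]
    bb <- bn_relu_bwd_cpp(dy, cc$bn$out, P[[pn(name, "gamma")]],
                          cc$bn$xhat, cc$bn$istd)
    G[[pn(name, "gamma")]] <<- as.numeric(bb$dgamma)
    G[[pn(name, "beta")]] <<- as.numeric(bb$dbeta)
    cb <- conv3_bwd(bb$dx, list(W = P[[pn(name, "W")]]), cc$conv, g)
    G[[pn(name, "W")]] <<- cb$dW
    G[[pn(name, "b")]] <<- as.numeric(cb$db)
    cb$dx
  }

  d <- spec$depth
  ch <- stage_channels(spec)
  ob <- conv1_bwd(dlogits, list(W = P[[pn("out", "W")]]), caches[["out"]])
  G[[pn("out", "W")]] <- ob$dW
  G[[pn("out", "b")]] <- ob$db
  cur <- ob$dx
  dskips <- vector("list", d)

  for (s in seq_len(d)) {  # decoder stages, shallow -> deep
    cur <- block_bwd(cur, sprintf("dec%db", s), gs[[s]])
    cur <- block_bwd(cur, sprintf("dec%da", s), gs[[s]])
    c_s <- ch[s]
    dsk <- cur[, seq_len(c_s), drop = FALSE]
    duc <- cur[, c_s + seq_len(c_s), drop = FALSE]
    dgating <- NULL
    if (s %in% spec$ag_levels) {
      ag <- caches[[sprintf("ag%d", s)]]
      dskip_direct <- dsk * ag$alpha[, 1L]
      dalpha <- rowSums(dsk * ag$skip)
      dpsi_in <- dalpha * ag$alpha[, 1L] * (1 - ag$alpha[, 1L])
      pb <- conv1_bwd(matrix(dpsi_in, ncol = 1L),
                      list(W = P[[pn(sprintf("ag%d_psi", s), "W")]]), ag$psi)
      G[[pn(sprintf("ag%d_psi", s), "W")]] <- pb$dW
      G[[pn(sprintf("ag%d_psi", s), "b")]] <- pb$db
      dq <- relu_bwd(pb$dx, ag$q)
      tb <- conv1_bwd(dq, list(W = P[[pn(sprintf("ag%d_theta", s), "W")]]), ag$theta)
      G[[pn(sprintf("ag%d_theta", s), "W")]] <- tb$dW
      G[[pn(sprintf("ag%d_theta", s), "b")]] <- tb$db
      dph_up <- up_bwd_cpp(dq, gs[[s + 1L]]$h, gs[[s + 1L]]$w, fwd$b)
      fb <- conv1_bwd(dph_up, list(W = P[[pn(sprintf("ag%d_phi", s), "W")]]), ag$phi)
      G[[pn(sprintf("ag%d_phi", s), "W")]] <- fb$dW
      G[[pn(sprintf("ag%d_phi", s), "b")]] <- fb$db
      dskips[[s]] <- dskip_direct + tb$dx
      dgating <- fb$dx
    } else {
      nm <- sprintf("skip%d", s)
      cc <- caches[[nm]]
      bb <- bn_relu_bwd_cpp(dsk, cc$bn$out, P[[pn(nm, "gamma")]],
                            cc$bn$xhat, cc$bn$istd)
      G[[pn(nm, "gamma")]] <- as.numeric(bb$dgamma)
      G[[pn(nm, "beta")]] <- as.numeric(bb$dbeta)
      ab <- conv1_bwd(bb$dx, list(W = P[[pn(nm, "W")]]), cc$conv)
      G[[pn(nm, "W")]] <- ab$dW
      G[[pn(nm, "b")]] <- ab$db
      dskips[[s]] <- ab$dx
    }
    du <- block_bwd(duc, sprintf("up%d", s), gs[[s]])
    dg <- up_bwd_cpp(du, gs[[s + 1L]]$h, gs[[s + 1L]]$w, fwd$b)
    cur <- if (is.null(dgating)) dg else dg + dgating
  }

  cur <- block_bwd(cur, "bottb", gs[[d + 1L]])
  cur <- block_bwd(cur, "botta", gs[[d + 1L]])
  for (s in rev(seq_len(d))) {  # encoder stages, deep -> shallow
    dx <- pool_bwd_cpp(cur, caches[[sprintf("pool%d", s)]]$arg,
                       gs[[s]]$h, gs[[s]]$w, fwd$b)
    dx <- dx + dskips[[s]]
    dx <- block_bwd(dx, sprintf("enc%db", s), gs[[s]])
    cur <- block_bwd(dx, sprintf("enc%da", s), gs[[s]])
  }
  G
}

#' Segment a preprocessed frame
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns per-pixel class probabilities together with the argmax label map.
#' Ties in the argmax are broken toward the lowest class index.
#'
#' @param object a `unet_model`.
#' @param image a square numeric matrix with values in \[0, 1\], or a 3D
#'   array (rows x cols x slices) treated as a batch of frames.
#' @param ... unused.
#' @return for a single frame, a list with `prob` (rows x cols x n_classes
#'   array) and `labels` (integer matrix, values 0..n_classes-1); for a 3D
#'   input, a list with `prob` (4D array) and `labels` (3D array).
#' @export
predict.unet_model <- function(object, image, ...) {
  dims <- dim(image)
  single <- length(dims) == 2L
  if (single) image <- array(image, c(dims, 1L))
  h <- dim(image)[1]; w <- dim(image)[2]; b <- dim(image)[3]
  x <- matrix(aperm(image, c(1, 2, 3)), h * w * b, 1L)
  fwd <- unet_forward(object, x, h, w, b, training = FALSE)
  nc <- object$spec$n_classes
  lab <- max.col(fwd$probs, ties.method = "first") - 1L
  prob <- array(fwd$probs, c(h, w, b, nc))
  labels <- array(lab, c(h, w, b))
  if (single) {
    list(prob = array(aperm(prob, c(1, 2, 4, 3))[, , , 1], c(h, w, nc)),
         labels = labels[, , 1])
  } else {
    list(prob = prob, labels = labels)
  }
}

#' Apply an additive spatial attention gate to skip features
#'
#' Projects the skip features and a coarser gating signal to a common
#' intermediate width with 1x1 convolutions, adds them (the gating signal is
#' upsampled to the skip resolution), applies ReLU, projects to a single
#' channel, and squashes with a sigmoid to obtain per-pixel attention
#' coefficients in \[0, 1\] that multiply the skip features.
#'
#' @param skip skip features, array (h x w x c).
#' @param gating gating features at half resolution, array (h/2 x w/2 x cg).
#' @param intermediate_channels width of the internal projection.
#' @param par optional parameter list (`theta`, `phi`, `psi`, each with `W`,
#'   `b`) to use instead of random initialization — useful for probing the
#'   gate in isolation.
#' @param seed seed for random initialization when `par` is absent.
#' @return list with `out` (gated skip features, h x w x c) and `alpha`
#'   (attention map, h x w matrix).
#' @export
attention_gate <- function(skip, gating, intermediate_channels,
                           par = NULL, seed = 1L) {
  stopifnot(length(dim(skip)) == 3L, length(dim(gating)) == 3L)
  h <- dim(skip)[1]; w <- dim(skip)[2]; c_s <- dim(skip)[3]
  hg <- dim(gating)[1]; wg <- dim(gating)[2]; c_g <- dim(gating)[3]
  if (!(hg * 2L == h && wg * 2L == w) && !(hg == h && wg == w))
    stop_cfg("gating resolution must be half (or equal to) the skip resolution")
  if (is.null(par)) {
    set.seed(seed)
    par <- list(theta = conv1_init(c_s, intermediate_channels),
                phi = conv1_init(c_g, intermediate_channels),
                psi = conv1_init(intermediate_channels, 1L))
  }
  gc_ <- new_geom_cache()
  skm <- matrix(skip, h * w, c_s)
  gm <- matrix(gating, hg * wg, c_g)
  th <- conv1_fwd(skm, par$theta)$out
  ph <- conv1_fwd(gm, par$phi)$out
  if (hg != h) ph <- up_fwd(ph, tensor_geometry(gc_, hg, wg, 1L))
  q <- relu_fwd(th + ph)$out
  alpha <- sigmoid(conv1_fwd(q, par$psi)$out)[, 1L]
  list(out = array(skm * alpha, c(h, w, c_s)),
       alpha = matrix(alpha, h, w))
}
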