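#' @keywords internal
"_PACKAGE"

#' @useDynLib cardunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median sd quantile predict
#' @importFrom utils write.csv read.csv
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a reproducible child seed from a master seed
#'
#' All pipeline stages draw their seeds from a single master seed so that a
#' whole run is a pure function of its configuration.  Kept below 2^31 so the
#' result is always a valid R integer.
#'
#' @param seed master seed (integer).
#' @param stage stage index or offset (integer).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + as.double(stage) * 104729) %% 2147483629)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

# quintic smoothstep on [0, 1]; 0 below, 1 above
smootherstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * t * (t * (t * 6 - 15) + 10)
}

# bilinear sampling of a 2D matrix at fractional (row, col) positions,
# edge-clamped; used by resizing, rotation and the artifact warp
bilinear_sample <- function(img, ry, rx) {
  h <- nrow(img); w <- ncol(img)
  ry <- pmin(pmax(ry, 1), h); rx <- pmin(pmax(rx, 1), w)
  y0 <- floor(ry); x0 <- floor(rx)
  y0 <- pmin(y0, h - 1L); x0 <- pmin(x0, w - 1L)
  wy <- ry - y0; wx <- rx - x0
  i00 <- y0 + (x0 - 1) * h
  v00 <- img[i00]; v10 <- img[i00 + 1]
  v01 <- img[i00 + h]; v11 <- img[i00 + h + 1]
  (1 - wy) * (1 - wx) * v00 + wy * (1 - wx) * v10 +
    (1 - wy) * wx * v01 + wy * wx * v11
}

# nearest-neighbour sampling with a fill value outside the grid
nearest_sample <- function(img, ry, rx, fill = 0L) {
  h <- nrow(img); w <- ncol(img)
  yi <- round(ry); xi <- round(rx)
  ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
  out <- rep(fill, length(ry))
  out[ok] <- img[cbind(yi[ok], xi[ok])]
  out
}
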