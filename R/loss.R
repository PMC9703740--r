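# Combined training objective: weighted cross-entropy + Focal Tversky.
#
# The cross-entropy term handles the heavy class imbalance of cardiac
# short-axis frames (background dominates); the Focal Tversky term weights
# false negatives more than false positives (alpha > beta) and focuses the
# gradient on poorly segmented structures via its focal exponent.

#' Configuration of the combined segmentation loss
#'
#' @param class_weights per-class positive weights for the cross-entropy
#'   term (length `n_classes`); default unit weights. In training these are
#'   typically set to inverse median frequency over the training split, see
#'   [median_frequency_weights()].
#' @param alpha Tversky false-negative weight (default 0.7).
#' @param beta Tversky false-positive weight (default 0.3); `alpha + beta`
#'   must equal 1.
#' @param gamma_ft focal exponent gamma (default 4/3); each class
#'   contributes `(1 - TI)^(1/gamma_ft)`.
#' @param lambda_ce,lambda_ft combination weights of the two terms.
#' @param smooth numerical stabilizer added to the Tversky numerator and
#'   denominator.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(class_weights = NULL, alpha = 0.7, beta = 0.3,
                        gamma_ft = 4 / 3, lambda_ce = 1, lambda_ft = 1,
                        smooth = 1e-6) {
  if (abs(alpha + beta - 1) > 1e-12) stop_cfg("alpha + beta must equal 1")
  if (gamma_ft < 1) stop_cfg("gamma_ft must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0))
    stop_cfg("class weights must be positive")
  structure(list(class_weights = class_weights, alpha = alpha, beta = beta,
                 gamma_ft = gamma_ft, lambda_ce = lambda_ce,
                 lambda_ft = lambda_ft, smooth = smooth),
            class = "loss_config")
}

as_prob_matrix <- function(probs) {
  if (is.matrix(probs)) return(probs)
  d <- dim(probs)
  if (length(d) == 3L) return(matrix(probs, d[1] * d[2], d[3]))
  stop_cfg("probabilities must be an N x C matrix or an h x w x C array")
}

as_label_vector <- function(target, n_classes) {
  y <- as.integer(target)
  bad <- setdiff(unique(y), 0:(n_classes - 1L))
  if (length(bad))
    stop_cfg("target contains invalid label value(s): %s",
             paste(sort(bad), collapse = ", "))
  y
}

#' Weighted multi-class cross-entropy
#'
#' `-(1/N) * sum_i w[y_i] * log p_i[y_i]`, with probabilities clipped to
#' `[1e-7, 1]` before the logarithm.
#'
#' @param probs per-pixel class probabilities (N x C matrix or h x w x C
#'   array).
#' @param target integer labels in `0:(C-1)` (vector, matrix or array).
#' @param weights per-class positive weights; default 1 for every class.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, target, weights = NULL) {
  p <- as_prob_matrix(probs)
  nc <- ncol(p)
  y <- as_label_vector(target, nc)
  if (length(y) != nrow(p)) stop_cfg("probs and target sizes differ")
  w <- weights %||% rep(1, nc)
  py <- pmax(p[cbind(seq_len(nrow(p)), y + 1L)], 1e-7)
  mean(-w[y + 1L] * log(py))
}

# gradient of weighted_cross_entropy w.r.t. the probability matrix
wce_grad_probs <- function(p, y, weights) {
  n <- nrow(p)
  g <- matrix(0, n, ncol(p))
  idx <- cbind(seq_len(n), y + 1L)
  py <- pmax(p[idx], 1e-7)
  g[idx] <- -weights[y + 1L] / (py * n)
  g
}

#' Focal Tversky loss
#'
#' For each foreground class c the soft Tversky index
#' `TI_c = (TP_c + s) / (TP_c + alpha*FN_c + beta*FP_c + s)` is computed from
#' soft counts (sums of predicted probability over reference-positive and
#' reference-negative pixels) and the loss is
#' `sum_c (1 - TI_c)^(1/gamma_ft)`.  Zero for a perfect prediction, bounded
#' above by the number of foreground classes.
#'
#' @inheritParams weighted_cross_entropy
#' @param config a [loss_config()].
#' @param foreground_classes classes entering the sum (default all non-zero
#'   labels, i.e. the three cardiac structures).
#' @return scalar loss.
#' @export
focal_tversky <- function(probs, target, config = loss_config(),
                          foreground_classes = NULL) {
  p <- as_prob_matrix(probs)
  y <- as_label_vector(target, ncol(p))
  fg <- foreground_classes %||% seq_len(ncol(p) - 1L)
  s <- config$smooth
  loss <- 0
  for (cl in fg) {
    pc <- p[, cl + 1L]
    t <- as.numeric(y == cl)
    tp <- sum(pc * t)
    fn <- sum((1 - pc) * t)
    fp <- sum(pc * (1 - t))
    ti <- (tp + s) / (tp + config$alpha * fn + config$beta * fp + s)
    loss <- loss + (max(1 - ti, 0))^(1 / config$gamma_ft)
  }
  loss
}

ft_grad_probs <- function(p, y, config, foreground_classes = NULL) {
  fg <- foreground_classes %||% seq_len(ncol(p) - 1L)
  s <- config$smooth
  e <- 1 / config$gamma_ft
  g <- matrix(0, nrow(p), ncol(p))
  for (cl in fg) {
    pc <- p[, cl + 1L]
    t <- as.numeric(y == cl)
    tp <- sum(pc * t)
    fn <- sum((1 - pc) * t)
    fp <- sum(pc * (1 - t))
    nu <- tp + s
    de <- tp + config$alpha * fn + config$beta * fp + s
    ti <- nu / de
    # d(nu)/dp = t ; d(de)/dp = t*(1-alpha) + (1-t)*beta
    dti <- (t * de - nu * (t * (1 - config$alpha) + (1 - t) * config$beta)) / de^2
    dterm <- -e * max(1 - ti, 1e-12)^(e - 1) * dti
    g[, cl + 1L] <- g[, cl + 1L] + dterm
  }
  g
}

#' Combined segmentation loss
#'
#' `lambda_ce * weighted cross-entropy + lambda_ft * Focal Tversky`; zero
#' iff both terms are zero (perfect one-hot prediction).
#'
#' @inheritParams focal_tversky
#' @return scalar loss.
#' @export
combined_loss <- function(probs, target, config = loss_config()) {
  p <- as_prob_matrix(probs)
  w <- config$class_weights %||% rep(1, ncol(p))
  config$lambda_ce * weighted_cross_entropy(p, target, w) +
    config$lambda_ft * focal_tversky(p, target, config)
}

# gradient of combined_loss w.r.t. logits, via the softmax Jacobian
combined_loss_grad_logits <- function(probs, target, config) {
  p <- as_prob_matrix(probs)
  y <- as_label_vector(target, ncol(p))
  w <- config$class_weights %||% rep(1, ncol(p))
  dp <- config$lambda_ce * wce_grad_probs(p, y, w) +
    config$lambda_ft * ft_grad_probs(p, y, config)
  softmax_bwd(dp, p)
}

#' Inverse median-frequency class weights
#'
#' Weights each class by `median(freq) / freq_c`, computed over a set of
#' label masks, clips the raw weights to `[floor, ceiling]`, and normalizes
#' to mean 1.  Classes absent from the data receive the largest observed
#' weight.  The clipping keeps the dominant background class from becoming
#' effectively cost-free: with a raw inverse-frequency weight the
#' cross-entropy term can tolerate large false-positive regions over
#' background, a failure mode that shows up as a structure "bleeding" into
#' the background for some initializations.
#'
#' @param masks list of integer label arrays.
#' @param n_classes number of classes.
#' @param floor,ceiling clipping bounds for the raw weights.
#' @return numeric vector of length `n_classes`.
#' @export
median_frequency_weights <- function(masks, n_classes = 4L, floor = 0.25,
                                     ceiling = 4) {
  counts <- numeric(n_classes)
  total <- 0
  for (m in masks) {
    tb <- tabulate(as.integer(m) + 1L, nbins = n_classes)
    counts <- counts + tb
    total <- total + length(m)
  }
  freq <- counts / total
  present <- freq > 0
  w <- rep(NA_real_, n_classes)
  w[present] <- median(freq[present]) / freq[present]
  w[!present] <- max(w[present])
  w <- pmin(pmax(w, floor), ceiling)
  w / mean(w)
}
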