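# Small shared fixtures, generated in code.

tiny_phantom_config <- function(...) {
  phantom_config(n_slices = 6, image_size = 64, pixel_spacing = 2.0, ...)
}

# a cached tiny study so multiple tests don't regenerate it
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(tiny_phantom_config())
    cache
  }
})

# random label-mask pair on a small grid
random_mask_pair <- function(n = 16, n_classes = 2) {
  list(a = matrix(sample(0:(n_classes - 1), n * n, replace = TRUE), n),
       b = matrix(sample(0:(n_classes - 1), n * n, replace = TRUE), n))
}

# brute-force confusion counts by explicit pixel loop
brute_counts <- function(pred, ref, class_id) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == class_id
    r <- ref[i] == class_id
    if (p && r) tp <- tp + 1L
    else if (p && !r) fp <- fp + 1L
    else if (!p && r) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# brute-force 2D Hausdorff distance over 4-neighbour boundary pixels
brute_hausdorff <- function(pred, ref, class_id, spacing = 1) {
  bpts <- function(m) {
    out <- NULL
    h <- nrow(m); w <- ncol(m)
    for (y in seq_len(h)) for (x in seq_len(w)) {
      if (m[y, x] != class_id) next
      nb <- c(if (y > 1) m[y - 1, x] else -1L,
              if (y < h) m[y + 1, x] else -1L,
              if (x > 1) m[y, x - 1] else -1L,
              if (x < w) m[y, x + 1] else -1L)
      if (any(nb != class_id)) out <- rbind(out, c(y, x))
    }
    out
  }
  pa <- bpts(pred); pb <- bpts(ref)
  if (is.null(pa) || is.null(pb)) return(NA_real_)
  directed <- function(u, v)
    max(apply(u, 1, function(p) min(sqrt((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2))))
  max(directed(pa, pb), directed(pb, pa)) * spacing
}

# ICC(2,1) oracle from an explicit two-way ANOVA fit
aov_icc <- function(x, y) {
  n <- length(x)
  d <- data.frame(value = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}
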