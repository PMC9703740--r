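# Synthetic short-axis cine phantom.
#
# Per slice the left ventricle is modelled as an annulus (epicardial disc
# minus endocardial disc) and the right-ventricular cavity as a crescent (a
# disc offset toward the septum minus the LV epicardial disc), with radii
# tapering linearly from base to apex and no RV on the most apical slice.
# End-systole scales the endocardial radii by `contraction_fraction`, with
# the epicardial radius adjusted so myocardial cross-sectional area is
# conserved slice by slice.  Ground-truth masks are the exact analytic
# regions rasterized with the pixel-center rule.

#' Configuration of the cine phantom
#'
#' Defaults emulate a clinical short-axis acquisition: ~10 slices base to
#' apex, 8 mm slice thickness with no interslice gap, 1.2-2.0 mm in-plane
#' resolution, bright blood pool over intermediate-intensity myocardium.
#'
#' @param n_slices number of short-axis slices.
#' @param image_size square image size in pixels.
#' @param pixel_spacing in-plane resolution, mm/pixel.
#' @param slice_thickness slice thickness in mm.
#' @param epi_radius_base LV epicardial radius at the most basal slice, mm.
#' @param wall_thickness_ed end-diastolic myocardial wall thickness at the
#'   base, mm (must be smaller than `epi_radius_base`).
#' @param rv_offset distance from the LV centre to the RV disc centre at the
#'   base, mm (along the septal direction).
#' @param rv_radius_frac RV disc radius as a fraction of the epicardial
#'   radius.
#' @param apex_taper fractional radius reduction at the most apical slice
#'   (0.4 means apical radii are 60% of basal).
#' @param contraction_fraction factor in (0, 1) scaling endocardial radii
#'   from ED to ES; the analytic LV ejection fraction is
#'   `100 * (1 - contraction_fraction^2)`.
#' @param intensity_means named intensity levels in \[0, 1\] for
#'   `background`, `myocardium` and `blood`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (applied before clipping to \[0, 1\]).
#' @param artifact an [artifact_config()], or `NULL` for an artifact-free
#'   study.
#' @param seed integer seed; identical configurations give bit-identical
#'   studies.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 10L, image_size = 192L,
                           pixel_spacing = 1.5, slice_thickness = 8,
                           epi_radius_base = 30, wall_thickness_ed = 10,
                           rv_offset = 27, rv_radius_frac = 0.85,
                           apex_taper = 0.4, contraction_fraction = 0.65,
                           intensity_means = c(background = 0.1,
                                               myocardium = 0.45,
                                               blood = 0.9),
                           noise_sd = 0.03, artifact = NULL, seed = 1L) {
  if (epi_radius_base <= wall_thickness_ed || wall_thickness_ed <= 0)
    stop_cfg("need epi_radius_base > wall_thickness_ed > 0")
  if (contraction_fraction <= 0 || contraction_fraction > 1)
    stop_cfg("contraction_fraction must lie in (0, 1]")
  if (any(intensity_means < 0 | intensity_means > 1))
    stop_cfg("intensity means must lie in [0, 1]")
  if (n_slices < 2) stop_cfg("need at least 2 slices")
  structure(as.list(environment()), class = "phantom_config")
}

#' Configuration of a simulated susceptibility artifact
#'
#' Emulates the localized signal void, hyperintense rim and mild geometric
#' distortion produced by an implanted cardiac device, placed by default
#' over the septal segments where such artifacts are most pronounced.
#'
#' @param void_center_angle angular position of the void centre on the
#'   epicardial circle, degrees (180 = septal side, where the RV sits).
#' @param void_radius radius of the signal void, mm.
#' @param falloff_width width of the smooth transition at the void margin,
#'   mm.
#' @param rim_gain hyperintensity factor of the rim at the void margin
#'   (>= 1; 1 disables the rim).
#' @param distortion_amplitude maximum displacement of the geometric warp,
#'   pixels (0 disables the warp).
#' @param placement_jitter uniform jitter of the void centre, mm per axis.
#' @return an object of class `artifact_config`.
#' @export
artifact_config <- function(void_center_angle = 180, void_radius = 14,
                            falloff_width = 3, rim_gain = 1.5,
                            distortion_amplitude = 1, placement_jitter = 2) {
  if (void_radius <= 0) stop_cfg("void_radius must be positive")
  if (falloff_width <= 0) stop_cfg("falloff_width must be positive")
  if (rim_gain < 1) stop_cfg("rim_gain must be >= 1")
  structure(as.list(environment()), class = "artifact_config")
}

# per-slice analytic radii (mm); slice 1 = base, slice n = apex
phantom_radii <- function(config) {
  n <- config$n_slices
  u <- (seq_len(n) - 1) / (n - 1)
  scale <- 1 - config$apex_taper * u
  r_epi_ed <- config$epi_radius_base * scale
  r_endo_ed <- (config$epi_radius_base - config$wall_thickness_ed) * scale
  cf <- config$contraction_fraction
  r_endo_es <- cf * r_endo_ed
  r_epi_es <- sqrt(r_endo_es^2 + r_epi_ed^2 - r_endo_ed^2)  # conserve wall area
  r_rv_ed <- config$rv_radius_frac * r_epi_ed
  r_rv_es <- cf * r_rv_ed
  d_rv <- config$rv_offset * scale
  has_rv <- seq_len(n) < n  # no RV on the most apical slice
  list(r_epi_ed = r_epi_ed, r_endo_ed = r_endo_ed,
       r_epi_es = r_epi_es, r_endo_es = r_endo_es,
       r_rv_ed = r_rv_ed, r_rv_es = r_rv_es,
       d_rv = d_rv, has_rv = has_rv)
}

# pixel-center coordinate grids in mm, origin at the image centre
pixel_grid <- function(image_size, pixel_spacing) {
  ax <- (seq_len(image_size) - (image_size + 1) / 2) * pixel_spacing
  list(y = matrix(ax, image_size, image_size),
       x = matrix(ax, image_size, image_size, byrow = TRUE))
}

rasterize_slice <- function(grid, r_endo, r_epi, r_rv, d_rv, has_rv) {
  r2 <- grid$x^2 + grid$y^2
  lab <- matrix(0L, nrow(grid$x), ncol(grid$x))
  if (has_rv) {
    rv2 <- (grid$x + d_rv)^2 + grid$y^2  # RV centre on the septal (-x) side
    lab[rv2 <= r_rv^2 & r2 > r_epi^2] <- 3L
  }
  lab[r2 <= r_epi^2] <- 2L
  lab[r2 <= r_endo^2] <- 1L
  lab
}

#' Generate one synthetic cine study with ground truth
#'
#' @param config a [phantom_config()].
#' @return a list with `study` (class `cine_study`: `ed_stack`, `es_stack`,
#'   `pixel_spacing`, `slice_thickness`, `study_id`) and `gt` (class
#'   `ground_truth`: `ed_mask`, `es_mask` integer label stacks with labels
#'   0 = background, 1 = LV cavity, 2 = LV myocardium, 3 = RV cavity).
#' @export
generate_study <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  rad <- phantom_radii(config)
  half_fov <- config$image_size * config$pixel_spacing / 2
  if (min(rad$d_rv + rad$r_rv_ed) > 0 &&
      max(rad$d_rv + rad$r_rv_ed) >= half_fov)
    stop_cfg("RV extends beyond the field of view; reduce radii or increase image size")
  crescent_reach <- rad$d_rv + rad$r_rv_ed - rad$r_epi_ed
  if (any(rad$has_rv & crescent_reach <= 0))
    stop_cfg("RV crescent degenerates: rv_offset too small for the chosen radii")
  grid <- pixel_grid(config$image_size, config$pixel_spacing)
  n <- config$n_slices
  sz <- config$image_size
  ed_mask <- array(0L, c(sz, sz, n))
  es_mask <- array(0L, c(sz, sz, n))
  for (s in seq_len(n)) {
    ed_mask[, , s] <- rasterize_slice(grid, rad$r_endo_ed[s], rad$r_epi_ed[s],
                                      rad$r_rv_ed[s], rad$d_rv[s], rad$has_rv[s])
    # mirror the tracing convention of keeping myocardial mass as similar as
    # possible between phases: nudge the ES epicardial radius (within half a
    # pixel of its area-conserving analytic value) so the rasterized ES ring
    # best matches the ED ring pixel count on this slice
    ed_ring <- sum(ed_mask[, , s] == 2L)
    deltas <- sort(seq(-0.5, 0.5, by = 0.05) * config$pixel_spacing)
    deltas <- deltas[order(abs(deltas))]
    best <- NULL
    best_err <- Inf
    for (d in deltas) {
      cand <- rasterize_slice(grid, rad$r_endo_es[s], rad$r_epi_es[s] + d,
                              rad$r_rv_es[s], rad$d_rv[s], rad$has_rv[s])
      err <- abs(sum(cand == 2L) - ed_ring)
      if (err < best_err) {
        best <- cand
        best_err <- err
      }
    }
    es_mask[, , s] <- best
  }
  im <- config$intensity_means
  levels <- c(im[["background"]], im[["blood"]], im[["myocardium"]], im[["blood"]])
  set.seed(config$seed)
  render <- function(mask) {
    img <- array(levels[as.integer(mask) + 1L], dim(mask))
    clamp01(img + array(rnorm(length(img), sd = config$noise_sd), dim(mask)))
  }
  ed_stack <- render(ed_mask)
  es_stack <- render(es_mask)
  gt <- structure(list(ed_mask = ed_mask, es_mask = es_mask),
                  class = "ground_truth")
  if (!is.null(config$artifact)) {
    ed_stack <- simulate_artifact(ed_stack, gt, config$artifact,
                                  seed = derive_seed(config$seed, 1L),
                                  pixel_spacing = config$pixel_spacing)
    es_stack <- simulate_artifact(es_stack, gt, config$artifact,
                                  seed = derive_seed(config$seed, 2L),
                                  pixel_spacing = config$pixel_spacing)
  }
  study <- structure(list(ed_stack = ed_stack, es_stack = es_stack,
                          pixel_spacing = config$pixel_spacing,
                          slice_thickness = config$slice_thickness,
                          study_id = sprintf("phantom_%06d", config$seed)),
                     class = "cine_study")
  list(study = study, gt = gt)
}

#' Overlay a simulated susceptibility artifact on an image stack
#'
#' Multiplies intensities by a smooth signal-void profile (0 at the void
#' centre, 1 beyond the void radius), adds a hyperintense rim at the void
#' margin, and applies a small smooth geometric warp — to the intensities
#' only. Ground-truth masks are never modified: the artifact corrupts the
#' appearance, not the reference anatomy. Output is clipped to \[0, 1\].
#'
#' The void is centred on the epicardial border at `void_center_angle`
#' (default septal), located from the ground-truth masks of the
#' mid-ventricular slice, with uniform placement jitter.
#'
#' @param stack 3D intensity array in \[0, 1\] (slices as third dimension).
#' @param gt a `ground_truth` object matching the stack.
#' @param config an [artifact_config()].
#' @param seed integer seed for placement jitter.
#' @param pixel_spacing in-plane spacing in mm.
#' @return the corrupted stack, same shape, in \[0, 1\].
#' @export
simulate_artifact <- function(stack, gt, config = artifact_config(),
                              seed = 1L, pixel_spacing = 1.5) {
  stopifnot(inherits(config, "artifact_config"))
  dims <- dim(stack)
  sz <- dims[1]
  mid <- (dim(gt$ed_mask)[3] + 1L) %/% 2L
  grid <- pixel_grid(sz, pixel_spacing)
  lvm <- gt$ed_mask[, , mid] == 2L
  if (!any(lvm)) stop_cfg("ground truth has no myocardium on the mid slice")
  cx <- mean(grid$x[lvm]); cy <- mean(grid$y[lvm])
  r_epi <- max(sqrt((grid$x[lvm] - cx)^2 + (grid$y[lvm] - cy)^2))
  th <- config$void_center_angle * pi / 180
  set.seed(seed)
  jit <- runif(2, -config$placement_jitter, config$placement_jitter)
  vx <- cx + r_epi * cos(th) + jit[1]
  vy <- cy + r_epi * sin(th) + jit[2]
  half_fov <- sz * pixel_spacing / 2
  if (abs(vx) - config$void_radius > half_fov ||
      abs(vy) - config$void_radius > half_fov)
    stop_cfg("artifact void lies entirely outside the image")
  d <- sqrt((grid$x - vx)^2 + (grid$y - vy)^2)
  wv <- min(config$falloff_width, config$void_radius)
  void <- smootherstep((d - (config$void_radius - wv)) / wv)
  rim <- exp(-((d - (config$void_radius + wv / 2))^2) / (2 * (wv / 2)^2))
  mult <- void * (1 + (config$rim_gain - 1) * rim)
  amp <- config$distortion_amplitude
  out <- stack
  if (amp > 0) {
    sigma_w <- config$void_radius + wv
    g <- exp(-d^2 / (2 * sigma_w^2))
    ux <- (grid$x - vx) / pmax(d, 1e-9)
    uy <- (grid$y - vy) / pmax(d, 1e-9)
    # inverse warp: sample each output pixel from a pushed-in source location
    src_y <- matrix(rep(seq_len(sz), sz), sz) - amp * g * uy
    src_x <- matrix(rep(seq_len(sz), each = sz), sz) - amp * g * ux
    max_disp <- amp * max(g)
    for (s in seq_len(dims[3])) {
      v <- stack[, , s] * mult
      if (max_disp > 1e-9)
        v <- matrix(bilinear_sample(v, as.vector(src_y), as.vector(src_x)), sz)
      out[, , s] <- v
    }
  } else {
    for (s in seq_len(dims[3])) out[, , s] <- stack[, , s] * mult
  }
  clamp01(out)
}
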