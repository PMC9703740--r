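test_that("no contraction means identical ED and ES masks", {
  gen <- generate_study(tiny_phantom_config(contraction_fraction = 1, seed = 4))
  expect_identical(gen$gt$ed_mask, gen$gt$es_mask)
})

test_that("identical configuration gives bit-identical studies", {
  g1 <- generate_study(tiny_phantom_config(seed = 9))
  g2 <- generate_study(tiny_phantom_config(seed = 9))
  expect_identical(g1$study, g2$study)
  expect_identical(g1$gt, g2$gt)
})

test_that("rasterized LV cavity area matches the analytic disc area", {
  cfg <- tiny_phantom_config()
  gen <- generate_study(cfg)
  rad <- cardunet:::phantom_radii(cfg)
  mid <- 3L
  n_px <- sum(gen$gt$ed_mask[, , mid] == 1L)
  analytic <- pi * (rad$r_endo_ed[mid] / cfg$pixel_spacing)^2
  expect_lt(abs(n_px - analytic) / analytic, 0.03)
})

test_that("myocardial area is conserved from ED to ES", {
  cfs <- c(0.55, 0.62, 0.68, 0.75)
  for (seed in 1:4) {
    cfg <- tiny_phantom_config(seed = seed, contraction_fraction = cfs[seed])
    gen <- generate_study(cfg)
    ed <- sum(gen$gt$ed_mask == 2L)
    es <- sum(gen$gt$es_mask == 2L)
    expect_lt(abs(ed - es) / ed, 0.02)
  }
})

test_that("ground-truth LV ejection fraction matches the contraction closed form", {
  cfg <- tiny_phantom_config(contraction_fraction = 0.6)
  gen <- generate_study(cfg)
  edv <- structure_volume(gen$gt$ed_mask, 1L, cfg$pixel_spacing, cfg$slice_thickness)
  esv <- structure_volume(gen$gt$es_mask, 1L, cfg$pixel_spacing, cfg$slice_thickness)
  expect_lt(abs(ejection_fraction(edv, esv) - 100 * (1 - 0.6^2)), 3)
})

test_that("degenerate geometry is rejected", {
  expect_error(generate_study(tiny_phantom_config(rv_offset = 1)), "crescent")
  expect_error(phantom_config(epi_radius_base = 5, wall_thickness_ed = 10),
               "epi_radius_base")
  expect_error(phantom_config(contraction_fraction = 0), "contraction")
  expect_error(artifact_config(void_radius = -1), "void_radius")
  expect_error(artifact_config(rim_gain = 0.5), "rim_gain")
})

test_that("a vanishing void leaves the image untouched", {
  gen <- tiny_study()
  out <- simulate_artifact(gen$study$ed_stack, gen$gt,
                           artifact_config(void_radius = 1e-9),
                           seed = 5, pixel_spacing = 2.0)
  expect_lt(max(abs(out - gen$study$ed_stack)), 1e-12)
})

test_that("without rim and warp the artifact is exactly multiplicative", {
  gen <- tiny_study()
  cfg <- artifact_config(distortion_amplitude = 0, rim_gain = 1,
                         placement_jitter = 0)
  out <- simulate_artifact(gen$study$ed_stack, gen$gt, cfg,
                           seed = 5, pixel_spacing = 2.0)
  # recompute the void profile from the same placement rule
  grid <- cardunet:::pixel_grid(64, 2.0)
  mid <- 3L
  lvm <- gen$gt$ed_mask[, , mid] == 2L
  cx <- mean(grid$x[lvm]); cy <- mean(grid$y[lvm])
  r_epi <- max(sqrt((grid$x[lvm] - cx)^2 + (grid$y[lvm] - cy)^2))
  vx <- cx - r_epi; vy <- cy
  d <- sqrt((grid$x - vx)^2 + (grid$y - vy)^2)
  wv <- min(cfg$falloff_width, cfg$void_radius)
  prof <- cardunet:::smootherstep((d - (cfg$void_radius - wv)) / wv)
  for (s in 1:6)
    expect_equal(out[, , s], pmin(pmax(gen$study$ed_stack[, , s] * prof, 0), 1),
                 tolerance = 1e-12)
})

test_that("the septal void suppresses intensity inside the void disc", {
  gen <- tiny_study()
  cfg <- artifact_config(placement_jitter = 0)
  out <- simulate_artifact(gen$study$ed_stack, gen$gt, cfg,
                           seed = 5, pixel_spacing = 2.0)
  grid <- cardunet:::pixel_grid(64, 2.0)
  mid <- 3L
  lvm <- gen$gt$ed_mask[, , mid] == 2L
  cx <- mean(grid$x[lvm]); cy <- mean(grid$y[lvm])
  r_epi <- max(sqrt((grid$x[lvm] - cx)^2 + (grid$y[lvm] - cy)^2))
  d <- sqrt((grid$x - (cx - r_epi))^2 + (grid$y - cy)^2)
  inside <- d <= cfg$void_radius
  ratio <- mean(out[, , mid][inside]) / mean(gen$study$ed_stack[, , mid][inside])
  expect_lt(ratio, 0.25)
})

test_that("the artifact corrupts appearance but never the reference masks", {
  cfg <- tiny_phantom_config(artifact = artifact_config(), seed = 21)
  clean <- generate_study(tiny_phantom_config(seed = 21))
  corrupted <- generate_study(cfg)
  expect_identical(corrupted$gt, clean$gt)
  expect_false(identical(corrupted$study$ed_stack, clean$study$ed_stack))
  expect_true(all(corrupted$study$ed_stack >= 0 & corrupted$study$ed_stack <= 1))
})
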