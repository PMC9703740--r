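test_that("structure volume is voxel count times voxel size", {
  m <- array(0L, c(10, 10, 10))
  m[seq_len(1000)] <- 1L
  expect_equal(structure_volume(m, 1L, 1.0, 8), 8.0)
  expect_equal(structure_volume(m, 2L, 1.0, 8), 0)
  expect_error(structure_volume(m, 1L, NULL, 8), "spacing")
})

test_that("volumes are additive over disjoint label regions", {
  gen <- tiny_study()
  v <- vapply(0:3, function(cl)
    structure_volume(gen$gt$ed_mask, cl, 2, 8), 0)
  total <- length(gen$gt$ed_mask) * 4 * 8 / 1000
  expect_equal(sum(v), total)
})

test_that("ejection fraction follows its definition and rejects bad input", {
  expect_equal(ejection_fraction(100, 40), 60)
  expect_equal(ejection_fraction(80, 80), 0)
  expect_error(ejection_fraction(0, 10), "positive")
})

test_that("ejection fraction is invariant to uniform voxel-size changes", {
  gen <- tiny_study()
  ef1 <- ejection_fraction(structure_volume(gen$gt$ed_mask, 1L, 2, 8),
                           structure_volume(gen$gt$es_mask, 1L, 2, 8))
  ef2 <- ejection_fraction(structure_volume(gen$gt$ed_mask, 1L, 6, 8),
                           structure_volume(gen$gt$es_mask, 1L, 6, 8))
  expect_identical(ef1, ef2)
})

test_that("myocardial mass uses the 1.05 g/mL density convention", {
  expect_equal(myocardial_mass(100), 105)
  expect_equal(myocardial_mass(0), 0)
  gen <- tiny_study()
  m_ed <- myocardial_mass(structure_volume(gen$gt$ed_mask, 2L, 2, 8))
  m_es <- myocardial_mass(structure_volume(gen$gt$es_mask, 2L, 2, 8))
  expect_lt(abs(m_ed - m_es) / m_ed, 0.02)
})

test_that("clinical parameters assemble into the per-study table", {
  gen <- tiny_study()
  tbl <- clinical_parameters(gen$gt$ed_mask, gen$gt$es_mask, 2, 8, "s1")
  expect_equal(tbl$lvedv_ml, structure_volume(gen$gt$ed_mask, 1L, 2, 8))
  expect_equal(tbl$lvef_pct,
               ejection_fraction(tbl$lvedv_ml, tbl$lvesv_ml))
  expect_gt(tbl$rvef_pct, 0)
})

test_that("ICC(2,1) matches a two-way ANOVA oracle on a fixed 6-pair fixture", {
  x <- c(10, 12, 14, 16, 18, 20)
  y <- c(11, 12.5, 13.5, 16.5, 17.5, 21)
  expect_equal(icc(x, y), aov_icc(x, y), tolerance = 1e-9)
  expect_equal(icc(x, x), 1)
  # absolute agreement penalizes a constant offset
  expect_lt(icc(x, x + 2), 1)
  expect_lt(icc(x, x + 2), icc(x, x + 1e-9))
  expect_error(icc(c(1, 2), c(1, 2)), "3")
  expect_warning(icc(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("ICC converges to 1 as the measurement noise vanishes", {
  set.seed(6)
  x <- runif(40, 50, 150)
  y <- x + rnorm(40, sd = 1e-6)
  expect_gt(icc(x, y), 0.999999)
})

test_that("Bland-Altman limits follow the 1.96 sd convention", {
  x <- c(1, 2, 3); y <- x
  ba <- bland_altman(x, y)
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))
  ba <- bland_altman(c(1, 2), c(0, 3))   # d = {+1, -1}
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10)
    bb <- bland_altman(a, b)
    expect_true(bb$loa_low <= bb$bias && bb$bias <= bb$loa_high)
  }
})

test_that("the agreement report flags reproducible parameters", {
  set.seed(8)
  auto <- tibble::tibble(study_id = sprintf("s%d", 1:8),
                         lvef_pct = runif(8, 40, 70),
                         lvm_ed_g = runif(8, 80, 160))
  ref <- auto
  rep1 <- agreement_report(auto, ref)
  expect_true(all(rep1$icc == 1))
  expect_true(all(rep1$reproducible))
  expect_true(all(rep1$bias == 0))
  # a single discordant parameter only changes its own row
  ref2 <- ref
  ref2$lvm_ed_g <- rev(ref2$lvm_ed_g)
  rep2 <- agreement_report(auto, ref2)
  expect_equal(rep2[rep2$parameter == "lvef_pct", ]$icc, 1)
  expect_lt(rep2[rep2$parameter == "lvm_ed_g", ]$icc, 1)
  # compositional: report equals per-parameter calls
  expect_equal(rep2[rep2$parameter == "lvm_ed_g", ]$icc,
               icc(auto$lvm_ed_g, ref2$lvm_ed_g))
  ba <- bland_altman(auto$lvm_ed_g, ref2$lvm_ed_g)
  expect_equal(rep2[rep2$parameter == "lvm_ed_g", ]$bias, ba$bias)
  expect_error(agreement_report(auto, ref[1:5, ]), "unmatched")
})

test_that("agreement reports provide tidy, glance and autoplot methods", {
  auto <- tibble::tibble(study_id = sprintf("s%d", 1:6),
                         lvef_pct = c(50, 55, 60, 65, 70, 45))
  ref <- tibble::tibble(study_id = sprintf("s%d", 1:6),
                        lvef_pct = c(51, 54, 61, 64, 72, 44))
  rep <- agreement_report(auto, ref)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_named(glance(rep), c("n_parameters", "n_reproducible", "min_icc"))
  expect_s3_class(autoplot(rep), "ggplot")
})
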