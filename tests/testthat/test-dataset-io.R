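test_that("group-wise split fractions give the documented counts", {
  td <- withr::local_tempdir()
  man <- generate_dataset(20, 20, td, seed = 3,
                          base_config = tiny_phantom_config())
  expect_equal(nrow(man), 80)  # 40 studies x 2 phases
  per_study <- unique(man[, c("study_id", "group", "split")])
  expect_equal(nrow(per_study), 40)
  counts <- table(per_study$split)
  expect_equal(as.integer(counts[c("train", "val", "test")]), c(28L, 5L, 7L))
  g1 <- table(per_study$split[per_study$group == 1])
  expect_equal(as.integer(g1[c("train", "val", "test")]), c(14L, 3L, 3L))
  g2 <- table(per_study$split[per_study$group == 2])
  expect_equal(as.integer(g2[c("train", "val", "test")]), c(14L, 2L, 4L))
})

test_that("a cohort without artifacts is all group 2", {
  td <- withr::local_tempdir()
  man <- generate_dataset(0, 4, td, seed = 3,
                          base_config = tiny_phantom_config())
  expect_true(all(man$group == 2L))
})

test_that("dataset generation is reproducible file by file", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  m1 <- generate_dataset(2, 2, td1, seed = 8, base_config = tiny_phantom_config())
  m2 <- generate_dataset(2, 2, td2, seed = 8, base_config = tiny_phantom_config())
  expect_equal(m1[setdiff(names(m1), c("image_path", "mask_path"))],
               m2[setdiff(names(m2), c("image_path", "mask_path"))])
  for (i in seq_len(nrow(m1))) {
    a <- load_study(m1$image_path[i], m1$mask_path[i])
    b <- load_study(m2$image_path[i], m2$mask_path[i])
    expect_identical(a, b)
  }
})

test_that("NIfTI stacks round-trip bit-exactly with spacing metadata", {
  gen <- tiny_study()
  td <- withr::local_tempdir()
  ip <- file.path(td, "img.nii.gz"); mp <- file.path(td, "msk.nii.gz")
  write_nifti_stack(gen$study$ed_stack, ip, 2.0, 8)
  write_nifti_stack(gen$gt$ed_mask, mp, 2.0, 8, mask = TRUE)
  ld <- load_study(ip, mp)
  expect_equal(ld$pixel_spacing, 2.0)
  expect_equal(ld$slice_thickness, 8)
  expect_identical(ld$mask, gen$gt$ed_mask)
  # image written as float32: round-trips to float precision
  expect_lt(max(abs(ld$image - gen$study$ed_stack)), 1e-6)
})

test_that("invalid masks and missing spacing are rejected with clear errors", {
  td <- withr::local_tempdir()
  gen <- tiny_study()
  ip <- file.path(td, "img.nii.gz")
  write_nifti_stack(gen$study$ed_stack, ip, 2.0, 8)
  bad <- gen$gt$ed_mask
  bad[1, 1, 1] <- 4L
  bp <- file.path(td, "bad.nii.gz")
  write_nifti_stack(bad, bp, 2.0, 8, mask = TRUE)
  expect_error(load_study(ip, bp), "4")
  expect_error(cardunet:::check_spacing(c(0, 0, 0), "x.nii"), "spacing")
  expect_error(cardunet:::check_spacing(c(1, 2, 8), "x.nii"), "anisotropic")
  expect_error(load_study(file.path(td, "absent.nii.gz")), "not found")
})

test_that("preprocessing crops, resizes and normalizes to [0, 1]", {
  x <- matrix(runif(192 * 192), 192)
  x[1] <- 0; x[2] <- 1
  expect_lt(max(abs(preprocess(x, 192) - x)), 1e-6)       # conforming input
  expect_true(all(preprocess(matrix(5, 64, 64), 64) == 0))  # constant frame
  expect_error(preprocess(matrix(0, 4, 4)), "8x8")
  y <- preprocess(matrix(runif(100 * 80), 100, 80), 64)
  expect_equal(dim(y), c(64L, 64L))
  expect_gte(min(y), 0); expect_equal(max(y), 1)
  # idempotence once conforming
  expect_lt(max(abs(preprocess(y, 64) - y)), 1e-6)
})

test_that("resizing scales structures by the expected factor", {
  img <- matrix(0, 256, 256)
  ax <- seq_len(256) - 128.5
  dd <- outer(ax, ax, function(y, x) sqrt(x^2 + y^2))
  img[dd <= 60] <- 1
  out <- preprocess(img, 192)
  extent_in <- sum(colSums(img > 0.5) > 0)
  extent_out <- sum(colSums(out > 0.5) > 0)
  expect_lt(abs(extent_out - extent_in * 192 / 256), 1)
})

test_that("augmentation with neutral parameters is the identity", {
  gen <- tiny_study()
  im <- gen$study$ed_stack[, , 3]; mk <- gen$gt$ed_mask[, , 3]
  out <- augment(im, mk, augment_params(rotation_range = c(0, 0),
                                        gamma_range = c(1, 1)), seed = 7)
  expect_equal(out$image, im)
  expect_identical(out$mask, mk)
})

test_that("augmentation preserves the label set and the intensity range", {
  gen <- tiny_study()
  im <- gen$study$ed_stack[, , 3]; mk <- gen$gt$ed_mask[, , 3]
  for (seed in 1:5) {
    out <- augment(im, mk, augment_params(), seed = seed)
    expect_true(all(unique(as.integer(out$mask)) %in%
                      unique(as.integer(mk))))
    expect_gte(min(out$image), 0)
    expect_lte(max(out$image), 1)
  }
  expect_error(augment(im, mk[1:10, 1:10], augment_params(), seed = 1),
               "grid")
  expect_error(augment_params(rotation_range = c(-10, 20)), "symmetric")
})
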