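# Synthetic dataset generation: many phantom studies with per-study
# anatomical and artifact variability, written as NIfTI files with a CSV
# manifest, and a patient-wise train/validation/test split (artifact group
# 70/15/15, artifact-free group 70/10/20).

split_counts <- function(n, fractions) {
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  c(train = n_train, val = n_val, test = n - n_train - n_val)
}

assign_split <- function(n, fractions) {
  k <- split_counts(n, fractions)
  rep(c("train", "val", "test"), times = k)
}

# per-study variability around the base configuration
sample_study_config <- function(base, seed, with_artifact) {
  set.seed(seed)
  art <- NULL
  epi <- base$epi_radius_base * runif(1, 0.9, 1.1)
  wall <- base$wall_thickness_ed * runif(1, 0.9, 1.1)
  cf <- runif(1, 0.55, 0.75)
  rvo <- base$rv_offset * runif(1, 0.95, 1.05)
  if (with_artifact) {
    ab <- base$artifact %||% artifact_config()
    art <- artifact_config(
      void_center_angle = runif(1, 150, 210),
      void_radius = ab$void_radius * runif(1, 0.7, 1.3),
      falloff_width = ab$falloff_width,
      rim_gain = ab$rim_gain,
      distortion_amplitude = ab$distortion_amplitude,
      placement_jitter = ab$placement_jitter)
  }
  phantom_config(
    n_slices = base$n_slices, image_size = base$image_size,
    pixel_spacing = base$pixel_spacing, slice_thickness = base$slice_thickness,
    epi_radius_base = epi, wall_thickness_ed = wall,
    rv_offset = rvo, rv_radius_frac = base$rv_radius_frac,
    apex_taper = base$apex_taper, contraction_fraction = cf,
    intensity_means = base$intensity_means, noise_sd = base$noise_sd,
    artifact = art, seed = derive_seed(seed, 17L))
}

#' Generate a synthetic cohort on disk
#'
#' Writes one NIfTI image and mask per phase per study plus `manifest.csv`
#' (schema `study_id,group,phase,image_path,mask_path,pixel_spacing_mm,`
#' `slice_thickness_mm,split`) and `studies.csv` recording the sampled
#' per-study parameters, including the contraction fraction whose square
#' determines the analytic LV ejection fraction. Group 1 (with artifact) is
#' split 70/15/15 into train/validation/test, group 2 (artifact-free)
#' 70/10/20, patient-wise.
#'
#' @param n_with_artifact number of artifact-corrupted studies (group 1).
#' @param n_without number of artifact-free studies (group 2).
#' @param out_dir output directory (created if missing).
#' @param seed master seed; identical seeds give identical cohorts.
#' @param base_config a [phantom_config()] providing acquisition geometry
#'   and the artifact template around which per-study parameters vary.
#' @return the manifest tibble (one row per study per phase), invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(n_with_artifact, n_without, out_dir,
                             seed = 1L, base_config = phantom_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_total <- n_with_artifact + n_without
  if (n_total == 0) stop_cfg("need at least one study")
  groups <- rep(c(1L, 2L), c(n_with_artifact, n_without))
  splits <- character(n_total)
  if (n_with_artifact > 0)
    splits[groups == 1L] <- assign_split(n_with_artifact, c(0.7, 0.15, 0.15))
  if (n_without > 0)
    splits[groups == 2L] <- assign_split(n_without, c(0.7, 0.10, 0.20))
  # randomize which study lands in which split slot, patient-wise
  set.seed(derive_seed(seed, 0L))
  for (g in 1:2) {
    idx <- which(groups == g)
    splits[idx] <- splits[sample(idx)]
  }
  rows <- vector("list", n_total)
  study_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sid <- sprintf("study_%03d", i)
    cfg <- sample_study_config(base_config, derive_seed(seed, i),
                               with_artifact = groups[i] == 1L)
    gen <- generate_study(cfg)
    paths <- list()
    for (ph in c("ed", "es")) {
      ip <- file.path(out_dir, sprintf("%s_%s.nii.gz", sid, ph))
      mp <- file.path(out_dir, sprintf("%s_%s_mask.nii.gz", sid, ph))
      write_nifti_stack(gen$study[[paste0(ph, "_stack")]], ip,
                        cfg$pixel_spacing, cfg$slice_thickness)
      write_nifti_stack(gen$gt[[paste0(ph, "_mask")]], mp,
                        cfg$pixel_spacing, cfg$slice_thickness, mask = TRUE)
      paths[[ph]] <- c(image = ip, mask = mp)
    }
    rows[[i]] <- tibble::tibble(
      study_id = sid, group = groups[i], phase = c("ed", "es"),
      image_path = c(paths$ed[["image"]], paths$es[["image"]]),
      mask_path = c(paths$ed[["mask"]], paths$es[["mask"]]),
      pixel_spacing_mm = cfg$pixel_spacing,
      slice_thickness_mm = cfg$slice_thickness,
      split = splits[i])
    study_rows[[i]] <- tibble::tibble(
      study_id = sid, group = groups[i], split = splits[i],
      contraction_fraction = cfg$contraction_fraction,
      analytic_lvef_pct = 100 * (1 - cfg$contraction_fraction^2),
      epi_radius_base_mm = cfg$epi_radius_base,
      wall_thickness_ed_mm = cfg$wall_thickness_ed,
      rv_offset_mm = cfg$rv_offset)
  }
  manifest <- dplyr::bind_rows(rows)
  studies <- dplyr::bind_rows(study_rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(studies, file.path(out_dir, "studies.csv"), row.names = FALSE)
  manifest
}

#' Read a cohort manifest
#'
#' @param path directory containing `manifest.csv`, or the file itself.
#' @return the manifest tibble.
#' @export
read_manifest <- function(path) {
  f <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(f)) stop_cfg("manifest not found: %s", f)
  tibble::as_tibble(read.csv(f, stringsAsFactors = FALSE))
}

# load all studies of one split into memory as per-study image/mask stacks
load_split <- function(manifest, split) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  ids <- unique(rows$study_id)
  if (!length(ids)) stop_cfg("split '%s' is empty", split)
  out <- lapply(ids, function(id) {
    r <- rows[rows$study_id == id, , drop = FALSE]
    st <- list(study_id = id, group = r$group[1],
               pixel_spacing = r$pixel_spacing_mm[1],
               slice_thickness = r$slice_thickness_mm[1])
    for (ph in c("ed", "es")) {
      rr <- r[r$phase == ph, , drop = FALSE]
      ld <- load_study(rr$image_path, rr$mask_path)
      st[[paste0(ph, "_image")]] <- ld$image
      st[[paste0(ph, "_mask")]] <- ld$mask
    }
    st
  })
  names(out) <- ids
  out
}
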