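# NIfTI I/O, preprocessing and on-the-fly augmentation.
#
# Images and masks travel as NIfTI volumes with in-plane spacing and slice
# thickness in the header (masks as unsigned 8-bit labels). Preprocessing
# follows the acquisition pipeline: centre crop to a square, bilinear resize
# to the network's input size, per-frame min-max normalization to [0, 1].

#' Write an image or mask stack as NIfTI
#'
#' @param data numeric or integer 3D array (rows x cols x slices).
#' @param path output file (`.nii` or `.nii.gz`).
#' @param pixel_spacing in-plane spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @param mask if `TRUE`, store as unsigned 8-bit labels.
#' @return `path`, invisibly.
#' @export
write_nifti_stack <- function(data, path, pixel_spacing, slice_thickness,
                              mask = FALSE) {
  img <- RNifti::asNifti(if (mask) array(as.integer(data), dim(data)) else data)
  RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, slice_thickness)
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Load a study (image and optional mask) from NIfTI files
#'
#' Spacing metadata is read from the header; a mask is validated against the
#' label set \{0, 1, 2, 3\}.
#'
#' @param image_path NIfTI image volume (one phase).
#' @param mask_path optional NIfTI label volume on the same grid.
#' @return a list with `image` (3D array), `mask` (3D integer array or
#'   `NULL`), `pixel_spacing`, `slice_thickness`.
#' @export
load_study <- function(image_path, mask_path = NULL) {
  if (!file.exists(image_path)) stop_cfg("image file not found: %s", image_path)
  img <- RNifti::readNifti(image_path)
  pd <- check_spacing(RNifti::pixdim(img), image_path)
  arr <- array(as.numeric(img), dim(img))
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) stop_cfg("mask file not found: %s", mask_path)
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.integer(m), dim(m))
    if (!identical(dim(mask), dim(arr)))
      stop_cfg("mask grid %s does not match image grid", mask_path)
    bad <- setdiff(unique(as.integer(mask)), 0:3)
    if (length(bad))
      stop_cfg("mask contains invalid label value(s): %s",
               paste(sort(bad), collapse = ", "))
  }
  list(image = arr, mask = mask,
       pixel_spacing = pd[1], slice_thickness = pd[3])
}

check_spacing <- function(pd, path) {
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop_cfg(paste("image %s lacks usable spacing metadata;",
                   "supply pixel spacing and slice thickness in the NIfTI header"),
             path)
  if (abs(pd[1] - pd[2]) > 1e-6)
    stop_cfg("anisotropic in-plane spacing in %s is not supported", path)
  pd
}

# bilinear resize of a 2D frame; identity (up to float round-off) when the
# size is unchanged
resize_bilinear <- function(img, target) {
  h <- nrow(img); w <- ncol(img)
  if (h == target && w == target) return(img)
  # map output pixel centres to source coordinates (align-centres convention)
  src_y <- (seq_len(target) - 0.5) * (h / target) + 0.5
  src_x <- (seq_len(target) - 0.5) * (w / target) + 0.5
  gy <- matrix(src_y, target, target)
  gx <- matrix(src_x, target, target, byrow = TRUE)
  matrix(bilinear_sample(img, as.vector(gy), as.vector(gx)), target)
}

#' Preprocess one frame: centre crop, resize, min-max normalize
#'
#' Centre-crops to a square over the shorter side, resizes to
#' `target_size x target_size` with bilinear interpolation, and rescales
#' intensities to \[0, 1\] (min-max per frame). A constant frame maps to all
#' zeros.
#'
#' @param image 2D numeric matrix (at least 8 pixels per side).
#' @param target_size output size in pixels.
#' @return a `target_size x target_size` matrix in \[0, 1\].
#' @export
preprocess <- function(image, target_size = 192L) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(h) || h < 8 || w < 8) stop_cfg("input image must be at least 8x8")
  side <- min(h, w)
  y0 <- (h - side) %/% 2L
  x0 <- (w - side) %/% 2L
  img <- image[y0 + seq_len(side), x0 + seq_len(side), drop = FALSE]
  img <- resize_bilinear(img, target_size)
  rng <- range(img)
  if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(0, target_size, target_size))
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Augmentation parameters
#'
#' @param rotation_range symmetric rotation range in degrees
#'   (default \[-30, 30\]).
#' @param gamma_range range of the gamma-correction exponent
#'   (default \[0.8, 1.2\]).
#' @param enabled logical; disables augmentation when `FALSE`.
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(rotation_range = c(-30, 30),
                           gamma_range = c(0.8, 1.2), enabled = TRUE) {
  if (abs(rotation_range[1] + rotation_range[2]) > 1e-9)
    stop_cfg("rotation_range must be symmetric about zero")
  if (any(gamma_range <= 0)) stop_cfg("gamma_range must be positive")
  structure(list(rotation_range = rotation_range, gamma_range = gamma_range,
                 enabled = enabled), class = "augment_params")
}

rotate_frame <- function(img, angle_deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (abs(angle_deg) < 1e-12) return(img)
  h <- nrow(img); w <- ncol(img)
  a <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  # rotate sampling grid by -angle (inverse mapping)
  sy <- cy + (-sin(-a)) * xx + cos(-a) * yy
  sx <- cx + cos(-a) * xx + sin(-a) * yy
  if (interp == "bilinear") {
    ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
    v <- bilinear_sample(img, as.vector(sy), as.vector(sx))
    v[!as.vector(ok)] <- 0
    matrix(v, h, w)
  } else {
    matrix(nearest_sample(img, as.vector(sy), as.vector(sx), fill = 0L), h, w)
  }
}

#' Randomly augment an image/mask pair
#'
#' Draws one rotation angle (uniform in `rotation_range`) and one gamma
#' exponent (uniform in `gamma_range`); rotates the image with bilinear and
#' the mask with nearest-neighbour interpolation about the grid centre
#' (fill 0), then applies `intensity^gamma` to the image. Never introduces
#' new label values and keeps intensities in \[0, 1\].
#'
#' @param image 2D numeric matrix in \[0, 1\].
#' @param mask matching integer label matrix.
#' @param params an [augment_params()].
#' @param seed integer seed for the draws.
#' @return list with `image` and `mask`.
#' @export
augment <- function(image, mask, params = augment_params(), seed = 1L) {
  if (!identical(dim(image), dim(mask)))
    stop_cfg("image and mask must share the same grid")
  if (!isTRUE(params$enabled)) return(list(image = image, mask = mask))
  set.seed(seed)
  draws <- augment_draws(params)
  apply_augment(image, mask, draws)
}

augment_draws <- function(params) {
  list(angle = runif(1, params$rotation_range[1], params$rotation_range[2]),
       gamma = runif(1, params$gamma_range[1], params$gamma_range[2]))
}

apply_augment <- function(image, mask, draws) {
  img <- rotate_frame(image, draws$angle, "bilinear")
  msk <- rotate_frame(mask, draws$angle, "nearest")
  if (abs(draws$gamma - 1) > 1e-12) img <- img^draws$gamma
  list(image = clamp01(img), mask = msk)
}
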