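# Segmentation-quality metrics: Dice similarity coefficient, Hausdorff
# distance, recall and precision, computed at volume level (over the whole
# slice stack) per structure and phase, with cohort aggregation as
# median (interquartile range).

STRUCTURE_CLASSES <- c(lv = 1L, lvm = 2L, rv = 3L)

check_same_grid <- function(pred, ref) {
  if (!identical(dim(pred) %||% length(pred), dim(ref) %||% length(ref)))
    stop_cfg("prediction and reference are not on the same grid")
}

#' Dice similarity coefficient for one class
#'
#' `2|X  intersect  Y| / (|X| + |Y|)` over all voxels of the stack. Returns 1
#' when the class is absent from both masks (perfect agreement on absence).
#'
#' @param pred,ref integer label arrays on the same grid.
#' @param class_id class label (0 = background, 1 = LV cavity,
#'   2 = LV myocardium, 3 = RV cavity).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(pred, ref, class_id) {
  check_same_grid(pred, ref)
  x <- pred == class_id
  y <- ref == class_id
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}

#' Recall and precision for one class
#'
#' Recall = TP / (TP + FN); precision = TP / (TP + FP). When a denominator
#' is empty the metric is 1 if the other mask is also empty for the class,
#' otherwise 0.
#'
#' @inheritParams dice
#' @return named numeric vector `c(recall =, precision =)`.
#' @export
recall_precision <- function(pred, ref, class_id) {
  check_same_grid(pred, ref)
  x <- pred == class_id
  y <- ref == class_id
  tp <- sum(x & y)
  fn <- sum(!x & y)
  fp <- sum(x & !y)
  rec <- if (tp + fn == 0) as.numeric(tp + fp == 0) else tp / (tp + fn)
  prec <- if (tp + fp == 0) as.numeric(tp + fn == 0) else tp / (tp + fp)
  c(recall = rec, precision = prec)
}

# boundary pixels of a binary slice: a positive pixel with at least one
# 4-neighbour outside the set (image border counts as outside)
boundary_points <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(core & !interior, arr.ind = TRUE)
}

directed_hd2 <- function(a, b) {
  # max over rows of a of the min squared distance to rows of b
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  max(apply(d2, 1, min))
}

#' Hausdorff distance between two segmentations of one class
#'
#' Symmetric Hausdorff distance between boundary point sets, in mm. By
#' default computed slice-wise in 2D (in-plane spacing) and maximized over
#' slices where the class is present in both masks, reflecting the strongly
#' anisotropic through-plane resolution of short-axis stacks; `method =
#' "3d"` computes a full 3D distance with anisotropic spacing instead.
#'
#' @inheritParams dice
#' @param spacing in-plane pixel spacing in mm.
#' @param slice_thickness through-plane spacing in mm (3D method only).
#' @param method `"slice"` (default) or `"3d"`.
#' @return distance in mm, or `NA` when the class is missing from either
#'   mask on every slice (undefined distance, excluded from aggregation).
#' @export
hausdorff <- function(pred, ref, class_id, spacing = 1,
                      slice_thickness = spacing, method = c("slice", "3d")) {
  method <- match.arg(method)
  check_same_grid(pred, ref)
  if (is.null(dim(pred))) stop_cfg("masks must be matrices or 3D arrays")
  pd <- if (length(dim(pred)) == 2L) array(pred, c(dim(pred), 1L)) else pred
  rf <- if (length(dim(ref)) == 2L) array(ref, c(dim(ref), 1L)) else ref
  if (method == "slice") {
    hds <- rep(NA_real_, dim(pd)[3])
    for (s in seq_len(dim(pd)[3])) {
      bp <- boundary_points(pd[, , s] == class_id)
      br <- boundary_points(rf[, , s] == class_id)
      if (nrow(bp) == 0 || nrow(br) == 0) next
      hds[s] <- sqrt(max(directed_hd2(bp, br), directed_hd2(br, bp))) * spacing
    }
    if (all(is.na(hds))) return(NA_real_)
    max(hds, na.rm = TRUE)
  } else {
    pts <- function(m) {
      out <- lapply(seq_len(dim(m)[3]), function(s) {
        b <- boundary_points(m[, , s] == class_id)
        if (nrow(b) == 0) return(NULL)
        cbind(b * spacing, s * slice_thickness)
      })
      do.call(rbind, out)
    }
    bp <- pts(pd); br <- pts(rf)
    if (is.null(bp) || is.null(br)) return(NA_real_)
    sqrt(max(directed_hd2(bp, br), directed_hd2(br, bp)))
  }
}

#' Volume-level metrics for one prediction/reference pair
#'
#' @inheritParams hausdorff
#' @param structures named integer vector of class labels to evaluate;
#'   default the three cardiac structures.
#' @return a tibble with one row per structure: `structure`, `dsc`, `hd_mm`,
#'   `recall`, `precision`.
#' @export
evaluate_masks <- function(pred, ref, spacing = 1,
                           structures = STRUCTURE_CLASSES) {
  purrr::imap_dfr(as.list(structures), function(cl, nm) {
    rp <- recall_precision(pred, ref, cl)
    tibble::tibble(structure = nm,
                   dsc = dice(pred, ref, cl),
                   hd_mm = hausdorff(pred, ref, cl, spacing = spacing),
                   recall = rp[["recall"]],
                   precision = rp[["precision"]])
  })
}

#' Per-study volume-level metrics for a cohort
#'
#' @param predictions named list (by study id) of lists with `ed` and `es`
#'   predicted label stacks.
#' @param references matching named list of reference label stacks.
#' @param spacing in-plane pixel spacing in mm (single value, or named
#'   vector/list by study id).
#' @return a tibble with columns `study_id`, `phase`, `structure`, `dsc`,
#'   `hd_mm`, `recall`, `precision`.
#' @export
evaluate_cohort <- function(predictions, references, spacing = 1) {
  ids <- names(predictions)
  missing_ids <- union(setdiff(ids, names(references)),
                       setdiff(names(references), ids))
  if (length(missing_ids))
    stop_cfg("study ids do not match between predictions and references: %s",
             paste(missing_ids, collapse = ", "))
  purrr::map_dfr(ids, function(id) {
    sp <- if (length(spacing) > 1L) spacing[[id]] else spacing
    purrr::map_dfr(c("ed", "es"), function(ph) {
      evaluate_masks(predictions[[id]][[ph]], references[[id]][[ph]],
                     spacing = sp) |>
        dplyr::mutate(study_id = id, phase = ph, .before = 1)
    })
  })
}

#' Cohort summary as median (interquartile range)
#'
#' Quartiles use linear interpolation (type 7). Undefined Hausdorff
#' distances are excluded.
#'
#' @param metrics a tibble from [evaluate_cohort()].
#' @return a tibble with one row per structure x phase and columns
#'   `<metric>_median`, `<metric>_q1`, `<metric>_q3`.
#' @export
summarize_cohort <- function(metrics) {
  metrics |>
    tidyr::pivot_longer(c("dsc", "hd_mm", "recall", "precision"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$structure, .data$phase, .data$metric) |>
    dplyr::summarise(
      median = median(.data$value, na.rm = TRUE),
      q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop")
}
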