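# Clinical parameters derived from label-mask stacks (volumes, ejection
# fraction, myocardial mass) and method-agreement statistics (ICC(2,1) and
# Bland-Altman limits of agreement).

#' Volume of one labelled structure in a mask stack
#'
#' Simple voxel summation: voxel count x in-plane spacing^2 x slice
#' thickness, converted to mL. Slices are assumed contiguous (no interslice
#' gap).
#'
#' @param mask_stack integer label array (rows x cols x slices or a single
#'   slice matrix).
#' @param class_id class label to measure.
#' @param spacing in-plane pixel spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @return volume in mL.
#' @export
structure_volume <- function(mask_stack, class_id, spacing, slice_thickness) {
  if (missing(spacing) || missing(slice_thickness) ||
      is.null(spacing) || is.null(slice_thickness) ||
      !is.finite(spacing) || !is.finite(slice_thickness))
    stop_cfg("pixel spacing and slice thickness metadata are required")
  sum(mask_stack == class_id) * spacing^2 * slice_thickness / 1000
}

#' Ejection fraction in percent
#'
#' @param edv end-diastolic volume in mL (must be positive).
#' @param esv end-systolic volume in mL.
#' @return `100 * (edv - esv) / edv`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop_cfg("end-diastolic volume must be positive")
  100 * (edv - esv) / edv
}

#' Myocardial mass from myocardial volume
#'
#' Uses the standard CMR myocardial density convention of 1.05 g/mL.
#'
#' @param myocardium_volume volume in mL.
#' @param density tissue density in g/mL.
#' @return mass in grams.
#' @export
myocardial_mass <- function(myocardium_volume, density = 1.05) {
  if (any(myocardium_volume < 0)) stop_cfg("volume must be non-negative")
  myocardium_volume * density
}

#' Clinical parameters for one study
#'
#' Computes LV and RV end-diastolic and end-systolic volumes, ejection
#' fractions and LV myocardial mass at both phases from a pair of label
#' stacks.
#'
#' @param ed_mask,es_mask label stacks at end-diastole and end-systole.
#' @param spacing in-plane pixel spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @param study_id optional identifier carried into the output.
#' @return a one-row tibble with columns `study_id`, `lvedv_ml`, `lvesv_ml`,
#'   `rvedv_ml`, `rvesv_ml`, `lvef_pct`, `rvef_pct`, `lvm_ed_g`, `lvm_es_g`.
#' @export
clinical_parameters <- function(ed_mask, es_mask, spacing, slice_thickness,
                                study_id = NA_character_) {
  lvedv <- structure_volume(ed_mask, 1L, spacing, slice_thickness)
  lvesv <- structure_volume(es_mask, 1L, spacing, slice_thickness)
  rvedv <- structure_volume(ed_mask, 3L, spacing, slice_thickness)
  rvesv <- structure_volume(es_mask, 3L, spacing, slice_thickness)
  tibble::tibble(
    study_id = study_id,
    lvedv_ml = lvedv, lvesv_ml = lvesv,
    rvedv_ml = rvedv, rvesv_ml = rvesv,
    lvef_pct = if (lvedv > 0) ejection_fraction(lvedv, lvesv) else NA_real_,
    rvef_pct = if (rvedv > 0) ejection_fraction(rvedv, rvesv) else NA_real_,
    lvm_ed_g = myocardial_mass(structure_volume(ed_mask, 2L, spacing, slice_thickness)),
    lvm_es_g = myocardial_mass(structure_volume(es_mask, 2L, spacing, slice_thickness)))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC,
#' computed from the mean squares of the two-way (subjects x methods)
#' layout. This is the method-comparison form: a constant offset between
#' methods lowers the coefficient.
#'
#' @param x,y paired measurements (two methods on the same subjects), at
#'   least 3 finite pairs.
#' @return the ICC value; `NA` with a warning for degenerate (zero
#'   variance) input.
#' @export
icc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_cfg("ICC requires at least 3 finite pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom <= .Machine$double.eps * max(1, abs(msr))) {
    warning("degenerate (zero-variance) input; ICC undefined")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are `x - y`; the bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * sd` (sample standard deviation). The 1.96
#' multiplier is configurable (some reports use 2).
#'
#' @param x,y paired measurements (at least 2 pairs).
#' @param k multiplier for the limits of agreement.
#' @return a list with `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(x, y, k = 1.96) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  if (length(d) < 2) stop_cfg("Bland-Altman requires at least 2 pairs")
  s <- sd(d)
  b <- mean(d)
  list(bias = b, loa_low = b - k * s, loa_high = b + k * s, sd = s,
       n = length(d))
}

#' Agreement report between automatic and reference clinical parameters
#'
#' Joins the two tables by `study_id` and computes, per parameter, the
#' ICC(2,1), Bland-Altman bias and 95% limits of agreement, and a
#' reproducibility flag (`icc > 0.75`).
#'
#' @param auto,ref tibbles as returned by [clinical_parameters()] (one row
#'   per study).
#' @param parameters character vector of parameter columns to compare;
#'   default every shared numeric column except `study_id`.
#' @param icc_threshold reproducibility threshold on the ICC.
#' @return a tibble of class `agreement_report` with columns `parameter`,
#'   `icc`, `bias`, `loa_low`, `loa_high`, `reproducible`. The matched pairs
#'   are attached as attribute `"pairs"` for plotting.
#' @export
agreement_report <- function(auto, ref, parameters = NULL,
                             icc_threshold = 0.75) {
  unmatched <- union(setdiff(auto$study_id, ref$study_id),
                     setdiff(ref$study_id, auto$study_id))
  if (length(unmatched))
    stop_cfg("unmatched study ids: %s", paste(unmatched, collapse = ", "))
  if (is.null(parameters))
    parameters <- intersect(setdiff(names(auto), "study_id"),
                            setdiff(names(ref), "study_id"))
  j <- dplyr::inner_join(auto, ref, by = "study_id",
                         suffix = c("_auto", "_ref"))
  res <- purrr::map_dfr(parameters, function(p) {
    xa <- j[[paste0(p, "_auto")]]
    xr <- j[[paste0(p, "_ref")]]
    n_ok <- sum(is.finite(xa) & is.finite(xr))
    if (n_ok < 3) {
      warning(sprintf("parameter '%s' has only %d finite pair(s); reported as NA",
                      p, n_ok))
      return(tibble::tibble(parameter = p, icc = NA_real_, bias = NA_real_,
                            loa_low = NA_real_, loa_high = NA_real_,
                            reproducible = FALSE))
    }
    ba <- bland_altman(xa, xr)
    ic <- suppressWarnings(icc(xa, xr))
    tibble::tibble(parameter = p, icc = ic, bias = ba$bias,
                   loa_low = ba$loa_low, loa_high = ba$loa_high,
                   reproducible = is.finite(ic) & ic > icc_threshold)
  })
  attr(res, "pairs") <- j
  attr(res, "parameters") <- parameters
  class(res) <- c("agreement_report", class(res))
  res
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x) %in%
    c("parameter", "icc", "bias", "loa_low", "loa_high", "reproducible")])
}

#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n_parameters = nrow(x),
                 n_reproducible = sum(x$reproducible, na.rm = TRUE),
                 min_icc = min(x$icc, na.rm = TRUE))
}

#' Bland-Altman panels for an agreement report
#'
#' One panel per parameter: difference against pair mean, with the bias
#' (dashed) and 95% limits of agreement (solid) as horizontal lines.
#'
#' @param object an [agreement_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  pairs <- attr(object, "pairs")
  params <- attr(object, "parameters")
  long <- purrr::map_dfr(params, function(p) {
    tibble::tibble(parameter = p,
                   mean = (pairs[[paste0(p, "_auto")]] + pairs[[paste0(p, "_ref")]]) / 2,
                   diff = pairs[[paste0(p, "_auto")]] - pairs[[paste0(p, "_ref")]])
  })
  lines <- tidy(object) |>
    tidyr::pivot_longer(c("bias", "loa_low", "loa_high"),
                        names_to = "line", values_to = "value") |>
    dplyr::mutate(style = ifelse(.data$line == "bias", "dashed", "solid"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$value,
                                     linetype = .data$style)) +
    ggplot2::scale_linetype_identity() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (auto - reference)")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
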