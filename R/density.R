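#' Per-nucleus normalized DNA image
#'
#' Divides the (background-subtracted) DNA-counterstain intensity inside one
#' nucleus by the maximum intensity in that nucleus, giving values in
#' \[0, 1\] that attain 1. In an interphase nucleus the maximum sits in a
#' heterochromatic region, so the normalized value reads as relative local
#' chromatin density. Normalization is strictly per nucleus: it removes
#' cell-to-cell intensity differences from cell-cycle stage, staining
#' efficiency and field inhomogeneity.
#'
#' @param dna_bg_subtracted Background-subtracted DNA `channel_image` or
#'   matrix.
#' @param nucleus Logical mask of the nucleus region.
#' @param max_quantile Quantile used as the normalizer, default 1 (the
#'   strict maximum). Values slightly below 1 (e.g. 0.999) resist hot
#'   pixels; with `max_quantile < 1` normalized values can exceed 1 and are
#'   clipped.
#' @return List with `values` (matrix, `NA` outside the nucleus) and
#'   `i_max` (the normalizer), class `normalized_dna`.
#' @export
normalize_dna <- function(dna_bg_subtracted, nucleus, max_quantile = 1) {
  px <- as_pixels(dna_bg_subtracted)
  nucleus <- as_binary(nucleus)
  if (!identical(dim(px), dim(nucleus))) stop("mask shape differs from image")
  if (!any(nucleus)) stop("empty nucleus region")
  vals <- px[nucleus]
  i_max <- if (max_quantile >= 1) max(vals) else
    as.numeric(stats::quantile(vals, max_quantile, names = FALSE))
  if (i_max <= 0) stop("empty nucleus signal")
  out <- matrix(NA_real_, nrow(px), ncol(px))
  out[nucleus] <- pmin(vals / i_max, 1)
  structure(list(values = out, i_max = i_max), class = "normalized_dna")
}

#' Mean normalized DNA density over the damage regions of one nucleus
#'
#' The region of interest is the intersection of the nucleus mask with the
#' binary damage mask; the statistic is the arithmetic mean of the
#' normalized DNA intensity over that ROI. High values mean the damage
#' sits in compact (bright-counterstain) chromatin; low values mean open
#' chromatin. A nucleus whose ROI is empty (no suprathreshold damage) has
#' an undefined density and is flagged, not errored.
#'
#' @param norm A `normalized_dna` object (or matrix of normalized values).
#' @param nucleus Logical nucleus mask.
#' @param damage Logical damage mask.
#' @return List: `dna_density` (in \[0,1\], or `NA` if the ROI is empty),
#'   `roi_area_px`, and `flag` (`""` or `"no foci"`).
#' @export
dna_density <- function(norm, nucleus, damage) {
  vals <- if (inherits(norm, "normalized_dna")) norm$values else as.matrix(norm)
  nucleus <- as_binary(nucleus)
  damage <- as_binary(damage)
  if (!identical(dim(vals), dim(nucleus)) ||
      !identical(dim(vals), dim(damage))) stop("shapes differ")
  roi <- nucleus & damage
  n_roi <- sum(roi)
  if (n_roi == 0L) {
    return(list(dna_density = NA_real_, roi_area_px = 0L, flag = "no foci"))
  }
  list(dna_density = mean(vals[roi]), roi_area_px = as.integer(n_roi),
       flag = "")
}
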