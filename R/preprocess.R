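#' Isodata (histogram bisection) threshold
#'
#' Classic isodata automatic threshold on an `n_bins` histogram: starting
#' from the histogram midpoint, iterate
#' `t <- (mean(pixels <= t) + mean(pixels > t)) / 2` until the threshold is
#' stable. The returned value satisfies the isodata fixed point within one
#' bin width and is deterministic for a fixed input. Bin placement can shift
#' the result by about one bin relative to other isodata variants; that
#' difference is far below biological variability.
#'
#' @param image A `channel_image` or numeric matrix.
#' @param n_bins Number of histogram bins (default 256, the 8-bit
#'   convention used by interactive thresholding tools).
#' @return The threshold intensity (scalar). Pixels strictly above it form
#'   the foreground class.
#' @export
isodata_threshold <- function(image, n_bins = 256L) {
  px <- as.vector(as_pixels(image))
  if (length(px) == 0L) stop("empty image")
  lo <- min(px); hi <- max(px)
  if (hi <= lo) stop("degenerate histogram: image is constant")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  width <- (hi - lo) / n_bins
  # bin index 1..n_bins; histogram means computed from bin centres
  idx <- pmin(floor((px - lo) / width) + 1, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centres <- lo + (seq_len(n_bins) - 0.5) * width
  csum_n <- cumsum(counts)
  csum_i <- cumsum(counts * centres)
  total_n <- csum_n[n_bins]
  total_i <- csum_i[n_bins]
  # threshold expressed as a bin boundary index k: classes are bins <= k and > k
  k <- n_bins %/% 2L
  for (iter in 1:1000) {
    # ensure both classes nonempty by moving to nearest populated split
    while (k >= 1L && csum_n[k] == 0L) k <- k + 1L
    while (k <= n_bins - 1L && csum_n[k] == total_n) k <- k - 1L
    mu_lo <- csum_i[k] / csum_n[k]
    mu_hi <- (total_i - csum_i[k]) / (total_n - csum_n[k])
    t_new <- (mu_lo + mu_hi) / 2
    k_new <- min(max(floor((t_new - lo) / width), 1), n_bins - 1L)
    if (k_new == k) break
    k <- as.integer(k_new)
  }
  lo + k * width
}

#' Segment nuclei into a count mask
#'
#' Binarizes the DNA-counterstain channel at its isodata threshold, fills
#' enclosed holes (so dim intranuclear regions do not fragment a nucleus),
#' labels 8-connected components, and filters by area and border contact.
#' Surviving nuclei are renumbered `1..n_objects` in raster order.
#'
#' @param dna_image A `channel_image` with role `"dna"` (or a plain matrix).
#' @param min_area_px Minimum nucleus area in pixels. Default 5000, about
#'   10 um^2 at 45 nm/px; also serves as a crude guard against debris.
#' @param exclude_border Drop nuclei touching the image border (default
#'   `TRUE`: partial nuclei bias the per-cell maximum intensity and the
#'   correlation estimates).
#' @param max_area_px Optional maximum-area filter (`Inf` to disable).
#' @param threshold Optional explicit binarization threshold; if `NULL`
#'   (default) the isodata threshold of the image is used.
#' @return A `count_mask`. A field with no surviving nuclei yields a valid
#'   mask with `n_objects = 0` (callers warn rather than fail).
#' @export
segment_nuclei <- function(dna_image, min_area_px = 5000L,
                           exclude_border = TRUE, max_area_px = Inf,
                           threshold = NULL) {
  px <- as_pixels(dna_image, role = if (inherits(dna_image, "channel_image")) "dna")
  if (is.null(threshold)) threshold <- isodata_threshold(px)
  bin <- px > threshold
  bin <- cf_fill_holes(bin)
  lab <- cf_label_components(bin)
  n <- attr(lab, "n")
  if (n == 0L) return(count_mask(matrix(0L, nrow(px), ncol(px))))
  areas <- tabulate(lab[lab > 0L], nbins = n)
  keep <- areas >= min_area_px & areas <= max_area_px
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep[border[border > 0L]] <- FALSE
  }
  # renumber survivors in raster order of first pixel; cf_label_components
  # already assigns labels in that order, so keeping order of old labels works
  map <- integer(n)
  map[keep] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- map[lab[nz]]
  count_mask(out)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the upper envelope of a ball of radius
#' `radius_px` rolled beneath the intensity surface (grayscale opening with
#' a non-flat spherical structuring element) and subtracts it, clipping at
#' zero. Features narrower than the ball survive; plateaus much wider than
#' the ball are removed. For counterstain images the radius should match
#' the largest chromatin feature to preserve (default 10 px).
#'
#' @param image A `channel_image` or matrix.
#' @param radius_px Ball radius in pixels (>= 1).
#' @return Same type as the input, with the background removed.
#' @export
rolling_ball_subtract <- function(image, radius_px = 10) {
  px <- as_pixels(image)
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px >= min(dim(px))) stop("radius too large for this image")
  bg <- cf_ball_dilate(cf_ball_erode(px, radius_px), radius_px)
  out <- pmax(px - bg, 0)
  if (inherits(image, "channel_image")) {
    channel_image(out, image$pixel_size_nm, image$role)
  } else {
    out
  }
}

#' Binary damage mask
#'
#' Thresholds the background-subtracted damage channel at a user-supplied
#' intensity: pixels strictly above `threshold` are damage. The threshold is
#' an experiment-level constant (keep it fixed across images acquired in the
#' same experiment) rather than a per-image automatic value.
#'
#' @param damage_image Background-subtracted `channel_image` with role
#'   `"damage"` (or a matrix).
#' @param threshold Intensity threshold (strict inequality).
#' @return Logical matrix; an all-`FALSE` mask is valid.
#' @export
damage_mask <- function(damage_image, threshold) {
  px <- as_pixels(damage_image,
                  role = if (inherits(damage_image, "channel_image")) "damage")
  px > threshold
}

#' Count damage foci within one nucleus
#'
#' Number of 8-connected components of `damage AND nucleus` with area of at
#' least `min_focus_px` pixels.
#'
#' @param damage Logical damage mask.
#' @param nucleus Logical mask of one nucleus region (same shape).
#' @param min_focus_px Minimum focus area in pixels (default 4).
#' @return Integer focus count.
#' @export
count_foci <- function(damage, nucleus, min_focus_px = 4L) {
  damage <- as_binary(damage)
  nucleus <- as_binary(nucleus)
  if (!identical(dim(damage), dim(nucleus))) stop("mask shapes differ")
  both <- damage & nucleus
  if (!any(both)) return(0L)
  lab <- cf_label_components(both)
  n <- attr(lab, "n")
  areas <- tabulate(lab[lab > 0L], nbins = n)
  sum(areas >= min_focus_px)
}

# Extract the logical region of nucleus `id` from a count mask.
nucleus_region <- function(nuclei, id) {
  stopifnot(inherits(nuclei, "count_mask"))
  nuclei$labels == id
}
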