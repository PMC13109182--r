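#' Single-channel fluorescence image
#'
#' Lightweight container for one 2D channel of a confocal field: a
#' nonnegative intensity matrix plus the physical pixel size and the
#' biological role of the channel (`"damage"` for the focus marker,
#' `"dna"` for the counterstain).
#'
#' @param pixels Numeric matrix of nonnegative intensities (rows = y,
#'   columns = x; 0-based pixel centres at integer coordinates).
#' @param pixel_size_nm Positive pixel size in nanometres. The default, 45,
#'   corresponds to typical oversampled confocal acquisition of nuclei.
#' @param role `"damage"` or `"dna"`.
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(runif(64 * 64), 64), role = "dna")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, pixel_size_nm = 45,
                          role = c("damage", "dna")) {
  role <- match.arg(role)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("empty image")
  if (anyNA(pixels)) stop("image contains missing values")
  if (min(pixels) < 0) stop("pixel values must be >= 0")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a positive scalar")
  }
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 role = role),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d px, %.3g nm/px, role = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$role))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Coerce matrix-or-channel_image inputs; role checked only when asserted.
as_pixels <- function(x, role = NULL) {
  if (inherits(x, "channel_image")) {
    if (!is.null(role) && x$role != role) {
      stop(sprintf("expected a '%s' channel, got '%s'", role, x$role))
    }
    x$pixels
  } else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

#' Labelled nucleus segmentation ("count mask")
#'
#' Integer-labelled segmentation of a field: 0 is background and labels
#' `1..n_objects` identify individual nuclei as disjoint 8-connected
#' regions, numbered in raster order of their first pixel.
#'
#' @param labels Integer matrix of labels.
#' @return An object of class `count_mask` with elements `labels` and
#'   `n_objects`.
#' @export
count_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  n <- if (length(labels)) max(labels) else 0L
  if (n < 0L || min(labels) < 0L) stop("labels must be nonnegative")
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_len(n))) {
    stop("labels must be consecutive 1..n_objects")
  }
  structure(list(labels = labels, n_objects = as.integer(n)),
            class = "count_mask")
}

#' @export
print.count_mask <- function(x, ...) {
  cat(sprintf("<count_mask> %d x %d px, %d nuclei\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

as_binary <- function(mask) {
  if (inherits(mask, "count_mask")) return(mask$labels > 0L)
  m <- as.matrix(mask)
  if (is.logical(m)) return(m)
  m != 0
}
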