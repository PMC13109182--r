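#' Synthetic nucleus scene parameters
#'
#' Describes one simulated interphase nucleus imaged in two channels: the
#' DNA counterstain (channel 2) is a uniform euchromatin baseline inside an
#' ellipse plus bright Gaussian heterochromatin blobs; the damage channel
#' (channel 1) is a set of compact Gaussian foci, each centred on a
#' heterochromatin blob with probability `p_het` and otherwise at an
#' off-blob euchromatic location. Both channels are blurred by a Gaussian
#' PSF, scaled to photons, Poisson-sampled, and offset.
#'
#' Defaults emulate oversampled confocal imaging of a leukaemia-line
#' nucleus at 45 nm/px: semi-axes 100 x 75 px (9.0 x 6.8 um nucleus),
#' 20 heterochromatin domains of sigma 4 px (about 0.4 um FWHM, i.e. below
#' the 10 px rolling-ball scale), blob peak twice the euchromatin baseline,
#' 5 diffraction-limited damage foci (sigma 3 px) at three times baseline,
#' PSF sigma 2 px (90 nm), 50 detected photons per intensity unit and a
#' detector offset of 2.
#'
#' @param image_shape Image dimensions (rows, cols).
#' @param nucleus_axes_px Ellipse semi-axes (row, col) in pixels.
#' @param n_blobs Number of heterochromatin blobs. Blob centres are kept
#'   at least five blob sigmas apart (domains are distinct, resolvable
#'   objects).
#' @param blob_sigma_px Blob Gaussian sigma in pixels.
#' @param blob_contrast Blob peak over euchromatin baseline (> 1).
#' @param n_foci Number of damage foci.
#' @param focus_sigma_px Focus Gaussian sigma in pixels.
#' @param focus_amplitude Focus peak in baseline units (> 0).
#' @param p_het Probability a focus is centred on a blob, in \[0, 1\]
#'   (used by `placement = "targeted"`).
#' @param placement `"targeted"` (default): each focus sits on a blob
#'   centre with probability `p_het`, otherwise at an off-blob location at
#'   least two blob sigmas (and six focus sigmas) from every blob centre
#'   and six focus sigmas from earlier foci, so damage sites are distinct
#'   and truth counts unambiguous; each blob hosts at most one focus, and
#'   foci in excess of the blob count fall back to off-blob placement.
#'   `"independent"`: foci
#'   are uniform over the nucleus interior regardless of blobs (placement
#'   probability proportional to area), the no-association null.
#' @param damage_background Diffuse nucleoplasmic level of the damage
#'   channel, in euchromatin-baseline units (default 0.5, about one sixth
#'   of the focus peak - typical nonspecific antibody staining). Without
#'   it the two channels carry very different relative intensity offsets
#'   after background subtraction and the ICCS amplitude ratio leaves its
#'   nominal range; see the methods vignette.
#' @param psf_sigma_px Gaussian PSF sigma in pixels.
#' @param photons_per_unit Photon yield per intensity unit; `Inf` disables
#'   Poisson noise.
#' @param background_offset Additive detector offset (intensity units
#'   after photon scaling).
#' @param pixel_size_nm Physical pixel size.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical images.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(image_shape = c(256L, 256L),
                         nucleus_axes_px = c(100, 75),
                         n_blobs = 20L, blob_sigma_px = 4,
                         blob_contrast = 2, n_foci = 5L,
                         focus_sigma_px = 3, focus_amplitude = 3,
                         p_het = 0.5, placement = c("targeted", "independent"),
                         damage_background = 0.5, psf_sigma_px = 2,
                         photons_per_unit = 50, background_offset = 2,
                         pixel_size_nm = 45, seed = 1L) {
  placement <- match.arg(placement)
  p <- list(image_shape = as.integer(image_shape),
            nucleus_axes_px = as.numeric(nucleus_axes_px),
            n_blobs = as.integer(n_blobs),
            blob_sigma_px = blob_sigma_px, blob_contrast = blob_contrast,
            n_foci = as.integer(n_foci), focus_sigma_px = focus_sigma_px,
            focus_amplitude = focus_amplitude, p_het = p_het,
            placement = placement, damage_background = damage_background,
            psf_sigma_px = psf_sigma_px,
            photons_per_unit = photons_per_unit,
            background_offset = background_offset,
            pixel_size_nm = pixel_size_nm, seed = as.integer(seed))
  stopifnot(length(p$image_shape) == 2L, all(p$image_shape >= 32L),
            length(p$nucleus_axes_px) == 2L, all(p$nucleus_axes_px > 0),
            p$n_blobs >= 0L, p$blob_sigma_px > 0, p$blob_contrast > 1,
            p$n_foci >= 0L, p$focus_sigma_px > 0, p$focus_amplitude > 0,
            p$p_het >= 0, p$p_het <= 1, p$damage_background >= 0,
            p$psf_sigma_px > 0,
            p$photons_per_unit > 0, p$background_offset >= 0,
            p$pixel_size_nm > 0)
  margin <- 3 * p$psf_sigma_px
  if (any(p$nucleus_axes_px + margin > p$image_shape / 2)) {
    stop("nucleus does not fit inside the image with a PSF-width margin")
  }
  class(p) <- "scene_params"
  p
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf(
    "<scene_params> %dx%d px, axes (%.3g, %.3g), %d blobs, %d foci, p_het = %.2g, seed = %d\n",
    x$image_shape[1], x$image_shape[2], x$nucleus_axes_px[1],
    x$nucleus_axes_px[2], x$n_blobs, x$n_foci, x$p_het, x$seed))
  invisible(x)
}

# Run expr with a private, seeded RNG stream; restores the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform point inside the ellipse (0-based pixel coordinates), optionally
# shrunk to keep structures away from the rim.
sample_in_ellipse <- function(centre, axes, shrink = 0.9) {
  rho <- sqrt(runif(1)) * shrink
  th <- runif(1, 0, 2 * pi)
  c(centre[1] + axes[1] * rho * sin(th), centre[2] + axes[2] * rho * cos(th))
}

# Add a Gaussian bump at `at` (0-based row/col) into `img`, evaluated on a
# local window of +/- 4 sigma.
add_bump <- function(img, at, sigma, amp) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(at[1] + 1 - 4 * sigma))
  r1 <- min(nr, ceiling(at[1] + 1 + 4 * sigma))
  c0 <- max(1L, floor(at[2] + 1 - 4 * sigma))
  c1 <- min(nc, ceiling(at[2] + 1 + 4 * sigma))
  rr <- r0:r1; cc <- c0:c1
  dr2 <- ((rr - 1) - at[1])^2
  dc2 <- ((cc - 1) - at[2])^2
  img[rr, cc] <- img[rr, cc] + amp * exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
  img
}

# Circular FFT Gaussian blur; scenes keep a dark margin so wrap-around is
# negligible.
gaussian_blur <- function(img, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  wrap <- function(n) {
    i <- seq_len(n) - 1L
    ifelse(i <= n / 2, i, i - n)
  }
  k <- exp(-outer(wrap(nr)^2, wrap(nc)^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(img) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

#' Simulate one two-channel nucleus with ground truth
#'
#' See [scene_params()] for the scene model. Off-blob foci are resampled
#' until they lie at least two blob sigmas from every blob centre, so
#' `p_het` cleanly separates the on-blob and off-blob regimes.
#'
#' @param params A `scene_params` object.
#' @return List with `ch1` (damage `channel_image`), `ch2` (DNA
#'   `channel_image`) and `truth` (blob/foci coordinates in 0-based
#'   row/col, `foci_on_blob` flags, `p_het`, `nucleus_mask_true`, `seed`).
#' @export
simulate_nucleus <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, simulate_nucleus_impl(params))
}

simulate_nucleus_impl <- function(params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  centre <- c((nr - 1) / 2, (nc - 1) / 2)
  axes <- params$nucleus_axes_px
  rowg <- matrix(seq_len(nr) - 1, nr, nc)
  colg <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  inside <- ((rowg - centre[1]) / axes[1])^2 +
            ((colg - centre[2]) / axes[2])^2 <= 1

  # blobs are distinct chromatin domains: keep centres >= 2 sigma apart
  blob_centres <- matrix(numeric(0), 0, 2)
  for (i in seq_len(params$n_blobs)) {
    ok <- FALSE
    for (try in 1:1000) {
      cand <- sample_in_ellipse(centre, axes)
      if (nrow(blob_centres) == 0L ||
          min((blob_centres[, 1] - cand[1])^2 +
              (blob_centres[, 2] - cand[2])^2) >=
            (5 * params$blob_sigma_px)^2) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible geometry: cannot place blob")
    blob_centres <- rbind(blob_centres, cand)
  }

  min_d2 <- (2 * params$blob_sigma_px)^2
  foci <- matrix(numeric(0), 0, 2)
  on_blob <- logical(0)
  if (params$placement == "independent") {
    for (i in seq_len(params$n_foci)) {
      cand <- sample_in_ellipse(centre, axes)
      foci <- rbind(foci, cand)
      on_blob <- c(on_blob, params$n_blobs > 0L &&
        min((blob_centres[, 1] - cand[1])^2 +
            (blob_centres[, 2] - cand[2])^2) < min_d2)
    }
  } else {
    free_blobs <- seq_len(params$n_blobs) # each blob hosts at most one focus
    foci_sep2 <- (6 * params$focus_sigma_px)^2
    excl2 <- max(min_d2, foci_sep2)
    for (i in seq_len(params$n_foci)) {
      if (length(free_blobs) > 0L && runif(1) < params$p_het) {
        j <- free_blobs[sample.int(length(free_blobs), 1L)]
        free_blobs <- setdiff(free_blobs, j)
        foci <- rbind(foci, blob_centres[j, ])
        on_blob <- c(on_blob, TRUE)
      } else {
        ok <- FALSE
        for (try in 1:1000) {
          cand <- sample_in_ellipse(centre, axes)
          far_blobs <- params$n_blobs == 0L ||
            min((blob_centres[, 1] - cand[1])^2 +
                (blob_centres[, 2] - cand[2])^2) >= excl2
          far_foci <- nrow(foci) == 0L ||
            min((foci[, 1] - cand[1])^2 + (foci[, 2] - cand[2])^2) >=
              foci_sep2
          if (far_blobs && far_foci) { ok <- TRUE; break }
        }
        if (!ok) stop("infeasible geometry: cannot place off-blob focus")
        foci <- rbind(foci, cand)
        on_blob <- c(on_blob, FALSE)
      }
    }
  }

  dna <- matrix(0, nr, nc)
  dna[inside] <- 1 # euchromatin baseline
  for (i in seq_len(nrow(blob_centres))) {
    dna <- add_bump(dna, blob_centres[i, ], params$blob_sigma_px,
                    params$blob_contrast - 1)
  }
  dam <- matrix(0, nr, nc)
  dam[inside] <- params$damage_background # diffuse nucleoplasmic staining
  for (i in seq_len(nrow(foci))) {
    dam <- add_bump(dam, foci[i, ], params$focus_sigma_px,
                    params$focus_amplitude)
  }
  dna <- gaussian_blur(dna, params$psf_sigma_px)
  dam <- gaussian_blur(dam, params$psf_sigma_px)

  detect <- function(ideal) {
    if (is.finite(params$photons_per_unit)) {
      counts <- matrix(rpois(length(ideal),
                             pmax(ideal, 0) * params$photons_per_unit),
                       nrow(ideal), ncol(ideal))
      counts + params$background_offset
    } else {
      ideal + params$background_offset
    }
  }
  ch1 <- detect(dam) # damage sampled first: keeps channel RNG streams stable
  ch2 <- detect(dna)

  truth <- list(blob_centers = blob_centres, foci_centers = foci,
                foci_on_blob = on_blob, p_het = params$p_het,
                nucleus_mask_true = inside, seed = params$seed)
  list(ch1 = channel_image(ch1, params$pixel_size_nm, "damage"),
       ch2 = channel_image(ch2, params$pixel_size_nm, "dna"),
       truth = truth)
}

#' Simulate a multi-nucleus field
#'
#' Tiles `n_cells` independently simulated nuclei on a rectangular grid
#' (one tile per nucleus, so placement never overlaps) and returns the
#' stitched two-channel field plus per-cell ground truth with coordinates
#' shifted into field space. Tile order is raster order, matching the
#' label numbering produced by [segment_nuclei()].
#'
#' @param n_cells Number of nuclei.
#' @param params A single `scene_params` (cell `i` uses `seed + i - 1`) or
#'   a list of `n_cells` `scene_params` objects used as-is.
#' @param seed Optional override of the base seed.
#' @return List with `ch1`, `ch2` (`channel_image`s), `truths` (list of
#'   per-cell truth records with field coordinates) and `truth_table`
#'   (data frame: cell, p_het, n_foci, n_on_blob, seed).
#' @export
simulate_field <- function(n_cells, params = scene_params(), seed = NULL) {
  n_cells <- as.integer(n_cells)
  if (inherits(params, "scene_params")) {
    base_seed <- if (is.null(seed)) params$seed else as.integer(seed)
    plist <- lapply(seq_len(n_cells), function(i) {
      p <- params; p$seed <- base_seed + i - 1L; p
    })
  } else {
    stopifnot(is.list(params), length(params) == n_cells)
    plist <- params
  }
  if (n_cells == 0L) {
    shp <- if (inherits(params, "scene_params")) params$image_shape
           else c(64L, 64L)
    z <- matrix(0, shp[1], shp[2])
    return(list(ch1 = channel_image(z, role = "damage"),
                ch2 = channel_image(z + 0, role = "dna"),
                truths = list(),
                truth_table = data.frame(cell = integer(), p_het = numeric(),
                                         n_foci = integer(),
                                         n_on_blob = integer(),
                                         seed = integer())))
  }
  cells <- lapply(plist, simulate_nucleus)
  tile <- dim(cells[[1]]$ch1$pixels)
  for (cell in cells) {
    if (!identical(dim(cell$ch1$pixels), tile)) {
      stop("all cells in a field must share image_shape")
    }
  }
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  ch1 <- matrix(0, nrow_grid * tile[1], ncol_grid * tile[2])
  ch2 <- matrix(0, nrow_grid * tile[1], ncol_grid * tile[2])
  truths <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    gi <- (i - 1L) %/% ncol_grid
    gj <- (i - 1L) %% ncol_grid
    rows <- gi * tile[1] + seq_len(tile[1])
    cols <- gj * tile[2] + seq_len(tile[2])
    ch1[rows, cols] <- cells[[i]]$ch1$pixels
    ch2[rows, cols] <- cells[[i]]$ch2$pixels
    tr <- cells[[i]]$truth
    off <- c(gi * tile[1], gj * tile[2])
    if (nrow(tr$blob_centers)) tr$blob_centers <-
      sweep(tr$blob_centers, 2, off, "+")
    if (nrow(tr$foci_centers)) tr$foci_centers <-
      sweep(tr$foci_centers, 2, off, "+")
    tr$tile_offset <- off
    tr$nucleus_mask_true <- NULL # field-size masks rebuilt on demand
    truths[[i]] <- tr
  }
  ps <- plist[[1]]$pixel_size_nm
  truth_table <- data.frame(
    cell = seq_len(n_cells),
    p_het = vapply(truths, function(t) t$p_het, numeric(1)),
    n_foci = vapply(truths, function(t) length(t$foci_on_blob), integer(1)),
    n_on_blob = vapply(truths, function(t) sum(t$foci_on_blob), integer(1)),
    seed = vapply(plist, function(p) p$seed, integer(1)))
  list(ch1 = channel_image(ch1, ps, "damage"),
       ch2 = channel_image(ch2, ps, "dna"),
       truths = truths, truth_table = truth_table)
}
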