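# ICCS measures colocalization from the amplitudes of spatial correlation
# functions instead of from segmented objects. For two channels a and b
# restricted to a nucleus mask, the correlation at lag (xi, eta) is
#   G_ab(xi, eta) = < dI_a(x, y) dI_b(x + xi, y + eta) > / (<I_a> <I_b>)
# with dI = I - <I>, all means over in-mask pixels, and the lag average
# running only over pixel pairs whose BOTH endpoints are in the mask
# (normalized per lag by the overlap count). A 2D Gaussian
# G0 * exp(-(xi^2 + eta^2) / w^2) + Ginf is fitted to each function; the
# colocalization fractions are ratios of fitted zero-lag amplitudes.

# --- internal FFT machinery ----------------------------------------------

# 2D FFT cross-correlation: returns S(lag) = sum_x a(x) * b(x + lag) for
# integer lags -L..L in both dimensions, linear (zero-padded, no wrap).
fft_corr_lags <- function(FA, FB, np, L) {
  s <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE)) / prod(np)
  # 1-based index n - k + 1 holds lag -k; reorder to -L..L
  pick <- function(n) c(seq_len(L + 1L), (n - L + 1L):n)
  ord <- c((L + 2L):(2L * L + 1L), seq_len(L + 1L))
  m <- s[pick(np[1]), pick(np[2]), drop = FALSE]
  m[ord, ord, drop = FALSE]
}

pad_to <- function(m, np) {
  out <- matrix(0, np[1], np[2])
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Compute correlation functions for channels cropped to the region bounding
# box. `pairs` selects which of auto1/auto2/cross to compute.
masked_corr_core <- function(A, B, W, max_lag, min_overlap,
                             pairs = c("auto1", "auto2", "cross")) {
  n_px <- sum(W)
  mA <- mean(A[W]); mB <- mean(B[W])
  Ac <- (A - mA) * W
  Bc <- (B - mB) * W
  L <- as.integer(max_lag)
  np <- c(stats::nextn(nrow(W) + L, c(2, 3, 5)),
          stats::nextn(ncol(W) + L, c(2, 3, 5)))
  FW <- stats::fft(pad_to(W * 1, np))
  Nlag <- round(fft_corr_lags(FW, FW, np, L))
  usable <- Nlag >= min_overlap
  lags <- -L:L
  out <- list()
  FA <- FB <- NULL
  if (any(c("auto1", "cross") %in% pairs)) FA <- stats::fft(pad_to(Ac, np))
  if (any(c("auto2", "cross") %in% pairs)) FB <- stats::fft(pad_to(Bc, np))
  mk <- function(S, pair, mu2) {
    G <- (S / ifelse(Nlag > 0, Nlag, NA_real_)) / mu2
    if (pair != "cross") {
      # autocorrelation is even; enforce G(xi,eta) = G(-xi,-eta) exactly
      # (the FFT result is symmetric only to rounding)
      n <- 2L * L + 1L
      G <- (G + G[n:1, n:1]) / 2
    }
    G[!usable] <- NA_real_
    structure(list(values = G, lags = lags, pair = pair,
                   n_pixels_used = n_px, overlap_counts = Nlag,
                   usable = usable),
              class = "correlation_fn")
  }
  if ("auto1" %in% pairs) {
    out$auto1 <- mk(fft_corr_lags(FA, FA, np, L), "auto1", mA * mA)
  }
  if ("auto2" %in% pairs) {
    out$auto2 <- mk(fft_corr_lags(FB, FB, np, L), "auto2", mB * mB)
  }
  if ("cross" %in% pairs) {
    out$cross <- mk(fft_corr_lags(FA, FB, np, L), "cross", mA * mB)
  }
  out
}

crop_bbox <- function(region) {
  rr <- range(which(rowSums(region) > 0))
  cc <- range(which(colSums(region) > 0))
  list(rows = rr[1]:rr[2], cols = cc[1]:cc[2])
}

#' Masked spatial correlation function
#'
#' Computes the normalized spatial auto- or cross-correlation of two
#' channels over an irregular region (typically one nucleus), at integer
#' lags `-max_lag..max_lag`. Means are taken over in-region pixels; each
#' lag is averaged over pixel pairs with both endpoints in the region and
#' normalized by that overlap count, so the nucleus silhouette contributes
#' no spurious correlation (unlike zero-padded estimators). Lags whose
#' overlap count falls below `min_overlap` pairs are marked unusable
#' (`NA`).
#'
#' The FFT implementation agrees with a direct double-loop sum to near
#' machine precision.
#'
#' @param imgA,imgB `channel_image`s or matrices of identical shape. Use
#'   the same image twice for an autocorrelation.
#' @param region Logical mask (same shape) selecting the analysis region.
#' @param max_lag Maximum lag in pixels; must be below half the region
#'   bounding-box extent.
#' @param min_overlap Minimum number of in-region pixel pairs for a lag to
#'   be usable (default 100).
#' @param pair Label stored on the result: `"auto1"`, `"auto2"` or
#'   `"cross"`. Purely descriptive.
#' @return A `correlation_fn`: `values` (matrix over lags), `lags`,
#'   `pair`, `n_pixels_used`, `overlap_counts`, `usable`.
#' @export
masked_correlation <- function(imgA, imgB, region, max_lag = 32L,
                               min_overlap = 100L,
                               pair = c("cross", "auto1", "auto2")) {
  pair <- match.arg(pair)
  A <- as_pixels(imgA); B <- as_pixels(imgB)
  region <- as_binary(region)
  if (!identical(dim(A), dim(B)) || !identical(dim(A), dim(region))) {
    stop("images and region must share shape")
  }
  if (!any(region)) stop("region is empty")
  if (sum(region) < min_overlap) stop("region too small for ICCS")
  bb <- crop_bbox(region)
  W <- region[bb$rows, bb$cols, drop = FALSE]
  if (max_lag >= min(dim(W)) / 2) {
    stop("max_lag must be below half the region bounding-box extent")
  }
  res <- masked_corr_core(A[bb$rows, bb$cols, drop = FALSE],
                          B[bb$rows, bb$cols, drop = FALSE],
                          W, max_lag, min_overlap,
                          pairs = if (pair == "cross") "cross" else pair)
  out <- res[[1]]
  out$pair <- pair
  out
}

#' @export
print.correlation_fn <- function(x, ...) {
  L <- max(x$lags)
  cat(sprintf("<correlation_fn> pair = %s, lags -%d..%d, %d px used\n",
              x$pair, L, L, x$n_pixels_used))
  cat(sprintf("  G(0,0) = %.4g, usable lags: %d/%d\n",
              x$values[L + 1L, L + 1L], sum(x$usable), length(x$usable)))
  invisible(x)
}

# --- Gaussian amplitude fitting ------------------------------------------

#' Fit a 2D Gaussian to a correlation function
#'
#' Least-squares fit of `G0 * exp(-(xi^2+eta^2)/w^2) + Ginf` to the usable
#' lags within `fit_range_px` of the origin. For autocorrelations the
#' (0,0) lag should be excluded (`exclude_zero_lag = TRUE`): uncorrelated
#' shot/detector noise appears only there, and excluding it makes `G0` the
#' amplitude extrapolated to zero lag of the structural correlation. Cross-
#' correlations have no such spike, so (0,0) is kept.
#'
#' The fit is a profiled least squares: for each candidate width the
#' amplitude and offset solve a linear system, and the width is found by a
#' deterministic 1D minimization over `w_bounds`. There is no iterative
#' multistart and no dependence on random initialization.
#'
#' @param corr A `correlation_fn`.
#' @param exclude_zero_lag Drop the (0,0) lag before fitting.
#' @param fit_range_px Radius (in lag pixels) of the disc of lags used.
#' @param w_bounds Width search interval in pixels (default `c(0.5, 30)`).
#' @param min_lags Minimum usable lags required (default 8).
#' @return A `gaussian_fit`: `amplitude_G0`, `width_w_px`, `offset_Ginf`,
#'   `fit_range_px`, `residual_norm`, `n_lags_used`, `converged`, `reason`.
#' @export
fit_gaussian <- function(corr, exclude_zero_lag = FALSE,
                         fit_range_px = NULL, w_bounds = c(0.5, 30),
                         min_lags = 8L) {
  stopifnot(inherits(corr, "correlation_fn"))
  L <- max(corr$lags)
  if (is.null(fit_range_px)) fit_range_px <- L
  xi <- matrix(corr$lags, 2L * L + 1L, 2L * L + 1L)
  eta <- t(xi)
  r2 <- xi^2 + eta^2
  sel <- corr$usable & is.finite(corr$values) & r2 <= fit_range_px^2
  if (exclude_zero_lag) sel[L + 1L, L + 1L] <- FALSE
  y <- corr$values[sel]
  r2s <- r2[sel]
  fail <- function(reason) {
    structure(list(amplitude_G0 = NA_real_, width_w_px = NA_real_,
                   offset_Ginf = NA_real_, fit_range_px = fit_range_px,
                   residual_norm = NA_real_, n_lags_used = length(y),
                   converged = FALSE, reason = reason),
              class = "gaussian_fit")
  }
  if (length(y) < min_lags) return(fail("insufficient usable lags"))
  # profiled linear LS in (G0, Ginf) for fixed w
  solve_w <- function(w) {
    x <- exp(-r2s / w^2)
    mx <- mean(x); my <- mean(y)
    vx <- sum((x - mx)^2)
    if (vx < 1e-300) {
      g0 <- 0; gi <- my
    } else {
      g0 <- sum((x - mx) * (y - my)) / vx
      gi <- my - g0 * mx
    }
    res <- y - g0 * x - gi
    list(sse = sum(res^2), g0 = g0, gi = gi)
  }
  opt <- stats::optimize(function(w) solve_w(w)$sse,
                         interval = w_bounds, tol = 1e-6)
  w <- opt$minimum
  sol <- solve_w(w)
  if (!is.finite(sol$g0) || !is.finite(sol$gi) || !is.finite(w)) {
    return(fail("non-finite fit parameters"))
  }
  structure(list(amplitude_G0 = sol$g0, width_w_px = w,
                 offset_Ginf = sol$gi, fit_range_px = fit_range_px,
                 residual_norm = sqrt(sol$sse), n_lags_used = length(y),
                 converged = TRUE, reason = ""),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<gaussian_fit> G0 = %.4g, w = %.3g px, Ginf = %.4g (%d lags, range %.3g px)\n",
      x$amplitude_G0, x$width_w_px, x$offset_Ginf, x$n_lags_used,
      x$fit_range_px))
  } else {
    cat(sprintf("<gaussian_fit> not converged: %s\n", x$reason))
  }
  invisible(x)
}

#' Colocalization fractions from fitted amplitudes
#'
#' `f1 = G0_cross / G0_auto2` and `f2 = G0_cross / G0_auto1`: the fraction
#' of the signal in channel 1 (2) that is cross-correlated with the other
#' channel. Values run from 1 (complete colocalization) through 0 (no
#' cross-correlation) to -1 (maximal anti-correlation / repulsion); the
#' ratio is not clamped. Auto amplitudes must be positive and all three
#' fits converged, otherwise the result is flagged invalid.
#'
#' @param fit_cross,fit_auto1,fit_auto2 `gaussian_fit` objects.
#' @return List: `f1`, `f2`, `valid`, `reason`.
#' @export
colocalization_fractions <- function(fit_cross, fit_auto1, fit_auto2) {
  fits <- list(fit_cross, fit_auto1, fit_auto2)
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    return(list(f1 = NA_real_, f2 = NA_real_, valid = FALSE,
                reason = "fit not converged"))
  }
  if (fit_auto1$amplitude_G0 <= 0 || fit_auto2$amplitude_G0 <= 0) {
    return(list(f1 = NA_real_, f2 = NA_real_, valid = FALSE,
                reason = "nonpositive auto amplitude"))
  }
  list(f1 = fit_cross$amplitude_G0 / fit_auto2$amplitude_G0,
       f2 = fit_cross$amplitude_G0 / fit_auto1$amplitude_G0,
       valid = TRUE, reason = "")
}

#' ICCS analysis parameters
#'
#' @param max_lag Maximum correlation lag in pixels (default 32, about
#'   1.4 um at 45 nm/px: covers focus and heterochromatin-domain scales
#'   while keeping per-lag overlap counts high).
#' @param k_range Fit-range multiplier: the next fit range is
#'   `k_range * w` (default 3, i.e. the fit window tracks three fitted
#'   widths).
#' @param range_tol_px Convergence tolerance on the fit range (default
#'   0.5 px).
#' @param max_iter Maximum range iterations (default 10).
#' @param min_overlap Minimum pixel pairs per usable lag (default 100).
#' @param w_bounds Acceptable fitted width interval in px (default
#'   `c(0.5, 30)`): narrower than half the PSF or wider than the lag
#'   window means the fit latched onto noise or trend.
#' @param f_limit Absolute bound on plausible fractions (default 1.2);
#'   beyond it the cell is flagged invalid.
#' @param initial_range_px First fit range (default `max_lag`).
#' @return Named list of parameters.
#' @export
iccs_params <- function(max_lag = 32L, k_range = 3, range_tol_px = 0.5,
                        max_iter = 10L, min_overlap = 100L,
                        w_bounds = c(0.5, 30), f_limit = 1.2,
                        initial_range_px = NULL) {
  list(max_lag = as.integer(max_lag), k_range = k_range,
       range_tol_px = range_tol_px, max_iter = as.integer(max_iter),
       min_overlap = as.integer(min_overlap), w_bounds = w_bounds,
       f_limit = f_limit,
       initial_range_px = if (is.null(initial_range_px)) as.integer(max_lag)
                          else initial_range_px)
}

# Iteratively refit with range = k * w until the range stabilizes.
iterate_fit <- function(corr, exclude_zero_lag, params) {
  rng <- min(params$initial_range_px, max(corr$lags))
  fit <- fit_gaussian(corr, exclude_zero_lag, rng,
                      w_bounds = params$w_bounds)
  for (i in seq_len(params$max_iter)) {
    if (!fit$converged) break
    new_rng <- min(max(params$k_range * fit$width_w_px, 3), max(corr$lags))
    if (abs(new_rng - rng) < params$range_tol_px) break
    rng <- new_rng
    fit <- fit_gaussian(corr, exclude_zero_lag, rng,
                        w_bounds = params$w_bounds)
  }
  fit
}

fit_field <- function(fit, what) {
  if (is.null(fit) || !isTRUE(fit$converged)) NA_real_ else fit[[what]]
}

#' Per-nucleus ICCS colocalization over a segmented field
#'
#' For every nucleus in the count mask: crop the bounding box, compute the
#' two autocorrelations and the cross-correlation over the nucleus mask,
#' fit each with an iteratively shrinking range (`range <- k * w` until it
#' moves less than `range_tol_px`, at most `max_iter` rounds), and form
#' the fractions f1 and f2. Autocorrelation fits exclude the (0,0) noise
#' spike; the cross fit keeps it. Per-nucleus failures are recorded
#' (`valid = FALSE`, with a reason) and never abort the batch.
#'
#' Quality control: a cell is valid when all three fits converged, both
#' auto amplitudes are positive, all widths lie inside `w_bounds` (not
#' pinned at a bound), and `|f1|, |f2| <= f_limit`.
#'
#' @param ch1 Background-subtracted damage `channel_image` (or matrix).
#' @param ch2 Background-subtracted DNA `channel_image` (or matrix).
#' @param nuclei A `count_mask`.
#' @param params See [iccs_params()].
#' @return Data frame, one row per nucleus: `cell_id`, `f1`, `f2`,
#'   `w_cross_px`, `w_auto1_px`, `w_auto2_px`, `G0_cross`, `G0_auto1`,
#'   `G0_auto2`, `valid`, `reason`.
#' @export
per_cell_iccs <- function(ch1, ch2, nuclei, params = iccs_params()) {
  stopifnot(inherits(nuclei, "count_mask"))
  A <- as_pixels(ch1); B <- as_pixels(ch2)
  if (!identical(dim(A), dim(B)) || !identical(dim(A), dim(nuclei$labels))) {
    stop("channels and count mask must share shape")
  }
  rows <- lapply(seq_len(nuclei$n_objects), function(id) {
    cell <- single_cell_iccs(A, B, nuclei$labels == id, params)
    cbind(data.frame(cell_id = id), as.data.frame(cell))
  })
  if (length(rows) == 0L) {
    return(data.frame(cell_id = integer(), f1 = numeric(), f2 = numeric(),
                      w_cross_px = numeric(), w_auto1_px = numeric(),
                      w_auto2_px = numeric(), G0_cross = numeric(),
                      G0_auto1 = numeric(), G0_auto2 = numeric(),
                      valid = logical(), reason = character()))
  }
  do.call(rbind, rows)
}

# One nucleus; returns a plain list of scalar results.
single_cell_iccs <- function(A, B, region, params) {
  empty <- function(reason) {
    list(f1 = NA_real_, f2 = NA_real_, w_cross_px = NA_real_,
         w_auto1_px = NA_real_, w_auto2_px = NA_real_,
         G0_cross = NA_real_, G0_auto1 = NA_real_, G0_auto2 = NA_real_,
         valid = FALSE, reason = reason)
  }
  out <- tryCatch({
    if (sum(region) < params$min_overlap) stop("region too small for ICCS")
    bb <- crop_bbox(region)
    W <- region[bb$rows, bb$cols, drop = FALSE]
    L <- min(params$max_lag, as.integer(floor((min(dim(W)) - 1) / 2)))
    if (L < 4L) stop("region too small for ICCS")
    cf <- masked_corr_core(A[bb$rows, bb$cols, drop = FALSE],
                           B[bb$rows, bb$cols, drop = FALSE],
                           W, L, params$min_overlap)
    f_a1 <- iterate_fit(cf$auto1, exclude_zero_lag = TRUE, params)
    f_a2 <- iterate_fit(cf$auto2, exclude_zero_lag = TRUE, params)
    f_x  <- iterate_fit(cf$cross, exclude_zero_lag = FALSE, params)
    fr <- colocalization_fractions(f_x, f_a1, f_a2)
    widths <- c(fit_field(f_x, "width_w_px"), fit_field(f_a1, "width_w_px"),
                fit_field(f_a2, "width_w_px"))
    valid <- fr$valid
    reason <- fr$reason
    eps <- 1e-3
    if (valid && any(!is.finite(widths) |
                     widths <= params$w_bounds[1] + eps |
                     widths >= params$w_bounds[2] - eps)) {
      valid <- FALSE; reason <- "width out of range"
    }
    if (valid && (abs(fr$f1) > params$f_limit ||
                  abs(fr$f2) > params$f_limit)) {
      valid <- FALSE; reason <- "fraction out of range"
    }
    list(f1 = fr$f1, f2 = fr$f2,
         w_cross_px = fit_field(f_x, "width_w_px"),
         w_auto1_px = fit_field(f_a1, "width_w_px"),
         w_auto2_px = fit_field(f_a2, "width_w_px"),
         G0_cross = fit_field(f_x, "amplitude_G0"),
         G0_auto1 = fit_field(f_a1, "amplitude_G0"),
         G0_auto2 = fit_field(f_a2, "amplitude_G0"),
         valid = valid, reason = reason)
  }, error = function(e) empty(conditionMessage(e)))
  out
}
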