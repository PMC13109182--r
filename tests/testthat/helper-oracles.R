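# Independent oracles (deliberately naive R implementations) and small
# scene builders shared across the test files.

# Direct double-loop masked correlation; O(n^2 L^2), for tiny regions only.
brute_masked_corr <- function(A, B, W, L) {
  mA <- mean(A[W]); mB <- mean(B[W])
  G <- matrix(NA_real_, 2 * L + 1, 2 * L + 1)
  N <- matrix(0L, 2 * L + 1, 2 * L + 1)
  for (xi in -L:L) for (eta in -L:L) {
    s <- 0; n <- 0L
    for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
      i2 <- i + xi; j2 <- j + eta
      if (i2 >= 1 && j2 >= 1 && i2 <= nrow(A) && j2 <= ncol(A) &&
          W[i, j] && W[i2, j2]) {
        s <- s + (A[i, j] - mA) * (B[i2, j2] - mB)
        n <- n + 1L
      }
    }
    G[xi + L + 1, eta + L + 1] <- if (n > 0) (s / n) / (mA * mB) else NA
    N[xi + L + 1, eta + L + 1] <- n
  }
  list(G = G, N = N)
}

# Recursive-free flood-fill labelling oracle, 8-connectivity, raster order.
flood_label_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i0, j0)); lab[i0, j0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Exhaustive isodata fixed-point scan over every bin boundary.
isodata_scan_oracle <- function(px, n_bins = 256L) {
  lo <- min(px); hi <- max(px)
  width <- (hi - lo) / n_bins
  fixed <- c()
  for (k in 1:(n_bins - 1L)) {
    t <- lo + k * width
    lo_cls <- px[px <= t]; hi_cls <- px[px > t]
    if (!length(lo_cls) || !length(hi_cls)) next
    t_next <- (mean(lo_cls) + mean(hi_cls)) / 2
    if (abs(t_next - t) <= width) fixed <- c(fixed, t)
  }
  fixed
}

# Rolling-ball background by direct min/max loops with the spherical
# structuring element (independent of the compiled path).
ball_background_oracle <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- expand.grid(di = -radius:radius, dj = -radius:radius)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$di^2 - offs$dj^2)
  stage <- function(src, sign) {
    out <- matrix(sign * Inf, nr, nc) # erosion starts at +Inf, dilation -Inf
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]; h <- offs$h[k]
      ri <- max(1, 1 - di):min(nr, nr - di)
      cj <- max(1, 1 - dj):min(nc, nc - dj)
      shifted <- src[ri + di, cj + dj, drop = FALSE] - sign * h
      cur <- out[ri, cj, drop = FALSE]
      out[ri, cj] <- if (sign > 0) pmin(cur, shifted) else pmax(cur, shifted)
    }
    out
  }
  stage(stage(img, 1), -1) # erode then dilate
}

# A field of bright discs on a dark background.
disc_scene <- function(shape, centres, radius, fg = 200, bg = 10) {
  img <- matrix(bg, shape[1], shape[2])
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(shape[1])) {
      d2 <- radius^2 - (i - centres[k, 1])^2
      if (d2 >= 0) {
        dj <- sqrt(d2)
        cols <- max(1, ceiling(centres[k, 2] - dj)):min(shape[2],
                                                        floor(centres[k, 2] + dj))
        img[i, cols] <- fg
      }
    }
  }
  img
}

# Wrap a matrix of correlation values as a correlation_fn object.
corr_object <- function(values, pair = "cross", n_px = 10000L) {
  L <- (nrow(values) - 1L) %/% 2L
  structure(list(values = values, lags = -L:L, pair = pair,
                 n_pixels_used = n_px,
                 overlap_counts = matrix(n_px, nrow(values), ncol(values)),
                 usable = matrix(TRUE, nrow(values), ncol(values))),
            class = "correlation_fn")
}

analytic_corr <- function(G0, w, Ginf, L) {
  r2 <- outer((-L:L)^2, (-L:L)^2, "+")
  corr_object(G0 * exp(-r2 / w^2) + Ginf)
}

# Full per-nucleus pipeline over a batch of single-cell simulations;
# returns the row-bound cells table.
run_sim_cells <- function(seeds, cfg = run_config(foci_threshold = 30), ...) {
  do.call(rbind, lapply(seeds, function(s) {
    sim <- simulate_nucleus(scene_params(seed = s, ...))
    analyze_field(sim$ch1, sim$ch2, cfg,
                  image_id = sprintf("seed%03d", s))$cells
  }))
}
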