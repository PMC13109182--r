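test_that("masked correlation matches definition and the brute-force oracle", {
  set.seed(101)
  A <- matrix(runif(576, 1, 5), 24)
  B <- matrix(runif(576, 1, 5), 24)
  W <- matrix(TRUE, 24, 24); W[1:4, 1:6] <- FALSE; W[20:24, 22:24] <- FALSE

  # zero-lag autocorrelation equals variance/mean^2 exactly
  ca <- masked_correlation(A, A, W, max_lag = 5, min_overlap = 1,
                           pair = "auto1")
  v <- A[W]
  expect_equal(ca$values[6, 6], mean((v - mean(v))^2) / mean(v)^2,
               tolerance = 1e-12)
  expect_equal(ca$overlap_counts[6, 6], sum(W))
  expect_equal(ca$n_pixels_used, sum(W))
  # auto symmetry G(xi,eta) = G(-xi,-eta)
  expect_identical(ca$values, ca$values[11:1, 11:1])

  bf <- brute_masked_corr(A, B, W, 5)
  cf <- masked_correlation(A, B, W, max_lag = 5, min_overlap = 1)
  expect_true(all(cf$overlap_counts == bf$N))
  expect_lt(max(abs(cf$values - bf$G) / pmax(abs(bf$G), 1e-12)), 1e-10)

  expect_error(masked_correlation(A, B, W & FALSE, 5), "empty")
  expect_error(masked_correlation(A, B, W, max_lag = 5, min_overlap = 1e5),
               "too small")
  expect_error(masked_correlation(A, B, W, max_lag = 15, min_overlap = 1),
               "max_lag")
})

test_that("cross-correlation of a shuffled channel is consistent with zero", {
  set.seed(202)
  A <- matrix(rexp(1024, 1 / 10), 32)
  B <- matrix(rexp(1024, 1 / 10), 32)
  W <- matrix(TRUE, 32, 32)
  nulls <- replicate(60, {
    Bs <- B
    Bs[W] <- sample(B[W])
    masked_correlation(A, Bs, W, max_lag = 4, min_overlap = 1)$values[5, 5]
  })
  obs <- masked_correlation(A, B, W, max_lag = 4, min_overlap = 1)$values[5, 5]
  se <- sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls)), 3 * sd(nulls)) # null centred on zero
  expect_lt(abs(obs), 4 * sd(nulls))         # independent channels too
  expect_gt(se, 0)
})

test_that("Gaussian fit recovers analytic surfaces and ignores the zero-lag spike", {
  corr <- analytic_corr(G0 = 0.5, w = 3, Ginf = 0.01, L = 20)
  f <- fit_gaussian(corr)
  expect_true(f$converged)
  expect_lt(abs(f$amplitude_G0 - 0.5) / 0.5, 0.01)
  expect_lt(abs(f$width_w_px - 3) / 3, 0.01)
  expect_lt(abs(f$offset_Ginf - 0.01) / 0.01, 0.01)

  spiked <- corr
  spiked$values[21, 21] <- spiked$values[21, 21] + 0.5
  fs <- fit_gaussian(spiked, exclude_zero_lag = TRUE)
  expect_lt(abs(fs$amplitude_G0 - 0.5) / 0.5, 0.02)

  # all-zero correlation grid: amplitude zero, still converged
  f0 <- fit_gaussian(corr_object(matrix(0, 41, 41)))
  expect_true(f0$converged)
  expect_lt(abs(f0$amplitude_G0), 1e-8)

  # insufficient usable lags
  tiny <- corr_object(matrix(0.1, 41, 41))
  tiny$usable[] <- FALSE; tiny$usable[21, 21] <- TRUE
  expect_false(fit_gaussian(tiny)$converged)
})

test_that("colocalization fractions are amplitude ratios with validity rules", {
  f <- function(G0) structure(list(amplitude_G0 = G0, width_w_px = 3,
                                   offset_Ginf = 0, converged = TRUE),
                              class = "gaussian_fit")
  expect_equal(colocalization_fractions(f(0.4), f(0.4), f(0.4))[c("f1", "f2")],
               list(f1 = 1, f2 = 1))
  expect_equal(colocalization_fractions(f(0), f(0.4), f(0.2))[c("f1", "f2")],
               list(f1 = 0, f2 = 0))
  r <- colocalization_fractions(f(-0.1), f(0.4), f(0.2))
  expect_equal(r$f1, -0.5)
  expect_equal(r$f2, -0.25)
  expect_true(r$valid)
  expect_false(colocalization_fractions(f(0.1), f(-0.4), f(0.2))$valid)
  bad <- f(0.1); bad$converged <- FALSE
  expect_false(colocalization_fractions(f(0.1), bad, f(0.2))$valid)
})

test_that("per-cell ICCS: identity, rescaling and translation invariance", {
  sim <- simulate_nucleus(scene_params(seed = 5))
  seg <- segment_nuclei(sim$ch2, min_area_px = 5000)
  s1 <- rolling_ball_subtract(sim$ch1$pixels, 10)
  s2 <- rolling_ball_subtract(sim$ch2$pixels, 10)

  # identical channels: complete colocalization
  rid <- per_cell_iccs(s2, s2, seg)
  expect_true(rid$valid)
  expect_lt(abs(rid$f1 - 1), 0.05)
  expect_equal(rid$f1, rid$f2)

  # invariance to linear rescaling of either channel
  r0 <- per_cell_iccs(s1, s2, seg)
  r_scaled <- per_cell_iccs(s1 * 7.3, s2 * 0.2, seg)
  expect_equal(r0$f1, r_scaled$f1, tolerance = 1e-9)
  expect_equal(r0$f2, r_scaled$f2, tolerance = 1e-9)

  # invariance to translation of the nucleus within the field
  pad <- function(m, dr, dc) {
    out <- matrix(0, nrow(m) + 40, ncol(m) + 40)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  lab <- seg$labels
  r_shift <- per_cell_iccs(pad(s1, 31, 7), pad(s2, 31, 7),
                           count_mask(pad(lab, 31, 7)))
  expect_equal(r0$f1, r_shift$f1, tolerance = 1e-9)

  # failures are captured per cell, never thrown
  small <- count_mask(matrix(c(rep(0L, 95), rep(1L, 5)), 10))
  rr <- per_cell_iccs(matrix(1, 10, 10), matrix(1, 10, 10), small)
  expect_false(rr$valid)
  expect_match(rr$reason, "too small")
})
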