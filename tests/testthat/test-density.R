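test_that("normalize_dna divides by the in-nucleus maximum and is scale invariant", {
  img <- matrix(0, 8, 8)
  nuc <- matrix(FALSE, 8, 8); nuc[3:5, 3:5] <- TRUE

  img[nuc] <- 500
  expect_true(all(normalize_dna(img, nuc)$values[nuc] == 1))

  img2 <- matrix(0, 8, 8)
  img2[3, 3] <- 10; img2[3, 4] <- 20; img2[3, 5] <- 40
  nuc2 <- matrix(FALSE, 8, 8); nuc2[3, 3:5] <- TRUE
  n2 <- normalize_dna(img2, nuc2)
  expect_equal(n2$values[3, 3:5], c(0.25, 0.5, 1.0))

  for (c_scale in c(0.01, 3, 1e4)) {
    ns <- normalize_dna(img2 * c_scale, nuc2)
    expect_equal(ns$values, n2$values)
  }
  expect_true(all(is.na(n2$values[!nuc2])))
  expect_error(normalize_dna(matrix(0, 8, 8), nuc2), "empty nucleus signal")
})

test_that("dna_density averages normalized intensity over the damage ROI", {
  vals <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0),
                 3, byrow = TRUE)
  nuc <- matrix(TRUE, 3, 3)

  top <- matrix(FALSE, 3, 3); top[1, ] <- TRUE
  expect_equal(dna_density(vals, nuc, top)$dna_density, 0.2)

  # ROI = the maximum pixel
  mx <- matrix(FALSE, 3, 3); mx[3, 3] <- TRUE
  expect_equal(dna_density(vals, nuc, mx)$dna_density, 1.0)

  # uniform nucleus: any nonempty ROI gives 1
  uni <- normalize_dna(matrix(7, 3, 3), nuc)
  expect_equal(dna_density(uni, nuc, top)$dna_density, 1.0)

  # empty ROI: undefined and flagged, not an error
  none <- matrix(FALSE, 3, 3)
  d <- dna_density(vals, nuc, none)
  expect_true(is.na(d$dna_density))
  expect_identical(d$roi_area_px, 0L)
  expect_identical(d$flag, "no foci")
})

test_that("dna_density is bounded and monotone under ROI relocation", {
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(rexp(400, 1 / 30), 20)
    nuc <- matrix(FALSE, 20, 20); nuc[4:17, 4:17] <- TRUE
    nrm <- normalize_dna(img, nuc)
    k <- 12
    ord <- order(nrm$values[nuc])
    idx <- which(nuc)
    lo <- matrix(FALSE, 20, 20); lo[idx[ord[seq_len(k)]]] <- TRUE
    hi <- matrix(FALSE, 20, 20); hi[idx[rev(ord)[seq_len(k)]]] <- TRUE
    d_lo <- dna_density(nrm, nuc, lo)$dna_density
    d_hi <- dna_density(nrm, nuc, hi)$dna_density
    expect_gte(d_hi, d_lo)
    expect_gte(d_lo, 0); expect_lte(d_hi, 1)
  }
})
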