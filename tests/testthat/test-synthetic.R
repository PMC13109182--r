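test_that("simulation is bit-identical for fixed parameters and seed", {
  p <- scene_params(seed = 99)
  a <- simulate_nucleus(p)
  b <- simulate_nucleus(p)
  expect_identical(a$ch1$pixels, b$ch1$pixels)
  expect_identical(a$ch2$pixels, b$ch2$pixels)
  expect_identical(a$truth, b$truth)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulate_nucleus(p)); after <- runif(3)
  expect_identical(before, after)
})

test_that("ground truth matches the scene construction", {
  p1 <- scene_params(p_het = 1, photons_per_unit = Inf, seed = 3)
  sim <- simulate_nucleus(p1)
  tr <- sim$truth
  expect_identical(length(tr$foci_on_blob), 5L)
  expect_true(all(tr$foci_on_blob))
  # every focus centre coincides with a blob centre
  for (i in seq_len(nrow(tr$foci_centers))) {
    d <- sqrt((tr$blob_centers[, 1] - tr$foci_centers[i, 1])^2 +
              (tr$blob_centers[, 2] - tr$foci_centers[i, 2])^2)
    expect_lt(min(d), 1e-12)
  }
  # off-blob foci keep their exclusion distance
  p0 <- scene_params(p_het = 0, seed = 4)
  tr0 <- simulate_nucleus(p0)$truth
  expect_false(any(tr0$foci_on_blob))
  for (i in seq_len(nrow(tr0$foci_centers))) {
    d <- sqrt((tr0$blob_centers[, 1] - tr0$foci_centers[i, 1])^2 +
              (tr0$blob_centers[, 2] - tr0$foci_centers[i, 2])^2)
    expect_gte(min(d), 2 * p0$blob_sigma_px)
  }
  # law of large numbers on the on-blob fraction
  hits <- unlist(lapply(1:40, function(s) {
    simulate_nucleus(scene_params(p_het = 0.5, n_foci = 4, seed = s,
                                  photons_per_unit = Inf))$truth$foci_on_blob
  }))
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / length(hits)))
})

test_that("off-blob damage sits in below-average DNA surroundings", {
  # averaged over seeds: mean normalized DNA over the true foci ROI is
  # below the nucleus-wide mean when placement avoids blobs
  diffs <- vapply(1:15, function(s) {
    sim <- simulate_nucleus(scene_params(p_het = 0, seed = s))
    seg <- segment_nuclei(sim$ch2, min_area_px = 5000)
    s1 <- rolling_ball_subtract(sim$ch1$pixels, 10)
    s2 <- rolling_ball_subtract(sim$ch2$pixels, 10)
    reg <- seg$labels == 1
    nrm <- normalize_dna(s2, reg)
    d <- dna_density(nrm, reg, damage_mask(s1, 30))$dna_density
    d - mean(nrm$values[reg])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
})

test_that("simulate_field tiles cells, carries truth and supports n_cells = 0", {
  fld <- simulate_field(10, scene_params(seed = 50))
  seg <- segment_nuclei(fld$ch2, min_area_px = 5000)
  expect_identical(seg$n_objects, 10L)
  expect_identical(nrow(fld$truth_table), 10L)
  expect_identical(fld$truth_table$n_foci, rep(5L, 10))
  # truth coordinates land inside segmented nuclei, one nucleus per cell
  # (label numbers follow raster order of first pixel, not tile order)
  hit <- vapply(fld$truths, function(tr) {
    ctr <- round(colMeans(tr$foci_centers)) + 1
    seg$labels[ctr[1], ctr[2]]
  }, integer(1))
  expect_identical(sort(hit), 1:10)
  empty <- simulate_field(0, scene_params())
  expect_identical(length(empty$truths), 0L)
  expect_identical(nrow(empty$truth_table), 0L)

  # disjoint seeds give different layouts
  f2 <- simulate_field(2, scene_params(seed = 1))
  f3 <- simulate_field(2, scene_params(seed = 1000))
  expect_false(identical(f2$ch1$pixels, f3$ch1$pixels))
})
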