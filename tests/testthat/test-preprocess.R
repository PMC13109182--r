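test_that("isodata threshold matches the two-level and fixed-point oracles", {
  # symmetric two-level histogram: threshold at the midpoint
  img <- matrix(c(rep(10, 512), rep(110, 512)), 32)
  t2 <- isodata_threshold(img)
  expect_lt(abs(t2 - 60), (110 - 10) / 256 + 1e-9)

  # tri-level image: agree with the exhaustive fixed-point scan
  set.seed(11)
  vals <- sample(c(rep(0, 900), rep(100, 50), rep(200, 50)))
  img3 <- matrix(vals, 25)
  fixed <- isodata_scan_oracle(as.vector(img3))
  t3 <- isodata_threshold(img3)
  expect_true(min(abs(fixed - t3)) <= 200 / 256 + 1e-9)

  # any image: both classes nonempty at the returned threshold
  for (s in 1:5) {
    set.seed(s)
    im <- matrix(rexp(400, 1 / 50), 20)
    t <- isodata_threshold(im)
    expect_gt(sum(im > t), 0)
    expect_gt(sum(im <= t), 0)
  }

  expect_error(isodata_threshold(matrix(5, 8, 8)), "degenerate")
})

test_that("segment_nuclei finds discs, filters by area and matches the flood-fill oracle", {
  centres <- rbind(c(16, 16), c(16, 48), c(48, 32))
  img <- disc_scene(c(64, 64), centres, radius = 7)
  seg <- segment_nuclei(img, min_area_px = 50, exclude_border = TRUE)
  expect_s3_class(seg, "count_mask")
  expect_identical(seg$n_objects, 3L)

  # min_area dominates
  expect_identical(segment_nuclei(img, min_area_px = 1000)$n_objects, 0L)

  # labels equal the oracle up to renumbering (random blobs, no filtering)
  set.seed(21)
  noise <- matrix(runif(64 * 64), 64)
  blobby <- disc_scene(c(64, 64), matrix(c(10, 10, 30, 40, 52, 20), 3,
                                         byrow = TRUE), radius = 5) + noise
  seg2 <- segment_nuclei(blobby, min_area_px = 1, exclude_border = FALSE)
  oracle <- flood_label_oracle(seg2$labels > 0L)
  # same partition: cross-tabulation is a permutation matrix
  tab <- table(seg2$labels[seg2$labels > 0], oracle[oracle > 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  # idempotence under relabelling: second run on same input is identical
  seg3 <- segment_nuclei(blobby, min_area_px = 1, exclude_border = FALSE)
  expect_identical(seg2$labels, seg3$labels)

  # hole filling: a ring segments as one solid object
  ring <- disc_scene(c(48, 48), matrix(c(24, 24), 1), radius = 12)
  ring[disc_scene(c(48, 48), matrix(c(24, 24), 1), radius = 5, fg = 1,
                  bg = 0) > 0] <- 10
  segr <- segment_nuclei(ring, min_area_px = 10)
  expect_identical(segr$n_objects, 1L)
  expect_true(all(segr$labels[disc_scene(c(48, 48), matrix(c(24, 24), 1),
                                         radius = 4, fg = 1, bg = 0) > 0] == 1L))

  # border exclusion
  edge <- disc_scene(c(40, 40), rbind(c(2, 20), c(20, 20)), radius = 6)
  expect_identical(segment_nuclei(edge, min_area_px = 10,
                                  exclude_border = TRUE)$n_objects, 1L)
  expect_identical(segment_nuclei(edge, min_area_px = 10,
                                  exclude_border = FALSE)$n_objects, 2L)
})

test_that("rolling-ball subtraction honours its contracts and the opening oracle", {
  # constant image goes to zero
  expect_true(all(rolling_ball_subtract(matrix(37, 40, 40), 10) == 0))

  # single-pixel spike mostly retained
  spike <- matrix(0, 41, 41); spike[21, 21] <- 1000
  out <- rolling_ball_subtract(spike, 10)
  expect_gte(out[21, 21], 0.9 * 1000)

  # offset invariance within 1 intensity unit
  shifted <- rolling_ball_subtract(spike + 50, 10)
  expect_lt(max(abs(out - shifted)), 1)

  # pixelwise bounds and agreement with the independent R oracle
  set.seed(31)
  img <- matrix(rexp(30 * 30, 1 / 40), 30)
  sub <- rolling_ball_subtract(img, 5)
  expect_true(all(sub >= 0) && all(sub <= img + 1e-12))
  oracle <- pmax(img - ball_background_oracle(img, 5), 0)
  expect_equal(sub, oracle, tolerance = 1e-12)

  expect_error(rolling_ball_subtract(matrix(1, 8, 8), 10), "radius")
})

test_that("damage_mask uses a strict threshold and is monotone", {
  img <- matrix(5, 32, 32)
  expect_false(any(damage_mask(img, 50)))          # all below
  expect_false(any(damage_mask(matrix(50, 8, 8), 50))) # boundary: strict

  foci <- matrix(5, 64, 64)
  foci <- chromafoci:::add_bump(foci, c(20, 20), 2, 95)
  foci <- chromafoci:::add_bump(foci, c(44, 40), 2, 95)
  m <- damage_mask(foci, 50)
  lab <- flood_label_oracle(m)
  expect_identical(max(lab), 2L)

  # monotone in threshold
  set.seed(41)
  r <- matrix(runif(400, 0, 100), 20)
  m1 <- damage_mask(r, 30); m2 <- damage_mask(r, 60)
  expect_true(all(m1[m2]))
})

test_that("count_foci intersects with the nucleus and is additive", {
  dmg <- matrix(FALSE, 60, 60)
  put <- function(m, at) { m[at[1] + 0:2, at[2] + 0:2] <- TRUE; m }
  dmg <- put(put(put(put(dmg, c(10, 10)), c(10, 30)), c(30, 10)), c(50, 50))
  nuc <- matrix(FALSE, 60, 60); nuc[5:40, 5:40] <- TRUE
  expect_identical(count_foci(dmg, nuc, min_focus_px = 4), 3L) # 1 outside
  expect_identical(count_foci(matrix(FALSE, 60, 60), nuc), 0L)
  expect_identical(count_foci(dmg, nuc, min_focus_px = 10), 0L)

  # additivity over disjoint nuclei
  nucA <- matrix(FALSE, 60, 60); nucA[5:20, 5:40] <- TRUE
  nucB <- matrix(FALSE, 60, 60); nucB[25:40, 5:40] <- TRUE
  expect_identical(count_foci(dmg, nucA | nucB, 4),
                   count_foci(dmg, nucA, 4) + count_foci(dmg, nucB, 4))
})
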