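test_that("TIFF round-trips 8-bit, 16-bit and float pages", {
  set.seed(61)
  m16 <- matrix(sample(0:65535, 300), 15)
  m8 <- matrix(sample(0:255, 300, replace = TRUE), 15)
  mf <- matrix(rnorm(300), 15)

  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff(m16, p, bits = 16)
  expect_equal(read_tiff(p)[[1]], m16)

  write_tiff(m8, p, bits = 8)
  expect_equal(read_tiff(p)[[1]], m8)

  write_tiff(mf, p, bits = "float")
  expect_equal(read_tiff(p)[[1]], mf, tolerance = 1e-7) # float32 precision

  # two-page file with pixel-size metadata
  write_tiff(list(m16, m8), p, bits = 16, pixel_size_nm = 45)
  back <- read_tiff(p)
  expect_length(back, 2)
  expect_equal(back[[1]], m16)
  expect_equal(back[[2]], m8)
  expect_equal(attr(back, "pixel_size_nm"), 45, tolerance = 1e-6)

  expect_error(read_tiff(withr::local_tempfile(lines = "not a tiff")),
               "not a TIFF")
})

test_that("read_channels maps pages to channel roles", {
  dmg <- matrix(1:20, 4); dna <- matrix(21:40, 4)
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff(list(dmg, dna), p, bits = 16, pixel_size_nm = 90)
  chs <- read_channels(p)
  expect_identical(chs$ch1$role, "damage")
  expect_equal(chs$ch1$pixels, dmg)
  expect_equal(chs$ch2$pixels, dna)
  expect_equal(chs$ch1$pixel_size_nm, 90, tolerance = 1e-6)

  # reversed channel order
  rev <- read_channels(p, channel_order = c("dna", "damage"))
  expect_equal(rev$ch1$pixels, dna)

  # two single-channel files
  p1 <- withr::local_tempfile(fileext = ".tif")
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff(dmg, p1); write_tiff(dna, p2)
  two <- read_channels(p1, p2)
  expect_equal(two$ch2$pixels, dna)
})
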