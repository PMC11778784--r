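test_that("TIFF round trip preserves voxels bit-exactly and metadata", {
  td <- withr::local_tempdir()
  set.seed(42)
  a1 <- array(sample(0:65535, 6 * 12 * 10, TRUE), c(12, 10, 6))
  a2 <- array(sample(0:65535, 6 * 12 * 10, TRUE), c(12, 10, 6))
  st <- IntensityStack(list(myo = a1, endo = a2),
                       spacing = c(0.5, 0.228, 0.228), origin = c(1, 2, 3))
  f <- file.path(td, "stack.tif")
  writeStack(st, f)

  # sidecar carries the metadata
  back <- readStack(f)
  expect_identical(unname(getChannel(back, "myo") + 0L), unname(a1))
  expect_identical(unname(getChannel(back, "endo") + 0L), unname(a2))
  expect_equal(unname(spacing(back)), c(0.5, 0.228, 0.228), tolerance = 1e-6)
  expect_equal(unname(origin(back)), c(1, 2, 3))
  expect_equal(channelNames(back), c("myo", "endo"))
})

test_that("interleaved pages de-interleave into per-channel arrays", {
  td <- withr::local_tempdir()
  # hand-build an interleaved fixture: page p holds constant value p
  pages <- lapply(1:20, function(p) matrix(p / 255, 4, 5))
  f <- file.path(td, "il.tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 8L)
  st <- readStack(f, spacing = c(0.5, 0.228, 0.228),
                  channelNames = c("c1", "c2"), layout = "interleaved")
  # channel 1 holds odd pages, channel 2 even pages, in z order
  expect_equal(dim(getChannel(st, "c1")), c(4, 5, 10))
  expect_equal(getChannel(st, "c1")[1, 1, ], seq(1, 19, by = 2))
  expect_equal(getChannel(st, "c2")[1, 1, ], seq(2, 20, by = 2))

  st2 <- readStack(f, spacing = c(0.5, 0.228, 0.228),
                   channelNames = c("c1", "c2"), layout = "stacked")
  expect_equal(getChannel(st2, "c1")[1, 1, ], 1:10)
})

test_that("readStack rejects bad inputs", {
  td <- withr::local_tempdir()
  f <- file.path(td, "x.tif")
  tiff::writeTIFF(lapply(1:9, function(p) matrix(0, 3, 3)), f)
  expect_error(readStack(file.path(td, "nope.tif"), c(1, 1, 1)), "no such file")
  expect_error(readStack(f, spacing = c(1, 1, 1),
                         channelNames = c("a", "b")), "not divisible")
  expect_error(readStack(f, spacing = c(0, 1, 1)), "> 0")
})

test_that("cropStack restricts voxels and shifts the origin", {
  a <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  st <- IntensityStack(a, spacing = c(0.5, 0.25, 0.25))
  # full-extent roi is the identity
  full <- cropStack(st, list(z = c(1, 6), y = c(1, 4), x = c(1, 5)))
  expect_identical(getChannel(full, "ch1"), a)
  expect_equal(origin(full), origin(st))
  # z offset of 2 slices at dz = 0.5 moves the origin by 1 um
  cr <- cropStack(st, list(z = c(3, 6)))
  expect_equal(origin(cr)[["z"]], 1.0)
  expect_identical(getChannel(cr, "ch1"), a[, , 3:6])
  expect_error(cropStack(st, list(z = c(5, 9))), "out of bounds")
  expect_error(cropStack(st, list(y = c(3, 2))), "empty roi")
})

test_that("despeckle is a per-slice median filter", {
  cst <- IntensityStack(array(7L, c(9, 9, 3)), spacing = c(1, 1, 1))
  expect_identical(getChannel(despeckle(cst, 1), "ch1"),
                   getChannel(cst, "ch1"))

  b <- array(0L, c(21, 21, 3))
  b[11, 11, 2] <- 100L
  st <- IntensityStack(b, spacing = c(1, 1, 1))
  expect_equal(getChannel(despeckle(st, 1), "ch1")[11, 11, 2], 0)
  expect_error(despeckle(st, 0), ">= 1")
})

test_that("despeckle restores most salt-and-pepper flips on a disc", {
  n <- 64
  img <- matrix(0L, n, n)
  img[(row(img) - 32)^2 + (col(img) - 32)^2 <= 20^2] <- 200L
  arr <- array(img, c(n, n, 1))
  set.seed(7)
  flips <- sample(length(arr), round(0.02 * length(arr)))
  noisy <- arr
  noisy[flips] <- ifelse(arr[flips] > 0, 0L, 200L)
  den <- getChannel(despeckle(IntensityStack(noisy, c(1, 1, 1)), 1), "ch1")
  restored <- mean(den[flips] == arr[flips])
  expect_gte(restored, 0.95)
})

test_that("crop commutes with despeckle away from the crop boundary", {
  set.seed(11)
  a <- array(sample(0:255, 20 * 20 * 4, TRUE), c(20, 20, 4))
  st <- IntensityStack(a, spacing = c(1, 1, 1))
  roi <- list(y = c(5, 16), x = c(5, 16))
  a1 <- getChannel(despeckle(cropStack(st, roi), 1), "ch1")
  a2 <- getChannel(cropStack(despeckle(st, 1), roi), "ch1")
  # interior (one-pixel boundary band excluded) must agree exactly
  expect_identical(a1[2:11, 2:11, ], a2[2:11, 2:11, ])
})
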