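test_that("straight-cylinder centreline follows the axis", {
  cl <- fxStraightCl()
  P <- clPoints(cl)
  # within one voxel of the analytic axis everywhere
  expect_lt(max(sqrt(P[, 1]^2 + P[, 2]^2)), 1)
  lm <- loopingMetrics(cl)
  expect_equal(lm$looped_length, 100, tolerance = 0.02)
  expect_equal(lm$looping_ratio, 1, tolerance = 0.02)
  # every point inside the lumen with positive clearance
  expect_true(all(clRadius(cl)[clArclength(cl) > 2 &
                               clArclength(cl) < 98] > 0))
  # away from the capped ends the clearance reaches at least half the
  # analytic tube radius (near the caps the inscribed sphere is bounded by
  # the end faces, not the lateral wall)
  mid <- clArclength(cl) > 25 & clArclength(cl) < 75
  expect_gt(min(clRadius(cl)[mid]), 0.5 * 20)
})

test_that("bent-tube centrelines recover analytic arc lengths and ratios", {
  # semicircle: length pi R, ratio pi / 2
  lm180 <- loopingMetrics(fxBentCl(180))
  expect_equal(lm180$looped_length, pi * 50, tolerance = 0.03)
  expect_equal(lm180$looping_ratio, pi / 2, tolerance = 0.03)
  # three-quarter circle: arc (3 pi / 2) R, chord sqrt(2) R
  lm270 <- loopingMetrics(fxBentCl(270))
  phi <- 270 * pi / 180
  expect_equal(lm270$looped_length, 50 * phi, tolerance = 0.03)
  expect_equal(lm270$looping_ratio, phi / (2 * sin(phi / 2)),
               tolerance = 0.03)
})

test_that("sphere with antipodal poles yields a diameter path", {
  h <- 1
  xs <- seq(-22, 22, by = h)
  arr <- array(FALSE, c(length(xs), length(xs), length(xs)))
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  Y <- matrix(xs, length(xs), length(xs))
  for (k in seq_along(xs)) arr[, , k] <- X^2 + Y^2 + xs[k]^2 <= 20^2
  ball <- VoxelMask(arr, c(h, h, h), c(-22, -22, -22))
  cl <- extractCentreline(ball, c(0, 0, -20), c(0, 0, 20))
  expect_equal(max(clArclength(cl)), 40, tolerance = 0.03)
})

test_that("reversing the pole labels reverses the line, not the metrics", {
  p <- fxStraight()
  lum <- VoxelMask(p$masks$lumen, p$spacing, p$origin)
  a <- fxStraightCl()
  b <- extractCentreline(lum, p$truth$poles[2, ], p$truth$poles[1, ])
  la <- loopingMetrics(a); lb <- loopingMetrics(b)
  expect_equal(la$looped_length, lb$looped_length, tolerance = 1e-6)
  expect_equal(la$looping_ratio, lb$looping_ratio, tolerance = 1e-6)
  # endpoints swap
  expect_equal(as.numeric(clPoints(b)[1, 3]), 100, tolerance = 1)
  expect_equal(as.numeric(clPoints(b)[nrow(clPoints(b)), 3]), 0,
               tolerance = 1)
})

test_that("pole preconditions are enforced", {
  p <- fxStraight()
  lum <- VoxelMask(p$masks$lumen, p$spacing, p$origin)
  expect_error(extractCentreline(lum, c(200, 200, 0), c(0, 0, 100)),
               "outside the lumen")
  expect_error(loopingMetrics(Centreline(matrix(0, 2, 3), c(0, 1), c(1, 1),
                                         anchors = matrix(0, 2, 3))),
               "coincide")
  # two disjoint lumen components
  a <- array(FALSE, c(9, 9, 20))
  a[3:7, 3:7, 1:8] <- TRUE; a[3:7, 3:7, 13:20] <- TRUE
  m <- VoxelMask(a, c(1, 1, 1))
  expect_error(extractCentreline(m, c(4, 4, 2), c(4, 4, 18)), "disjoint")
})

test_that("extendCentreline prolongs along the end tangents", {
  # straight line: endpoints displaced exactly along the axis
  cl <- fxStraightCl()
  ext <- extendCentreline(cl, 10)
  expect_equal(clPoints(ext)[1, 3], clPoints(cl)[1, 3] - 10,
               tolerance = 0.2)
  n <- nrow(clPoints(ext))
  expect_equal(clPoints(ext)[n, 3], clPoints(cl)[nrow(clPoints(cl)), 3] + 10,
               tolerance = 0.2)
  expect_lt(max(abs(clPoints(ext)[c(1, n), 1:2])), 0.5)

  # semicircle: extensions tangent to the circle at its ends (< 5 degrees)
  clB <- fxBentCl(180)
  extB <- extendCentreline(clB, 10)
  PB <- clPoints(extB)
  dirStart <- PB[1, ] - clPoints(clB)[1, ]
  # analytic tangent at the theta = 0 end, pointing outward: -y
  cosang <- sum(.normalizeV(dirStart) * c(0, -1, 0))
  expect_gt(cosang, cos(5 * pi / 180))

  # extend then crop recovers the original within the resampling step
  L <- max(clArclength(cl))
  back <- cropCentreline(ext, 10, 10 + L)
  expect_equal(max(clArclength(back)), L, tolerance = 0.02)
  expect_error(extendCentreline(cl, -1), "> 0")
})

test_that("centreline CSV/VTK writers produce parseable artifacts", {
  td <- withr::local_tempdir()
  cl <- fxStraightCl()
  f <- file.path(td, "cl.csv")
  writeCentrelineCsv(cl, f)
  df <- read.csv(f)
  expect_equal(nrow(df), nrow(clPoints(cl)))
  expect_equal(df$arclength, clArclength(cl))
  writeCentrelineVTK(cl, file.path(td, "cl.vtk"))
  expect_match(readLines(file.path(td, "cl.vtk"), n = 4)[4], "POLYDATA")
})
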