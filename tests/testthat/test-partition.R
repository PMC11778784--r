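test_that("disc cut through a symmetric bend halves the tube volume", {
  ph <- fxBent(180)
  solid <- VoxelMask(ph$masks$lumen | ph$masks$wall, ph$spacing, ph$origin)
  # apex of the semicircle is at (0, R, 0); local tube axis is x
  disc <- CutDisc(c(0, 50, 0), c(1, 0, 0), 30)
  part <- splitByDisc(solid, disc, atrialSide = "negative")
  vv <- prod(spacing(solid))
  half <- maskVolume(solid) / 2
  expect_equal(sum(part@labels == 1L) * vv, half, tolerance = 0.03)
  expect_equal(sum(part@labels == 2L) * vv, half, tolerance = 0.03)
  # reported cut area approximates the tube cross-section
  expect_equal(part@cutArea, pi * 14^2, tolerance = 0.1)

  # flipping the atrial side swaps the labels only (probed with a plane
  # off the voxel grid, where the on-plane tie set is empty)
  discOff <- CutDisc(c(0.25, 50, 0), c(1, 0, 0), 30)
  pa <- splitByDisc(solid, discOff, atrialSide = "negative")
  pb <- splitByDisc(solid, discOff, atrialSide = "positive")
  expect_identical(pb@labels == 1L, pa@labels == 2L)
})

test_that("disc preconditions: missing the target, undersized radius", {
  a <- array(FALSE, c(8, 8, 8)); a[3:6, 3:6, 3:6] <- TRUE
  m <- VoxelMask(a, c(1, 1, 1))
  expect_error(splitByDisc(m, CutDisc(c(0, 0, 50), c(0, 0, 1), 20)),
               "misses")
  expect_error(splitByDisc(m, CutDisc(c(3.5, 3.5, 4), c(0, 0, 1), 0.5)),
               "overhang")
})

test_that("on-plane voxels take the ventricular label (tie-break)", {
  a <- array(TRUE, c(1, 5, 1))
  m <- VoxelMask(a, c(1, 1, 1))   # voxels at x = 0..4, y = z = 0
  part <- splitByDisc(m, CutDisc(c(2, 0, 0), c(1, 0, 0), 10),
                      atrialSide = "positive")
  lab <- part@labels[1, , 1]
  expect_equal(lab, c(2L, 2L, 2L, 1L, 1L))  # x = 2 (s = 0) -> ventricle
})

test_that("left/right split about the centreline is symmetric", {
  # half-voxel margin keeps voxel centres symmetric about (and off) the
  # dividing plane; the analytic axis centreline isolates the splitting
  # rule from centreline extraction
  p <- phantomStraightTube(rIn = 20, rOut = 25, height = 100,
                           spacing = c(1, 1, 1), margin = 3.5)
  wall <- VoxelMask(p$masks$myo_wall, p$spacing, p$origin)
  cl <- Centreline(cbind(0, 0, 0:100), 0:100, rep(20, 101),
                   anchors = rbind(c(0, 0, 0), c(0, 0, 100)))
  lr <- splitLeftRight(wall, cl, dorsalRef = c(0, 1, 0))
  nl <- sum(lr == 1L); nr <- sum(lr == 2L)
  expect_equal(nl / nr, 1, tolerance = 0.02)
  # negating the dorsal reference swaps the labels
  lr2 <- splitLeftRight(wall, cl, dorsalRef = c(0, -1, 0))
  expect_identical(lr2 == 1L, lr == 2L)
  # documented tie rule: voxel on the tangent-dorsal plane goes right
  one <- array(TRUE, c(1, 1, 1))
  mk1 <- VoxelMask(one, c(1, 1, 1), origin = c(0, 5, 50))  # on the y axis
  expect_equal(as.integer(suppressWarnings(
    splitLeftRight(mk1, cl, c(0, 1, 0)))), 2L)
})

test_that("chamber angles follow the projected axes", {
  ph <- phantomTwoChamber(spacing = c(1, 0.5, 0.5))
  solid <- VoxelMask(ph$masks$solid, ph$spacing, ph$origin)
  disc <- CutDisc(c(0, 0, 0), c(1, -1, 0) / sqrt(2), 40)
  part <- splitByDisc(solid, disc, atrialSide = "negative")
  # chamber A along +y (parallel to ref): 0 degrees; B along +x: -90
  ang <- chamberAngles(part, refVector = c(0, 1, 0), view = "ventral")
  expect_equal(ang$atrium, 0, tolerance = 2)
  expect_equal(abs(ang$ventricle), 90, tolerance = 2)
  expect_equal(ang$between, 90, tolerance = 2)
  # antiparallel reference flips the atrial angle to 180
  ang2 <- chamberAngles(part, refVector = c(0, -1, 0), view = "ventral")
  expect_equal(abs(ang2$atrium), 180, tolerance = 2)
})

test_that("angles are rotation equivariant about the view axis", {
  ph <- phantomTwoChamber(spacing = c(1, 0.5, 0.5))
  solid <- VoxelMask(ph$masks$solid, ph$spacing, ph$origin)
  disc <- CutDisc(c(0, 0, 0), c(1, -1, 0) / sqrt(2), 40)
  part <- splitByDisc(solid, disc, atrialSide = "negative")
  ref <- c(0, 1, 0)
  a0 <- chamberAngles(part, ref, "ventral")

  # rotate the voxel cloud and the reference together by 30 degrees
  # about z; with origin rotated too, the scene is rigidly transformed
  R <- rotationMatrix(c(0, 0, 1), 30)
  idx <- which(maskVoxels(solid), arr.ind = TRUE)
  P <- cardiomorph:::.voxelToPhys(idx[, 1], idx[, 2], idx[, 3],
                                  spacing(solid), origin(solid))
  Pr <- P %*% t(R)
  # re-voxelize the rotated cloud on a fresh grid
  rng <- apply(Pr, 2, range)
  sp <- c(1, 0.5, 0.5)
  gx <- seq(rng[1, 1] - 1, rng[2, 1] + 1, by = sp[3])
  gy <- seq(rng[1, 2] - 1, rng[2, 2] + 1, by = sp[2])
  gz <- seq(rng[1, 3] - 1, rng[2, 3] + 1, by = sp[1])
  arr <- array(FALSE, c(length(gy), length(gx), length(gz)))
  j <- round((Pr[, 2] - gy[1]) / sp[2]) + 1
  i <- round((Pr[, 1] - gx[1]) / sp[3]) + 1
  k <- round((Pr[, 3] - gz[1]) / sp[1]) + 1
  arr[cbind(j, i, k)] <- TRUE
  solidR <- VoxelMask(arr, sp, c(gx[1], gy[1], gz[1]))
  discR <- CutDisc(c(0, 0, 0), as.numeric(R %*% (c(1, -1, 0) / sqrt(2))), 40)
  partR <- splitByDisc(solidR, discR, atrialSide = "negative")
  aR <- chamberAngles(partR, as.numeric(R %*% ref), "ventral")
  expect_equal(aR$atrium, a0$atrium, tolerance = 0.5)
  expect_equal(aR$between, a0$between, tolerance = 0.5)
})
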