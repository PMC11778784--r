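# unrolled heatmaps on a straight tube: the cylinder is the one phantom
# whose unrolling is fully analytic (every interior station cuts a circle)

.tubeHeatmap <- function(scalarFun, nPlanes = 50, nAngleBins = 36) {
  mesh <- fxTubeSolidMesh()
  cl <- extendCentreline(fxStraightCl(), 5)
  V <- vertices(mesh)
  mesh <- setMeshScalar(mesh, scalarFun(V), "thickness", "um")
  unrollHeatmap(mesh, cl, dorsalRef = c(0, 1, 0), nPlanes = nPlanes,
                nAngleBins = nAngleBins)
}

test_that("a constant scalar unrolls to a constant matrix with full rows", {
  hm <- .tubeHeatmap(function(V) rep(5, nrow(V)))
  v <- heatmapValues(hm)
  arc <- hm@arcCenters
  interior <- arc > 10 & arc < max(arc) - 10
  expect_false(any(is.na(v[interior, ])))     # no spurious gaps
  expect_equal(range(v[interior, ]), c(5, 5))
  # angle bin centres uniformly cover [-180, 180)
  expect_equal(hm@angleCenters, -180 + (seq_len(36) - 0.5) * 10)
})

test_that("a left/right split field lands in the correct angular half-planes", {
  # left half (positive angles): tangent +z, dorsal +y -> left is -x
  hm <- .tubeHeatmap(function(V) ifelse(V[, 1] < 0, 10, 2))
  v <- heatmapValues(hm)
  ang <- hm@angleCenters
  arc <- hm@arcCenters
  interior <- arc > 10 & arc < max(arc) - 10
  left <- ang > 15 & ang < 165
  right <- ang < -15 & ang > -165
  expect_equal(mean(v[interior, left], na.rm = TRUE), 10, tolerance = 0.1)
  expect_equal(mean(v[interior, right], na.rm = TRUE), 2, tolerance = 0.1)
})

test_that("unrolling is equivariant under joint rotation", {
  mesh <- fxTubeSolidMesh()
  cl <- extendCentreline(fxStraightCl(), 5)
  V <- vertices(mesh)
  mesh <- setMeshScalar(mesh, ifelse(V[, 1] < 0, 10, 2), "thickness", "um")
  hm0 <- unrollHeatmap(mesh, cl, c(0, 1, 0), nPlanes = 30, nAngleBins = 24)
  R <- rotationMatrix(c(1, 2, 3), 40)
  hmR <- unrollHeatmap(rotateMesh(mesh, R), rotateCentreline(cl, R),
                       as.numeric(R %*% c(0, 1, 0)), nPlanes = 30,
                       nAngleBins = 24)
  v0 <- heatmapValues(hm0); vR <- heatmapValues(hmR)
  arc <- hm0@arcCenters
  interior <- arc > 10 & arc < max(arc) - 10
  # identical up to one angular bin: compare against shifts of -1..1 bins
  errs <- vapply(-1:1, function(s) {
    shifted <- vR[, ((seq_len(24) - 1 + s) %% 24) + 1]
    mean(abs(v0[interior, ] - shifted[interior, ]), na.rm = TRUE)
  }, 0)
  expect_lt(min(errs), 0.2)
})

test_that("stations beyond the mesh stay missing and are never imputed", {
  mesh <- fxTubeSolidMesh()
  cl <- extendCentreline(fxStraightCl(), 20)   # far beyond the caps
  mesh <- setMeshScalar(mesh, rep(1, nrow(vertices(mesh))), "x", "um")
  expect_warning(
    hm <- unrollHeatmap(mesh, cl, c(0, 1, 0), nPlanes = 60, nAngleBins = 24),
    NA)
  v <- heatmapValues(hm)
  # first and last stations sit ~20 um outside the tube: whole rows NA
  expect_true(all(is.na(v[1, ])))
  expect_true(all(is.na(v[nrow(v), ])))
})

test_that("averaging is idempotent, gap-preserving and conservative", {
  m <- matrix(c(1, NA, 3, 4), 2, 2)
  mk <- function(vals) new("Heatmap2D", values = vals,
                           arcCenters = c(0, 10),
                           angleCenters = c(-90, 90), count = NULL,
                           sd = NULL, scalarName = "t", scalarUnits = "um",
                           regionLabels = list())
  # average of identical maps is that map, bit-equal on present cells
  avg <- averageHeatmaps(list(mk(m), mk(m), mk(m)))
  expect_identical(heatmapValues(avg)[!is.na(m)], m[!is.na(m)])
  expect_true(is.na(heatmapValues(avg)[2, 1]))   # the gap stays a gap
  expect_equal(avg@count[2, 1], 0)

  # mean 5, sample SD sqrt(2) for contributions 4 and 6
  m1 <- matrix(4, 1, 2); m2 <- matrix(6, 1, 2)
  mk1 <- function(vals) new("Heatmap2D", values = vals, arcCenters = 0,
                            angleCenters = c(-90, 90), count = NULL,
                            sd = NULL, scalarName = "t", scalarUnits = "um",
                            regionLabels = list())
  a2 <- averageHeatmaps(list(mk1(m1), mk1(m2)))
  expect_equal(heatmapValues(a2)[1, 1], 5)
  expect_equal(a2@sd[1, 1], sqrt(2))

  # a cell present in 1 of 3 maps keeps that value with count 1
  mm1 <- mk(matrix(c(7, NA, NA, NA), 2, 2))
  mm2 <- mk(matrix(NA_real_, 2, 2))
  a3 <- averageHeatmaps(list(mm1, mm2, mm2))
  expect_equal(heatmapValues(a3)[1, 1], 7)
  expect_equal(a3@count[1, 1], 1)

  # conservation: sum(value x count) equals the column sums of inputs
  maps <- list(mk(m), mk(matrix(c(2, 8, NA, 0), 2, 2)))
  av <- averageHeatmaps(maps)
  tot <- heatmapValues(av) * av@count
  tot[is.na(tot)] <- 0
  ref <- Reduce(`+`, lapply(maps, function(x) {
    v <- heatmapValues(x); v[is.na(v)] <- 0; v
  }))
  expect_equal(tot, ref)

  expect_error(averageHeatmaps(list()), "empty")
  expect_error(averageHeatmaps(list(mk(m), mk1(m1))), "shape")
})

test_that("heatmap CSV round-trips bit-exactly with empty missing cells", {
  td <- withr::local_tempdir()
  hm <- .tubeHeatmap(function(V) V[, 3] + 0.123456789, nPlanes = 20,
                     nAngleBins = 12)
  f <- file.path(td, "hm.csv")
  exportHeatmapCsv(hm, f)
  raw <- readLines(f)
  # missing cells are empty fields, never zeros
  expect_true(any(grepl(",,", raw)) || !anyNA(heatmapValues(hm)))
  back <- readHeatmapCsv(f)
  expect_identical(heatmapValues(back), heatmapValues(hm))
  expect_equal(back@angleCenters, hm@angleCenters)
  expect_equal(back@arcCenters, hm@arcCenters)
})

test_that("band summaries are reproducible from the exported CSV alone", {
  td <- withr::local_tempdir()
  hm <- .tubeHeatmap(function(V) rep(3, nrow(V)), nPlanes = 20,
                     nAngleBins = 12)
  hm <- labelHeatmapBands(hm, list(low = c(0, 50), high = c(50, 120)))
  f <- file.path(td, "hm.csv")
  exportHeatmapCsv(hm, f)
  back <- labelHeatmapBands(readHeatmapCsv(f),
                            list(low = c(0, 50), high = c(50, 120)))
  expect_identical(heatmapBandSummary(back), heatmapBandSummary(hm))
})
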