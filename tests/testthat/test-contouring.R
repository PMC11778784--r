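discImage <- function(n = 64, r = 20, cy = 32, cx = 32, value = 150) {
  img <- matrix(0, n, n)
  img[(row(img) - cy)^2 + (col(img) - cx)^2 <= r^2] <- value
  img
}

test_that("contour detection recovers discs, annuli and blank slices", {
  img <- discImage()
  polys <- detectSliceContours(img)
  expect_length(polys, 1L)
  expect_equal(attr(polys[[1]], "depth"), 0L)
  # enclosed area within 3% of pi r^2 (rasterized-disc oracle: pixel count)
  expect_equal(attr(polys[[1]], "area"), pi * 400, tolerance = 0.03)
  expect_equal(attr(polys[[1]], "area"), sum(img > 0), tolerance = 0.03)

  ann <- discImage()
  ann[(row(ann) - 32)^2 + (col(ann) - 32)^2 <= 10^2] <- 0
  pa <- detectSliceContours(ann)
  expect_length(pa, 2L)
  expect_setequal(vapply(pa, attr, 1L, "depth"), c(0L, 1L))

  expect_length(detectSliceContours(matrix(0, 16, 16)), 0L)
  expect_error(detectSliceContours(img, "fixed", level = NULL), "fixed")
  expect_length(detectSliceContours(img, "fixed", level = 200), 0L)
})

test_that("minArea filters small specks", {
  img <- discImage()
  img[3, 3] <- 150
  expect_length(detectSliceContours(img, minArea = 4), 1L)
  expect_length(detectSliceContours(img, minArea = 0), 2L)
})

test_that("classification follows containment-depth parity", {
  ann <- discImage()
  ann[(row(ann) - 32)^2 + (col(ann) - 32)^2 <= 10^2] <- 0
  sc <- classifyContours(detectSliceContours(ann))
  expect_setequal(sc@roles, c("external", "internal"))
  expect_equal(sc@roles[sc@depth == 0L], "external")
  expect_equal(sc@roles[sc@depth == 1L], "internal")

  # two disjoint discs: both external, no internal
  two <- discImage(r = 10, cy = 18, cx = 18) + discImage(r = 10, cy = 46,
                                                         cx = 46)
  sc2 <- classifyContours(detectSliceContours(two))
  expect_equal(sc2@roles, c("external", "external"))

  # disc-in-hole-in-disc: depth 2 is external again (even parity)
  nest <- discImage(r = 25)
  nest[(row(nest) - 32)^2 + (col(nest) - 32)^2 <= 16^2] <- 0
  nest[(row(nest) - 32)^2 + (col(nest) - 32)^2 <= 8^2] <- 150
  sc3 <- classifyContours(detectSliceContours(nest))
  expect_equal(sort(sc3@depth), 0:2)
  expect_equal(sc3@roles[sc3@depth == 2L], "external")
})

test_that("filled masks obey the XOR algebra bit-exactly", {
  ann <- discImage()
  ann[(row(ann) - 32)^2 + (col(ann) - 32)^2 <= 10^2] <- 0
  sc <- classifyContours(detectSliceContours(ann))
  mk <- fillMasks(sc, c(64, 64))
  expect_identical(mk@tissue, xor(mk@filledExternal, mk@filledInternal))
  expect_false(any(mk@filledInternal & !mk@filledExternal))
  expect_false(any(mk@tissue & mk@filledInternal))
  expect_identical(mk@tissue | mk@filledInternal, mk@filledExternal)
  # |tissue| = |ext| - |int| exactly
  expect_equal(sum(mk@tissue),
               sum(mk@filledExternal) - sum(mk@filledInternal))
  # independent oracle: foreground + hole filling via EBImage
  B <- ann > 50
  expect_identical(unname(mk@filledExternal),
                   unname(as.array(EBImage::fillHull(B)) > 0))
  expect_identical(unname(mk@tissue), unname(B))

  # no internal contours: tissue = filled external
  scD <- classifyContours(detectSliceContours(discImage()))
  mkD <- fillMasks(scD, c(64, 64))
  expect_identical(mkD@tissue, mkD@filledExternal)
  expect_equal(sum(mkD@filledInternal), 0)
})

test_that("recovered per-slice areas stay within the rasterization bound", {
  for (r in c(8, 14, 20)) {
    img <- discImage(r = r)
    mk <- fillMasks(classifyContours(detectSliceContours(img)), c(64, 64))
    # error bounded by perimeter x pixel size
    expect_lt(abs(sum(mk@filledExternal) - pi * r^2), 2 * pi * r * 1)
  }
})

test_that("contours touching the image border are closed along it", {
  img <- matrix(0, 40, 40)
  img[1:20, 10:30] <- 150     # block truncated by the top border
  polys <- detectSliceContours(img)
  expect_length(polys, 1L)
  mk <- fillMasks(classifyContours(polys), c(40, 40))
  expect_equal(sum(mk@tissue), sum(img > 0))
})

test_that("contour library reproduces phantom wall volume within 3%", {
  ph <- fxNested()
  lib <- fxNestedLib()
  vv <- prod(ph$spacing)
  # truth recomputed in closed form, not read from the generator
  myoTruth <- pi * (30^2 - 25^2) * 100
  expect_equal(maskVolume(libraryMask(lib, "outer", "tissue")), myoTruth,
               tolerance = 0.03)
  endoTruth <- pi * (20^2 - 17^2) * 100
  expect_equal(maskVolume(libraryMask(lib, "inner", "tissue")), endoTruth,
               tolerance = 0.03)
  # per-slice XOR identity holds on every slice of both channels
  for (ch in channelNames(lib)) {
    mk <- lib@masks[[ch]]
    expect_identical(mk$tissue,
                     xor(mk$filled_external, mk$filled_internal))
  }
})

test_that("an all-blank channel yields empty masks throughout", {
  st <- IntensityStack(list(a = array(0L, c(16, 16, 4))),
                       spacing = c(1, 1, 1))
  lib <- buildContourLibrary(st)
  expect_equal(sum(lib@masks$a$tissue), 0)
  expect_length(lib@contours$a, 4L)
})

test_that("manual overrides substitute polygons for named slices only", {
  st <- IntensityStack(array(discImage(n = 40, r = 12, cy = 20, cx = 20),
                             c(40, 40, 3)), spacing = c(1, 1, 1))
  sq <- cbind(y = c(5, 5, 15, 15, 5), x = c(5, 15, 15, 5, 5))
  ov <- list(ch1 = list("2" = list(polygons = list(sq),
                                   roles = "external")))
  lib <- buildContourLibrary(st, overrides = ov)
  expect_equal(sliceContours(lib, "ch1", 2)@provenance, "manual")
  expect_equal(sliceContours(lib, "ch1", 1)@provenance, "auto")
  # overridden slice holds the 11 x 11 filled square
  expect_equal(sum(lib@masks$ch1$tissue[, , 2]), 121)
  expect_identical(lib@masks$ch1$tissue[, , 1], lib@masks$ch1$tissue[, , 3])
  expect_error(buildContourLibrary(st, overrides = list(
    ch1 = list("9" = list(polygons = list(sq), roles = "external")))),
    "nonexistent")
})

test_that("contour library persists to JSON + TIFF and overrides round-trip", {
  td <- withr::local_tempdir()
  st <- IntensityStack(array(discImage(n = 40, r = 12, cy = 20, cx = 20),
                             c(40, 40, 2)), spacing = c(1, 1, 1))
  lib <- buildContourLibrary(st)
  writeContourLibrary(lib, td)
  expect_true(file.exists(file.path(td, "contours_ch1.json")))
  expect_true(file.exists(file.path(td, "ch1_tissue.tif")))
  back <- readStack(file.path(td, "ch1_tissue.tif"))
  expect_identical(unname(getChannel(back, "tissue") > 0),
                   unname(lib@masks$ch1$tissue))

  ovPath <- file.path(td, "ov.json")
  sq <- cbind(c(5, 5, 15, 15, 5), c(5, 15, 15, 5, 5))
  jsonlite::write_json(
    list(ch1 = list("1" = list(roles = list("external"),
                               polygons = list(apply(sq, 1, as.list))))),
    ovPath, auto_unbox = TRUE)
  ov <- readContourOverrides(ovPath)
  expect_equal(ov$ch1[["1"]]$roles, "external")
  expect_equal(dim(ov$ch1[["1"]]$polygons[[1]]), c(5L, 2L))
})
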