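# Shared phantom fixtures, built once per test run and memoized.
#
# Test grids are deliberately coarse (0.75-1 um isotropic) so the whole
# suite stays fast; the geometric tolerances asserted in the tests are
# derived for these grids (rasterization error scales with voxel size).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  got <- get0(name, envir = .fixtures, ifnotfound = NULL)
  if (!is.null(got)) return(got)
  val <- builder()
  assign(name, val, envir = .fixtures)
  val
}

fxNested <- function() fixture("nested", function()
  phantomNestedTubes(spacing = c(1, 0.5, 0.5)))

fxNestedLib <- function() fixture("nested_lib", function()
  buildContourLibrary(fxNested()$stack))

fxStraight <- function() fixture("straight", function()
  phantomStraightTube(rIn = 20, rOut = 25, height = 100,
                      spacing = c(1, 1, 1)))

fxStraightCl <- function() fixture("straight_cl", function() {
  p <- fxStraight()
  lum <- VoxelMask(p$masks$lumen, p$spacing, p$origin, "lumen")
  extractCentreline(lum, p$truth$poles[1, ], p$truth$poles[2, ])
})

fxBent <- function(angle) fixture(paste0("bent", angle), function()
  phantomBentTube(R = 50, angleDeg = angle, rIn = 10, rOut = 14,
                  spacing = c(1, 1, 1)))

fxBentCl <- function(angle) fixture(paste0("bent_cl", angle), function() {
  p <- fxBent(angle)
  lum <- VoxelMask(p$masks$lumen, p$spacing, p$origin, "lumen")
  extractCentreline(lum, p$truth$poles[1, ], p$truth$poles[2, ])
})

fxShells <- function() fixture("shells", function()
  phantomConcentricShells(spacing = c(0.75, 0.75, 0.75)))

fxShellMeshes <- function() fixture("shell_meshes", function() {
  p <- fxShells()
  list(outer = maskToMesh(VoxelMask(p$masks$outer_lumen, p$spacing,
                                    p$origin), smoothingIterations = 20),
       inner = maskToMesh(VoxelMask(p$masks$inner_solid, p$spacing,
                                    p$origin), smoothingIterations = 20))
})

fxBulged <- function() fixture("bulged", function()
  phantomBulgedTube(spacing = c(1, 1, 1)))

# voxelized axis-aligned ellipsoid mask (fine grid: extents drive the
# bounding-ellipsoid tests)
fxEllipsoidMesh <- function() fixture("ellipsoid_mesh", function() {
  h <- 0.25
  xs <- seq(-32, 32, by = h); ys <- xs; zs <- seq(-12, 12, by = h)
  arr <- array(FALSE, c(length(ys), length(xs), length(zs)))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  for (k in seq_along(zs))
    arr[, , k] <- (X / 30)^2 + (Y / 20)^2 + (zs[k] / 10)^2 <= 1
  maskToMesh(VoxelMask(arr, c(h, h, h), c(-32, -32, -12)))
})

fxSphereMesh <- function() fixture("sphere_mesh", function() {
  h <- 0.25
  xs <- seq(-22, 22, by = h)
  arr <- array(FALSE, c(length(xs), length(xs), length(xs)))
  X <- matrix(xs, length(xs), length(xs), byrow = TRUE)
  Y <- matrix(xs, length(xs), length(xs))
  for (k in seq_along(xs)) arr[, , k] <- X^2 + Y^2 + xs[k]^2 <= 20^2
  maskToMesh(VoxelMask(arr, c(h, h, h), c(-22, -22, -22)))
})

# straight tube solid (to r = rOut) mesh with unit scalar support
fxTubeSolidMesh <- function() fixture("tube_solid_mesh", function() {
  p <- fxStraight()
  maskToMesh(VoxelMask(p$masks$myo_wall | p$masks$myo_lumen, p$spacing,
                       p$origin))
})

.normalizeV <- function(v) v / sqrt(sum(v^2))

rotationMatrix <- function(axis, angleDeg) {
  a <- angleDeg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

rotateMesh <- function(mesh, R) {
  m <- mesh
  m@vertices <- mesh@vertices %*% t(R)
  m
}

rotateCentreline <- function(cl, R) {
  Centreline(cl@points %*% t(R), cl@arclength, cl@inscribedRadius,
             anchors = cl@anchors %*% t(R))
}
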