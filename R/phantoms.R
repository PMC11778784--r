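## phantoms: synthetic two-channel z-stacks, meshes and nuclei sets with
## closed-form ground truth. These are the validation surface of the whole
## package: every phantom records the analytic quantities (volumes,
## lengths, ratios, thicknesses) its geometry implies.
##
## Voxelization rule: a voxel is foreground iff its centre lies inside the
## analytic solid (centre sampling), so rasterization error bounds are
## derivable from the surface area and voxel size.

.makeGrid <- function(xr, yr, zr, spacing) {
  dz <- spacing[1]; dy <- spacing[2]; dx <- spacing[3]
  xs <- seq(xr[1], xr[2], by = dx)
  ys <- seq(yr[1], yr[2], by = dy)
  zs <- seq(zr[1], zr[2], by = dz)
  list(xs = xs, ys = ys, zs = zs,
       dims = c(length(ys), length(xs), length(zs)),
       origin = c(xr[1], yr[1], zr[1]))
}

# voxelize inside(X, Y, z) slice by slice; inside must be vectorized over
# matrices X, Y (both ny x nx) at scalar z
.voxelize <- function(grid, inside) {
  d <- grid$dims
  X <- matrix(grid$xs, d[1], d[2], byrow = TRUE)
  Y <- matrix(grid$ys, d[1], d[2])
  arr <- array(FALSE, d)
  for (k in seq_len(d[3])) arr[, , k] <- inside(X, Y, grid$zs[k])
  arr
}

.applyNoise <- function(arr, noise, seed, fg = 180L) {
  if (is.null(noise) || identical(noise$type, "none")) return(arr)
  .withSeed(seed, {
    if (noise$type == "salt_pepper") {
      n <- length(arr)
      hit <- sample.int(n, round((noise$fraction %||% 0.01) * n))
      arr[hit] <- ifelse(stats::runif(length(hit)) < 0.5, 0L, fg)
    } else if (noise$type == "gaussian") {
      arr[] <- pmax(0L, pmin(255L, as.integer(round(
        arr + stats::rnorm(length(arr), sd = noise$sigma %||% 10)))))
    } else stop("unknown noise type: ", noise$type)
    arr
  })
}

.phantomStack <- function(grid, insideOuter, insideInner, spacing, noise,
                          seed, fg = 180L) {
  ch1 <- .voxelize(grid, insideOuter)
  ch2 <- .voxelize(grid, insideInner)
  a1 <- array(fg * as.integer(ch1), grid$dims)
  a2 <- array(fg * as.integer(ch2), grid$dims)
  a1 <- .applyNoise(a1, noise, seed, fg)
  a2 <- .applyNoise(a2, noise, seed + 1L, fg)
  IntensityStack(list(outer = a1, inner = a2), spacing = spacing,
                 channelNames = c("outer", "inner"), origin = grid$origin)
}

.checkWall <- function(wall, spacing, what) {
  if (wall < 2 * max(spacing))
    stop(what, " thinner than 2 voxels at this spacing")
}

#' Nested-tubes phantom (two-layer tube with an ECM gap)
#'
#' A straight two-layer tube along z: the outer layer ("myocardium") is the
#' cylindrical shell between `rMyoIn` and `rMyoOut`, the inner layer
#' ("endocardium") the shell between `rEndoIn` and `rEndoOut`, with
#' `rEndoOut < rMyoIn` leaving an analytic ECM gap annulus.
#'
#' @param rMyoOut,rMyoIn,rEndoOut,rEndoIn,height geometry in micrometres.
#' @param spacing voxel spacing `(dz, dy, dx)`; the default mimics typical
#'   anisotropic lightsheet sampling.
#' @param noise `NULL`/`list(type = "none")`, or
#'   `list(type = "salt_pepper", fraction = )`, or
#'   `list(type = "gaussian", sigma = )`.
#' @param seed RNG seed for the noise (generation is seed-deterministic).
#' @param margin empty border around the solid, micrometres.
#' @return list with `stack` (two-channel [IntensityStack-class]), `truth`
#'   (closed-form volumes/lengths) and `masks` (analytic compartment
#'   voxelizations: `lumen`, `myo_wall`, `endo_wall`, `ecm`).
#' @export
phantomNestedTubes <- function(rMyoOut = 30, rMyoIn = 25, rEndoOut = 20,
                               rEndoIn = 17, height = 100,
                               spacing = c(0.5, 0.25, 0.25), noise = NULL,
                               seed = 1L, margin = 3) {
  stopifnot(rMyoOut > rMyoIn, rMyoIn > rEndoOut, rEndoOut > rEndoIn)
  .checkWall(rMyoOut - rMyoIn, spacing, "outer wall")
  .checkWall(rEndoOut - rEndoIn, spacing, "inner wall")
  g <- .makeGrid(c(-rMyoOut - margin, rMyoOut + margin),
                 c(-rMyoOut - margin, rMyoOut + margin),
                 c(-margin, height + margin), spacing)
  shell <- function(rin, rout) function(X, Y, z) {
    if (z < 0 || z > height) return(matrix(FALSE, nrow(X), ncol(X)))
    r2 <- X^2 + Y^2
    r2 <= rout^2 & r2 > rin^2
  }
  solid <- function(rout) function(X, Y, z) {
    if (z < 0 || z > height) return(matrix(FALSE, nrow(X), ncol(X)))
    X^2 + Y^2 <= rout^2
  }
  stack <- .phantomStack(g, shell(rMyoIn, rMyoOut), shell(rEndoIn, rEndoOut),
                         spacing, noise, seed)
  masks <- list(lumen = .voxelize(g, solid(rEndoIn)),
                myo_wall = .voxelize(g, shell(rMyoIn, rMyoOut)),
                endo_wall = .voxelize(g, shell(rEndoIn, rEndoOut)),
                ecm = .voxelize(g, shell(rEndoOut, rMyoIn)),
                myo_lumen = .voxelize(g, solid(rMyoIn)))
  truth <- list(kind = "nested_tubes",
                myo_volume = pi * (rMyoOut^2 - rMyoIn^2) * height,
                endo_volume = pi * (rEndoOut^2 - rEndoIn^2) * height,
                lumen_volume = pi * rEndoIn^2 * height,
                ecm_volume = pi * (rMyoIn^2 - rEndoOut^2) * height,
                heart_volume = pi * rMyoOut^2 * height,
                height = height,
                poles = rbind(c(0, 0, 0), c(0, 0, height)))
  list(stack = stack, truth = truth, masks = masks,
       spacing = .namedSpacing(spacing), origin = .namedOrigin(g$origin))
}

#' Straight-tube phantom
#'
#' Single straight tube along z: wall shell `rIn`..`rOut` (outer channel)
#' with a thin inner marker shell well inside the lumen. The analytic
#' centreline is the z axis; looping ratio truth is exactly 1.
#'
#' @inheritParams phantomNestedTubes
#' @param rIn,rOut lumen and outer wall radius, micrometres.
#' @export
phantomStraightTube <- function(rIn = 20, rOut = 25, height = 100,
                                spacing = c(0.5, 0.25, 0.25), noise = NULL,
                                seed = 1L, margin = 3) {
  p <- phantomNestedTubes(rMyoOut = rOut, rMyoIn = rIn,
                          rEndoOut = 0.8 * rIn, rEndoIn = 0.6 * rIn,
                          height = height, spacing = spacing, noise = noise,
                          seed = seed, margin = margin)
  p$truth <- c(p$truth[setdiff(names(p$truth), "kind")],
               list(kind = "straight_tube",
                    linear_length = height, looped_length = height,
                    looping_ratio = 1, radius = rIn))
  p$masks$lumen <- p$masks$myo_lumen
  p
}

#' Bent-tube phantom (circular arc)
#'
#' A tube whose midline is a circular arc of radius `R` spanning
#' `angleDeg` degrees in the x-y plane. Closed-form truths: looped length
#' `R * angle`, chord `2 R sin(angle/2)`, looping ratio their quotient
#' (pi/2 for a semicircle).
#'
#' @inheritParams phantomNestedTubes
#' @param R midline bend radius, micrometres.
#' @param angleDeg arc angle in degrees (e.g. 180, 270).
#' @param rIn,rOut lumen and outer wall radius of the tube.
#' @export
phantomBentTube <- function(R = 50, angleDeg = 180, rIn = 10, rOut = 14,
                            spacing = c(0.5, 0.25, 0.25), noise = NULL,
                            seed = 1L, margin = 3) {
  .checkWall(rOut - rIn, spacing, "wall")
  phi <- angleDeg * pi / 180
  ext <- R + rOut + margin
  g <- .makeGrid(c(-ext, ext), c(-ext, ext), c(-rOut - margin, rOut + margin),
                 spacing)
  e0 <- c(R, 0, 0)
  e1 <- c(R * cos(phi), R * sin(phi), 0)
  distArc <- function(X, Y, z) {
    th <- atan2(Y, X)
    th[th < 0] <- th[th < 0] + 2 * pi
    rho <- sqrt(X^2 + Y^2)
    onArc <- th <= phi
    d <- sqrt((rho - R)^2 + z^2)
    d0 <- sqrt((X - e0[1])^2 + (Y - e0[2])^2 + z^2)
    d1 <- sqrt((X - e1[1])^2 + (Y - e1[2])^2 + z^2)
    ifelse(onArc, d, pmin(d0, d1))
  }
  insideWall <- function(X, Y, z) { d <- distArc(X, Y, z); d <= rOut & d > rIn }
  insideInner <- function(X, Y, z) { d <- distArc(X, Y, z); d <= 0.8 * rIn & d > 0.6 * rIn }
  stack <- .phantomStack(g, insideWall, insideInner, spacing, noise, seed)
  masks <- list(lumen = .voxelize(g, function(X, Y, z) distArc(X, Y, z) <= rIn),
                wall = .voxelize(g, insideWall))
  chord <- 2 * R * sin(phi / 2)
  truth <- list(kind = "bent_tube", R = R, angle_deg = angleDeg,
                looped_length = R * phi, linear_length = chord,
                looping_ratio = R * phi / chord,
                poles = rbind(e0, e1))
  list(stack = stack, truth = truth, masks = masks,
       spacing = .namedSpacing(spacing), origin = .namedOrigin(g$origin))
}

#' Concentric-shells phantom (nested spheres)
#'
#' Outer spherical shell `rOuterIn`..`rOuterOut` and inner shell
#' `rInnerIn`..`rInnerOut` about the origin. The analytic distance between
#' the outer layer's internal surface and the inner layer's external
#' surface is `rOuterIn - rInnerOut` everywhere.
#'
#' @inheritParams phantomNestedTubes
#' @param rOuterOut,rOuterIn,rInnerOut,rInnerIn shell radii, micrometres.
#' @export
phantomConcentricShells <- function(rOuterIn = 30, rOuterOut = 34,
                                    rInnerOut = 20, rInnerIn = 17,
                                    spacing = c(0.5, 0.25, 0.25),
                                    noise = NULL, seed = 1L, margin = 3) {
  stopifnot(rOuterOut > rOuterIn, rOuterIn > rInnerOut, rInnerOut > rInnerIn)
  ext <- rOuterOut + margin
  g <- .makeGrid(c(-ext, ext), c(-ext, ext), c(-ext, ext), spacing)
  shell <- function(rin, rout) function(X, Y, z) {
    r2 <- X^2 + Y^2 + z^2
    r2 <= rout^2 & r2 > rin^2
  }
  ball <- function(r) function(X, Y, z) X^2 + Y^2 + z^2 <= r^2
  stack <- .phantomStack(g, shell(rOuterIn, rOuterOut),
                         shell(rInnerIn, rInnerOut), spacing, noise, seed)
  masks <- list(outer_lumen = .voxelize(g, ball(rOuterIn)),
                inner_solid = .voxelize(g, ball(rInnerOut)))
  truth <- list(kind = "concentric_shells",
                gap_thickness = rOuterIn - rInnerOut,
                outer_lumen_volume = 4 / 3 * pi * rOuterIn^3,
                inner_volume = 4 / 3 * pi * rInnerOut^3)
  list(stack = stack, truth = truth, masks = masks,
       spacing = .namedSpacing(spacing), origin = .namedOrigin(g$origin))
}

#' Bulged-tube phantom
#'
#' Straight tube along z whose lumen radius carries a Gaussian bump:
#' `r(z) = r0 + amp * exp(-(z - zCentre)^2 / (2 width^2))`. Truth: the
#' maximal distance from the axis to the lumen surface is `r0 + amp`,
#' attained at `zCentre`.
#'
#' @inheritParams phantomNestedTubes
#' @param r0 base lumen radius; `amp`, `width`, `zCentre` bump parameters;
#'   `wall` wall thickness (all micrometres).
#' @param amp,width,zCentre,wall see `r0`.
#' @export
phantomBulgedTube <- function(r0 = 20, amp = 10, width = 12, zCentre = 50,
                              height = 100, wall = 5,
                              spacing = c(0.5, 0.25, 0.25), noise = NULL,
                              seed = 1L, margin = 3) {
  .checkWall(wall, spacing, "wall")
  rmax <- r0 + amp
  g <- .makeGrid(c(-rmax - wall - margin, rmax + wall + margin),
                 c(-rmax - wall - margin, rmax + wall + margin),
                 c(-margin, height + margin), spacing)
  rz <- function(z) r0 + amp * exp(-(z - zCentre)^2 / (2 * width^2))
  insideWall <- function(X, Y, z) {
    if (z < 0 || z > height) return(matrix(FALSE, nrow(X), ncol(X)))
    r2 <- X^2 + Y^2
    r2 <= (rz(z) + wall)^2 & r2 > rz(z)^2
  }
  insideInner <- function(X, Y, z) {
    if (z < 0 || z > height) return(matrix(FALSE, nrow(X), ncol(X)))
    r2 <- X^2 + Y^2
    r2 <= (0.5 * rz(z))^2 & r2 > (0.35 * rz(z))^2
  }
  stack <- .phantomStack(g, insideWall, insideInner, spacing, noise, seed)
  masks <- list(lumen = .voxelize(g, function(X, Y, z) {
    if (z < 0 || z > height) return(matrix(FALSE, nrow(X), ncol(X)))
    X^2 + Y^2 <= rz(z)^2
  }))
  truth <- list(kind = "bulged_tube", r0 = r0, max_radius = r0 + amp,
                bump_z = zCentre, bump_width = width, height = height,
                poles = rbind(c(0, 0, 0), c(0, 0, height)))
  list(stack = stack, truth = truth, masks = masks,
       spacing = .namedSpacing(spacing), origin = .namedOrigin(g$origin))
}

#' Two-chamber phantom
#'
#' Two overlapping ellipsoidal chambers whose long axes meet at a known
#' angle in the x-y (ventral-view) plane: chamber A elongated along +y,
#' chamber B along +x, joined around the origin (the "atrioventricular"
#' junction). Truth: ventral-view inter-chamber angle 90 degrees.
#'
#' @inheritParams phantomNestedTubes
#' @param semiLong,semiShort ellipsoid semi-axes, micrometres.
#' @param offset centre offset of each chamber from the junction.
#' @export
phantomTwoChamber <- function(semiLong = 35, semiShort = 15, offset = 30,
                              spacing = c(0.5, 0.25, 0.25), noise = NULL,
                              seed = 1L, margin = 3) {
  ext <- offset + semiLong + margin
  g <- .makeGrid(c(-semiShort - margin, ext), c(-semiShort - margin, ext),
                 c(-semiShort - margin, semiShort + margin), spacing)
  inA <- function(X, Y, z)
    (X / semiShort)^2 + ((Y - offset) / semiLong)^2 + (z / semiShort)^2 <= 1
  inB <- function(X, Y, z)
    ((X - offset) / semiLong)^2 + (Y / semiShort)^2 + (z / semiShort)^2 <= 1
  union <- function(X, Y, z) inA(X, Y, z) | inB(X, Y, z)
  scaled <- function(X, Y, z)
    (X / (0.7 * semiShort))^2 + ((Y - offset) / (0.7 * semiLong))^2 +
      (z / (0.7 * semiShort))^2 <= 1 |
    ((X - offset) / (0.7 * semiLong))^2 + (Y / (0.7 * semiShort))^2 +
      (z / (0.7 * semiShort))^2 <= 1
  stack <- .phantomStack(g, union, scaled, spacing, noise, seed)
  masks <- list(solid = .voxelize(g, union))
  truth <- list(kind = "two_chamber",
                axisA = c(0, 1, 0), axisB = c(1, 0, 0),
                ventral_between_angle = 90,
                junction = c(0, 0, 0),
                apexA = c(0, offset + semiLong, 0),
                apexB = c(offset + semiLong, 0, 0))
  list(stack = stack, truth = truth, masks = masks,
       spacing = .namedSpacing(spacing), origin = .namedOrigin(g$origin))
}

#' Cubic nuclei lattice phantom
#'
#' Simple cubic lattice of nuclei with lattice constant `a`; for interior
#' seeds the k = 4 nearest neighbours all sit at distance exactly `a`, so
#' the internuclear distance truth is `a`.
#'
#' @param a lattice constant, micrometres.
#' @param n lattice extents `(nx, ny, nz)` in points.
#' @param jitter optional uniform jitter amplitude (micrometres, default 0).
#' @param seed RNG seed for the jitter.
#' @return list with `nuclei` (a [NucleiSet-class]) and `truth`.
#' @export
phantomNucleiLattice <- function(a = 8, n = c(7, 7, 7), jitter = 0,
                                 seed = 1L) {
  gx <- (seq_len(n[1]) - 1) * a
  gy <- (seq_len(n[2]) - 1) * a
  gz <- (seq_len(n[3]) - 1) * a
  P <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  interior <- P[, 1] > 0 & P[, 1] < max(gx) &
              P[, 2] > 0 & P[, 2] < max(gy) &
              P[, 3] > 0 & P[, 3] < max(gz)
  if (jitter > 0)
    P <- .withSeed(seed, P + matrix(stats::runif(length(P), -jitter, jitter),
                                    nrow(P)))
  list(nuclei = NucleiSet(P), interior = interior,
       truth = list(kind = "nuclei_lattice", a = a, ind_interior = a))
}

#' Generate a phantom by kind
#'
#' Dispatcher over the phantom constructors; `params` are passed through.
#' Generation is seed-deterministic: the same spec and seed reproduce the
#' same stack bit for bit.
#'
#' @param kind one of `"straight_tube"`, `"bent_tube"`, `"nested_tubes"`,
#'   `"concentric_shells"`, `"bulged_tube"`, `"two_chamber"`,
#'   `"nuclei_lattice"`.
#' @param params named list of geometry parameters for the kind.
#' @param spacing,noise,seed forwarded to the constructor.
#' @return the constructor's result (stack/truth/masks or nuclei/truth).
#' @export
generatePhantom <- function(kind, params = list(),
                            spacing = c(0.5, 0.25, 0.25), noise = NULL,
                            seed = 1L) {
  fun <- switch(kind,
                straight_tube = phantomStraightTube,
                bent_tube = phantomBentTube,
                nested_tubes = phantomNestedTubes,
                concentric_shells = phantomConcentricShells,
                bulged_tube = phantomBulgedTube,
                two_chamber = phantomTwoChamber,
                nuclei_lattice = phantomNucleiLattice,
                stop("unknown phantom kind: ", kind))
  if (kind == "nuclei_lattice")
    do.call(fun, c(params, list(seed = seed)))
  else
    do.call(fun, c(params, list(spacing = spacing, noise = noise,
                                seed = seed)))
}
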