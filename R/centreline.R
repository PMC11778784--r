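## centreline: lumen midline between the venous and arterial pole anchors.
##
## The continuous formulation ("the 3D curve within the lumen whose minimal
## distance from the tissue wall is maximal", classically computed from the
## Voronoi diagram / maximal inscribed spheres of the lumen surface) is
## realized discretely: the Euclidean distance transform of the lumen gives
## every voxel's inscribed-sphere radius, and the centreline is the
## minimum-cost path on the 26-connected voxel graph with edge cost
## step_length / (eps + mean inscribed radius), i.e. the path that stays as
## deep inside the lumen as possible. The raw grid path is then Gaussian
## smoothed (mirror-padded at the ends, so the anchors stay put) and
## resampled uniformly.

# trilinear interpolation of a [y,x,z] array at physical (x,y,z) points
.interp3 <- function(arr, spacing, origin, pts) {
  d <- dim(arr)
  gj <- (pts[, 2] - origin[["y"]]) / spacing[["dy"]] + 1
  gi <- (pts[, 1] - origin[["x"]]) / spacing[["dx"]] + 1
  gk <- (pts[, 3] - origin[["z"]]) / spacing[["dz"]] + 1
  j0 <- pmin(pmax(floor(gj), 1), d[1] - 1); fj <- gj - j0
  i0 <- pmin(pmax(floor(gi), 1), d[2] - 1); fi <- gi - i0
  k0 <- pmin(pmax(floor(gk), 1), d[3] - 1); fk <- gk - k0
  fj <- pmin(pmax(fj, 0), 1); fi <- pmin(pmax(fi, 0), 1); fk <- pmin(pmax(fk, 0), 1)
  at <- function(j, i, k) arr[cbind(j, i, k)]
  v000 <- at(j0, i0, k0);     v100 <- at(j0 + 1, i0, k0)
  v010 <- at(j0, i0 + 1, k0); v110 <- at(j0 + 1, i0 + 1, k0)
  v001 <- at(j0, i0, k0 + 1); v101 <- at(j0 + 1, i0, k0 + 1)
  v011 <- at(j0, i0 + 1, k0 + 1); v111 <- at(j0 + 1, i0 + 1, k0 + 1)
  (1 - fk) * ((1 - fi) * ((1 - fj) * v000 + fj * v100) +
              fi * ((1 - fj) * v010 + fj * v110)) +
  fk * ((1 - fi) * ((1 - fj) * v001 + fj * v101) +
        fi * ((1 - fj) * v011 + fj * v111))
}

.cumArclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
}

# uniform arclength resampling of a polyline
.resamplePolyline <- function(pts, step) {
  s <- .cumArclength(pts)
  L <- s[length(s)]
  if (L == 0) return(pts[1, , drop = FALSE])
  snew <- seq(0, L, by = step)
  if (snew[length(snew)] < L) snew <- c(snew, L)
  out <- cbind(stats::approx(s, pts[, 1], xout = snew)$y,
               stats::approx(s, pts[, 2], xout = snew)$y,
               stats::approx(s, pts[, 3], xout = snew)$y)
  colnames(out) <- c("x", "y", "z")
  out
}

# Gaussian smoothing along arclength with mirror padding at both ends
.smoothPolyline <- function(pts, sigma, step) {
  n <- nrow(pts)
  if (sigma <= 0 || n < 5) return(pts)
  npad <- min(n - 1L, ceiling(3 * sigma / step))
  head <- 2 * matrix(pts[1, ], npad, 3, byrow = TRUE) -
    pts[seq(npad + 1L, 2L), , drop = FALSE]
  tail <- 2 * matrix(pts[n, ], npad, 3, byrow = TRUE) -
    pts[seq(n - 1L, n - npad), , drop = FALSE]
  ext <- rbind(head, pts, tail)
  w <- stats::dnorm(seq(-npad, npad) * step, sd = sigma)
  w <- w / sum(w)
  sm <- sapply(1:3, function(c) stats::filter(ext[, c], w, sides = 2))
  out <- sm[npad + seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

# snap a physical point to a nearby foreground voxel (within `reach` voxels)
.snapToMask <- function(p, arr, spacing, origin, reach = 2L, what = "pole") {
  d <- dim(arr)
  v <- .physToVoxel(p, spacing, origin)
  rng <- function(c, n) {
    lo <- max(1L, c - reach); hi <- min(n, c + reach)
    if (lo > hi) integer(0) else lo:hi
  }
  best <- NULL; bestd <- Inf
  for (k in rng(v[["k"]], d[3])) for (i in rng(v[["i"]], d[2]))
    for (j in rng(v[["j"]], d[1])) {
      if (!arr[j, i, k]) next
      q <- .voxelToPhys(j, i, k, spacing, origin)
      dd <- sum((q - p)^2)
      if (dd < bestd) { bestd <- dd; best <- c(j, i, k) }
    }
  if (is.null(best))
    stop(what, " lies outside the lumen mask")
  best
}

#' Extract the lumen centreline between two poles
#'
#' @param lumen the lumen [VoxelMask-class] (filled internal contour of the
#'   outer tissue layer).
#' @param poleA,poleB venous / arterial pole anchor points, physical
#'   `(x, y, z)` micrometres, inside (or within ~2 voxels of) the lumen.
#' @param stepSize resampling step in micrometres; default the smallest
#'   spacing component.
#' @param smoothSigma Gaussian smoothing bandwidth along the path,
#'   micrometres; default half the mean inscribed radius along the raw
#'   path (tube-scale smoothing that removes grid jaggedness without
#'   shortcutting bends).
#' @param eps clearance regularizer in the edge cost; default 0.1 x the
#'   smallest spacing component.
#' @return a [Centreline-class] ordered from pole A to pole B, with
#'   per-point inscribed radius from the distance transform.
#' @export
extractCentreline <- function(lumen, poleA, poleB, stepSize = NULL,
                              smoothSigma = NULL, eps = NULL) {
  stopifnot(is(lumen, "VoxelMask"))
  arr <- lumen@voxels
  sp <- lumen@spacing
  orig <- lumen@origin
  d <- dim(arr)
  if (is.null(eps)) eps <- 0.1 * min(sp)
  if (is.null(stepSize)) stepSize <- min(sp)

  va <- .snapToMask(as.numeric(poleA), arr, sp, orig, what = "pole A")
  vb <- .snapToMask(as.numeric(poleB), arr, sp, orig, what = "pole B")

  lab <- array(.cpp_label3d(as.logical(arr), d), d)
  if (lab[va[1], va[2], va[3]] != lab[vb[1], vb[2], vb[3]])
    stop("poles lie in disjoint lumen components")

  edt <- array(.cpp_edt3d(as.logical(arr), d,
                          c(sp[["dy"]], sp[["dx"]], sp[["dz"]])), d)
  path0 <- .cpp_dijkstra_grid(as.logical(arr), as.numeric(edt), d,
                              c(sp[["dy"]], sp[["dx"]], sp[["dz"]]),
                              eps,
                              .linearIndex0(va[1], va[2], va[3], d),
                              .linearIndex0(vb[1], vb[2], vb[3], d))
  if (!length(path0)) stop("no lumen path between the poles")
  k <- path0 %/% (d[1] * d[2])
  r <- path0 %% (d[1] * d[2])
  i <- r %/% d[1]
  j <- r %% d[1]
  pts <- .voxelToPhys(j + 1, i + 1, k + 1, sp, orig)

  radRaw <- edt[cbind(j + 1, i + 1, k + 1)]
  if (is.null(smoothSigma)) smoothSigma <- 0.5 * mean(radRaw)

  pts <- .resamplePolyline(pts, stepSize)
  pts <- .smoothPolyline(pts, smoothSigma, stepSize)
  pts <- .resamplePolyline(pts, stepSize)

  rad <- .interp3(edt, sp, orig, pts)
  Centreline(pts, .cumArclength(pts), rad,
             anchors = rbind(as.numeric(poleA), as.numeric(poleB)))
}

#' Looping metrics of a centreline
#'
#' The linear length is the straight pole-to-pole distance, the looped
#' length is the centreline arclength, and the looping ratio is
#' looped / linear (1 for a straight tube, increasing as the organ loops).
#'
#' @param cl a [Centreline-class].
#' @return list with `linear_length`, `looped_length` (micrometres) and
#'   `looping_ratio`.
#' @export
loopingMetrics <- function(cl) {
  stopifnot(is(cl, "Centreline"))
  lin <- sqrt(sum((cl@anchors[2, ] - cl@anchors[1, ])^2))
  if (lin == 0) stop("pole anchors coincide")
  loop <- max(cl@arclength)
  list(linear_length = lin, looped_length = loop,
       looping_ratio = loop / lin)
}

# least-squares tangent over the terminal `frac` of arclength, pointing
# outward through the terminal point
.endTangent <- function(cl, end = c("A", "B"), frac = 0.05) {
  end <- match.arg(end)
  s <- cl@arclength
  L <- max(s)
  idx <- if (end == "A") which(s <= frac * L) else which(s >= (1 - frac) * L)
  if (length(idx) < 2)
    idx <- if (end == "A") 1:2 else (nrow(cl@points) - 1):nrow(cl@points)
  P <- cl@points[idx, , drop = FALSE]
  Pc <- sweep(P, 2, colMeans(P))
  tang <- svd(Pc, nu = 0, nv = 1)$v[, 1]
  ref <- if (end == "A") cl@points[idx[1], ] - cl@points[idx[length(idx)], ]
         else cl@points[idx[length(idx)], ] - cl@points[idx[1], ]
  if (sum(tang * ref) < 0) tang <- -tang
  .normalize(tang)
}

#' Extend a centreline beyond both poles
#'
#' Prolongs the line at each end along the least-squares tangent of the
#' terminal 5% of arclength; interior points are unchanged. Extension
#' points carry inscribed radius 0 (they lie outside the lumen).
#'
#' @param cl a [Centreline-class].
#' @param extraLength length to add at each end, micrometres (> 0).
#' @return the extended [Centreline-class].
#' @export
extendCentreline <- function(cl, extraLength) {
  stopifnot(is(cl, "Centreline"))
  if (nrow(cl@points) < 2) stop("degenerate single-point centreline")
  if (extraLength <= 0) stop("extraLength must be > 0")
  step <- stats::median(diff(cl@arclength))
  next_ <- max(1L, ceiling(extraLength / step))
  ta <- .endTangent(cl, "A")
  tb <- .endTangent(cl, "B")
  sa <- seq_len(next_) / next_ * extraLength
  headP <- sweep(outer(rev(sa), ta), 2, cl@points[1, ], "+")
  tailP <- sweep(outer(sa, tb), 2, cl@points[nrow(cl@points), ], "+")
  pts <- rbind(headP, cl@points, tailP)
  rad <- c(rep(0, next_), cl@inscribedRadius, rep(0, next_))
  Centreline(pts, .cumArclength(pts), rad, anchors = cl@anchors)
}

#' Crop a centreline to an arclength window
#'
#' @param cl a [Centreline-class].
#' @param from,to arclength bounds in micrometres.
#' @return the cropped [Centreline-class] (arclength restarts at 0).
#' @export
cropCentreline <- function(cl, from, to) {
  stopifnot(is(cl, "Centreline"))
  keep <- cl@arclength >= from & cl@arclength <= to
  if (sum(keep) < 2) stop("crop window retains fewer than 2 points")
  Centreline(cl@points[keep, , drop = FALSE],
             cl@arclength[keep] - min(cl@arclength[keep]),
             cl@inscribedRadius[keep], anchors = cl@anchors)
}

#' Persist a centreline
#'
#' `writeCentrelineCsv` writes columns x, y, z, arclength,
#' inscribed_radius (micrometres); `writeCentrelineVTK` writes a legacy-VTK
#' polyline.
#'
#' @param cl a [Centreline-class].
#' @param path output path.
#' @name centreline-io
NULL

#' @rdname centreline-io
#' @export
writeCentrelineCsv <- function(cl, path) {
  df <- data.frame(x = cl@points[, 1], y = cl@points[, 2],
                   z = cl@points[, 3], arclength = cl@arclength,
                   inscribed_radius = cl@inscribedRadius)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname centreline-io
#' @export
writeCentrelineVTK <- function(cl, path) {
  n <- nrow(cl@points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "centreline", "ASCII",
               "DATASET POLYDATA", paste("POINTS", n, "float")), con)
  writeLines(apply(cl@points, 1, paste, collapse = " "), con)
  writeLines(paste("LINES 1", n + 1L), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  invisible(path)
}
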