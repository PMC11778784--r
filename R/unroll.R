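## unroll: standardized 2D heatmaps from per-vertex scalars on tubular
## meshes, cross-specimen averaging, and CSV export.
##
## A defined number of planes is cut through the mesh transverse to the
## (extended) centreline; on each cutting plane the intersection loop is
## parameterized by the signed circumferential angle about the centreline
## station, anchored at the ventral direction (0 degrees; dorsal-most point
## +/-180 degrees), and the scalar is averaged per angle bin. Stations or
## bins the mesh does not reach stay missing (NA) and are never imputed.

.angleCenters <- function(q) -180 + (seq_len(q) - 0.5) * (360 / q)

#' Unroll a heatmapped tubular mesh to 2D
#'
#' @param mesh a [SurfaceMesh-class] carrying a per-vertex scalar
#'   (see [thicknessMap()], [ballooningMap()]).
#' @param cl a [Centreline-class], extended beyond both poles
#'   (see [extendCentreline()]).
#' @param dorsalRef unit vector pointing dorsally; its negation projected
#'   into each cutting plane defines the 0-degree (ventral) direction.
#' @param nPlanes number of cutting planes along the centreline.
#' @param nAngleBins number of circumferential angle bins.
#' @return a [Heatmap2D-class] (`nPlanes` rows from the venous to the
#'   arterial end x `nAngleBins` columns). When a plane cuts the mesh in
#'   several closed loops (e.g. both chambers of a looped organ) the loop
#'   whose centroid is nearest the station is kept; the number of discarded
#'   loops is reported as attribute `discarded_loops`.
#' @export
unrollHeatmap <- function(mesh, cl, dorsalRef, nPlanes = 100L,
                          nAngleBins = 72L) {
  stopifnot(is(mesh, "SurfaceMesh"), is(cl, "Centreline"))
  if (length(mesh@scalar) != nrow(mesh@vertices))
    stop("mesh carries no per-vertex scalar")
  dorsalRef <- .normalize(as.numeric(dorsalRef))
  L <- max(cl@arclength)
  sStations <- seq(0, L, length.out = nPlanes)
  P <- cbind(stats::approx(cl@arclength, cl@points[, 1], xout = sStations)$y,
             stats::approx(cl@arclength, cl@points[, 2], xout = sStations)$y,
             stats::approx(cl@arclength, cl@points[, 3], xout = sStations)$y)
  Tg <- .polylineTangents(P)

  V <- mesh@vertices
  Fc <- mesh@faces
  sc <- mesh@scalar
  q <- as.integer(nAngleBins)
  binEdges <- seq(-180, 180, by = 360 / q)
  vals <- matrix(NA_real_, nPlanes, q)
  discarded <- 0L

  for (m in seq_len(nPlanes)) {
    p <- P[m, ]; t <- Tg[m, ]
    if (!all(is.finite(t))) stop("degenerate tangent at station ", m)
    dproj <- dorsalRef - sum(dorsalRef * t) * t
    if (sqrt(sum(dproj^2)) < 1e-8)
      stop("degenerate tangent at station ", m,
           ": dorsal reference parallel to the centreline")
    v0 <- -dproj / sqrt(sum(dproj^2))
    w <- .cross3(t, dorsalRef)
    w <- .normalize(w - sum(w * t) * t)

    s <- (V[, 1] - p[1]) * t[1] + (V[, 2] - p[2]) * t[2] +
         (V[, 3] - p[3]) * t[3]
    s[s == 0] <- 1e-12
    sgn <- s > 0
    cross <- sgn[Fc[, 1]] + sgn[Fc[, 2]] + sgn[Fc[, 3]]
    fIdx <- which(cross == 1L | cross == 2L)
    if (!length(fIdx)) next

    # crossing points live on mesh edges; key edges so adjacent faces share
    edgeKey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    segA <- character(length(fIdx)); segB <- character(length(fIdx))
    ptsList <- new.env(parent = emptyenv())
    for (fi in seq_along(fIdx)) {
      f <- Fc[fIdx[fi], ]
      ss <- s[f]
      pos <- f[ss > 0]; neg <- f[ss < 0]
      # two crossing edges: (each pos-neg pair that is an actual face edge)
      if (length(pos) == 1L) es <- list(c(pos, neg[1]), c(pos, neg[2]))
      else es <- list(c(pos[1], neg), c(pos[2], neg))
      keys <- character(2)
      for (e in 1:2) {
        a <- es[[e]][1]; b <- es[[e]][2]
        keys[e] <- edgeKey(a, b)
        if (!exists(keys[e], envir = ptsList, inherits = FALSE)) {
          ta <- s[a] / (s[a] - s[b])
          qpt <- V[a, ] + ta * (V[b, ] - V[a, ])
          qsc <- sc[a] + ta * (sc[b] - sc[a])
          assign(keys[e], c(qpt, qsc), envir = ptsList)
        }
      }
      segA[fi] <- keys[1]; segB[fi] <- keys[2]
    }

    # group crossing edges into loops via union-find over face segments
    keys <- unique(c(segA, segB))
    comp <- seq_along(keys); names(comp) <- keys
    findRoot <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
    for (fi in seq_along(segA)) {
      ra <- findRoot(match(segA[fi], keys))
      rb <- findRoot(match(segB[fi], keys))
      if (ra != rb) comp[rb] <- ra
    }
    roots <- vapply(seq_along(keys), findRoot, 1L)
    pts <- t(vapply(keys, function(k) get(k, envir = ptsList),
                    numeric(4)))
    loops <- split(seq_along(keys), roots)
    if (length(loops) > 1L) {
      cen <- vapply(loops, function(ii) {
        colMeans(pts[ii, 1:3, drop = FALSE])
      }, numeric(3))
      d2 <- colSums((cen - p)^2)
      keep <- loops[[which.min(d2)]]
      discarded <- discarded + length(loops) - 1L
    } else keep <- loops[[1]]

    U <- pts[keep, 1:3, drop = FALSE]
    scal <- pts[keep, 4]
    rel <- sweep(U, 2, p)
    uperp <- rel - outer(as.numeric(rel %*% t), t)
    ang <- atan2(uperp %*% w, uperp %*% v0) * 180 / pi
    bin <- findInterval(ang, binEdges, rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > q] <- q
    mv <- tapply(scal, bin, mean)
    vals[m, as.integer(names(mv))] <- mv
  }

  rowsPresent <- which(rowSums(!is.na(vals)) > 0)
  if (length(rowsPresent)) {
    interiorEmpty <- setdiff(seq(min(rowsPresent), max(rowsPresent)),
                             rowsPresent)
    if (length(interiorEmpty))
      warning(length(interiorEmpty),
              " interior station(s) do not intersect the mesh; rows left missing")
  }

  hm <- new("Heatmap2D", values = vals, arcCenters = sStations,
            angleCenters = .angleCenters(q), count = NULL, sd = NULL,
            scalarName = if (is.na(mesh@scalarName)) "scalar" else mesh@scalarName,
            scalarUnits = if (is.na(mesh@scalarUnits)) "" else mesh@scalarUnits,
            regionLabels = list())
  attr(hm, "discarded_loops") <- discarded
  hm
}

#' Average heatmaps across specimens
#'
#' Per-cell mean over contributing (non-missing) maps; cells with zero
#' contributors stay missing — gaps are never imputed. The per-cell
#' contributor count and the sample (n-1) standard deviation are returned
#' alongside (SD is `NA` where fewer than two maps contribute).
#'
#' @param maps list of [Heatmap2D-class] with identical shape and axes.
#' @return a [Heatmap2D-class] with `count` and `sd` matrices filled.
#' @export
averageHeatmaps <- function(maps) {
  if (!length(maps)) stop("empty heatmap list")
  stopifnot(all(vapply(maps, is, TRUE, "Heatmap2D")))
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(dim(m@values), dim(ref@values)) ||
        max(abs(m@angleCenters - ref@angleCenters)) > 1e-9 ||
        max(abs(m@arcCenters - ref@arcCenters)) > 1e-6)
      stop("heatmaps differ in shape or axes")
  }
  arr <- simplify2array(lapply(maps, heatmapValues))   # P x Q x n
  cnt <- apply(!is.na(arr), c(1, 2), sum)
  mean_ <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  sd_ <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  })
  new("Heatmap2D", values = mean_, arcCenters = ref@arcCenters,
      angleCenters = ref@angleCenters, count = cnt, sd = sd_,
      scalarName = ref@scalarName, scalarUnits = ref@scalarUnits,
      regionLabels = ref@regionLabels)
}

#' Label arclength bands on a heatmap
#'
#' @param map a [Heatmap2D-class].
#' @param bands named list of `c(from, to)` arclength windows in
#'   micrometres (e.g. atrial/ventricular outer/inner curvature bands).
#' @return the map with `regionLabels` set.
#' @export
labelHeatmapBands <- function(map, bands) {
  stopifnot(is(map, "Heatmap2D"))
  map@regionLabels <- bands
  map
}

#' Per-band mean of a heatmap
#'
#' @param map a [Heatmap2D-class] with labelled bands.
#' @return data.frame with one row per band (`band`, `mean`, `n_cells`).
#' @export
heatmapBandSummary <- function(map) {
  stopifnot(is(map, "Heatmap2D"))
  if (!length(map@regionLabels)) stop("no labelled bands")
  rows <- lapply(names(map@regionLabels), function(nm) {
    w <- map@regionLabels[[nm]]
    sel <- map@arcCenters >= w[1] & map@arcCenters <= w[2]
    v <- map@values[sel, , drop = FALSE]
    data.frame(band = nm, mean = mean(v, na.rm = TRUE),
               n_cells = sum(!is.na(v)))
  })
  do.call(rbind, rows)
}

#' Export / import a heatmap as CSV
#'
#' Comma-separated, '.' decimal; the header row holds the angle bin centres
#' (degrees), the first column the arclength bin centres (micrometres).
#' Missing cells serialize as empty fields, never zeros; the round trip is
#' bit-exact on present cells.
#'
#' @param map a [Heatmap2D-class].
#' @param path CSV path.
#' @name heatmap-io
NULL

#' @rdname heatmap-io
#' @export
exportHeatmapCsv <- function(map, path) {
  stopifnot(is(map, "Heatmap2D"))
  # %.17g serializes doubles losslessly, so present cells round-trip
  # bit-exactly through read.csv
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  }
  header <- paste(c("arclength_um", sprintf("%.17g", map@angleCenters)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(map@values)), function(r)
    paste(c(sprintf("%.17g", map@arcCenters[r]), fmt(map@values[r, ])),
          collapse = ","), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname heatmap-io
#' @export
readHeatmapCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  arc <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  ang <- as.numeric(names(df)[-1])
  new("Heatmap2D", values = vals, arcCenters = arc, angleCenters = ang,
      count = NULL, sd = NULL, scalarName = "scalar", scalarUnits = "",
      regionLabels = list())
}
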