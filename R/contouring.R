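## contouring: per-slice contour detection, internal/external classification
## by containment parity, mask filling, and the contour library.
##
## A slice is thresholded (Otsu by default), boundary polygons of the
## foreground are traced at the 0.5 iso-level of the binary image (with a
## one-pixel zero pad, so contours touching the image border are closed
## along the border), and each polygon's containment depth is counted:
## even depth = external contour, odd depth = internal (lumen) contour.
## Filled masks are unions of scanline-filled polygons by role, and the
## tissue mask is their exclusive disjunction (XOR).

# even-odd ray-casting point-in-polygon (poly: closed, columns (y, x))
.pointInPolygon <- function(pt, poly) {
  y <- pt[1]; x <- pt[2]
  py <- poly[, 1]; px <- poly[, 2]
  n <- nrow(poly) - 1L
  inside <- FALSE
  for (e in seq_len(n)) {
    y1 <- py[e]; y2 <- py[e + 1L]
    if ((y1 > y) != (y2 > y)) {
      xint <- px[e] + (y - y1) / (y2 - y1) * (px[e + 1L] - px[e])
      if (x < xint) inside <- !inside
    }
  }
  inside
}

.polygonArea <- function(poly) {
  y <- poly[, 1]; x <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

.closePolygon <- function(poly) {
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ])))
    poly <- rbind(poly, poly[1, ])
  poly
}

#' Detect closed contours in one z-slice
#'
#' Thresholds the slice (per-slice Otsu or a fixed level), traces the 0.5
#' iso-contours of the binary foreground, and annotates each closed polygon
#' with its enclosed area and containment depth (0 = outermost). Contours
#' touching the image border are closed along the border. An empty
#' foreground yields an empty list, not an error.
#'
#' @param img 2D intensity matrix `[y, x]`.
#' @param thresholdPolicy `"auto"` (per-slice Otsu) or `"fixed"`.
#' @param level threshold level for `thresholdPolicy = "fixed"`, on the
#'   intensity scale of `img`.
#' @param minArea drop polygons enclosing fewer pixels than this.
#' @return list of closed polygons (n x 2 matrices, columns `(y, x)` in
#'   voxel coordinates) with attributes `depth` and `area`.
#' @export
detectSliceContours <- function(img, thresholdPolicy = c("auto", "fixed"),
                                level = NULL, minArea = 0) {
  thresholdPolicy <- match.arg(thresholdPolicy)
  if (length(img) == 0) stop("empty image")
  img <- as.matrix(img)
  if (thresholdPolicy == "fixed") {
    if (is.null(level) || !is.finite(level))
      stop("a finite fixed threshold level is required")
    thr <- level
  } else {
    maxv <- max(img)
    if (maxv <= 0) return(list())
    thr <- EBImage::otsu(img / maxv, range = c(0, 1)) * maxv
  }
  B <- img > thr
  if (!any(B)) return(list())

  nr <- nrow(B); nc <- ncol(B)
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- B
  # grid coordinates such that original pixel (j, i) sits at (j, i)
  lines <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L), z = P,
                                   levels = 0.5)
  polys <- lapply(lines, function(l) .closePolygon(cbind(y = l$x, x = l$y)))
  areas <- vapply(polys, .polygonArea, 0)
  keep <- areas >= minArea
  polys <- polys[keep]; areas <- areas[keep]
  if (!length(polys)) return(list())

  # containment depth: count enclosing polygons, probing with an edge
  # midpoint (contour vertices lie on grid-line crossings, so midpoints of
  # one contour generically avoid the others)
  n <- length(polys)
  depth <- integer(n)
  for (a in seq_len(n)) {
    probe <- (polys[[a]][1, ] + polys[[a]][2, ]) / 2
    for (b in seq_len(n)) {
      if (a != b && .pointInPolygon(probe, polys[[b]]))
        depth[a] <- depth[a] + 1L
    }
  }
  mapply(function(p, d, ar) {
    attr(p, "depth") <- d; attr(p, "area") <- ar; p
  }, polys, depth, areas, SIMPLIFY = FALSE)
}

#' Classify detected contours as internal or external
#'
#' Deterministic parity rule: even containment depth outlines the external
#' border of the tissue, odd depth outlines a lumen. Consistency is checked:
#' every internal polygon must be geometrically contained in some external
#' polygon.
#'
#' @param polygons output of [detectSliceContours()].
#' @param sliceIndex 1-based z index recorded in the result.
#' @param provenance `"auto"` or `"manual"`.
#' @return a [SliceContours-class].
#' @export
classifyContours <- function(polygons, sliceIndex = 1L,
                             provenance = "auto") {
  depth <- vapply(polygons, function(p) as.integer(attr(p, "depth")), 1L)
  roles <- c("external", "internal")[depth %% 2L + 1L]
  for (a in which(roles == "internal")) {
    probe <- (polygons[[a]][1, ] + polygons[[a]][2, ]) / 2
    ok <- any(vapply(which(roles == "external"), function(b)
      .pointInPolygon(probe, polygons[[b]]), TRUE))
    if (!ok)
      stop("inconsistent containment: internal contour ", a,
           " lies in no external contour")
  }
  new("SliceContours", sliceIndex = as.integer(sliceIndex),
      polygons = lapply(polygons, function(p) { attributes(p) <- list(dim = dim(p)); p }),
      roles = roles, depth = depth, provenance = provenance)
}

#' Fill classified contours into slice masks
#'
#' Each polygon is rasterized by even-odd scanline filling at pixel centres
#' (boundary pixels belong to the filled region); filled external and
#' internal masks are unions by role and the tissue mask is their XOR,
#' bit-exactly.
#'
#' @param contours a [SliceContours-class].
#' @param shape image shape `c(ny, nx)`.
#' @return a [SliceMasks-class].
#' @export
fillMasks <- function(contours, shape) {
  stopifnot(is(contours, "SliceContours"))
  ny <- shape[1]; nx <- shape[2]
  ext <- matrix(FALSE, ny, nx)
  int <- matrix(FALSE, ny, nx)
  for (q in seq_along(contours@polygons)) {
    p <- contours@polygons[[q]]
    f <- .cpp_fill_polygon(p[, 1], p[, 2], ny, nx)
    if (contours@roles[q] == "external") ext <- ext | f else int <- int | f
  }
  if (any(int & !ext))
    stop("internal contour not contained in any external contour")
  new("SliceMasks", filledExternal = ext, filledInternal = int,
      tissue = xor(ext, int))
}

#' Build the contour library of a stack
#'
#' Runs contour detection, parity classification and mask filling on every
#' slice of every requested channel. Per-slice manual overrides substitute
#' the automatic polygons before filling; provenance (auto vs manual) is
#' recorded per slice.
#'
#' @param stack an [IntensityStack-class].
#' @param policy a list of per-channel settings, or one shared list, with
#'   elements `threshold` (`"auto"`/`"fixed"`), `level`, `minArea`.
#' @param overrides optional named list (per channel) mapping slice index
#'   (as character) to `list(polygons = <list of closed (y,x) matrices>,
#'   roles = <character>)`; see [readContourOverrides()].
#' @return a [ContourLibrary-class].
#' @export
buildContourLibrary <- function(stack, policy = list(threshold = "auto",
                                                     level = NULL,
                                                     minArea = 4),
                                overrides = NULL) {
  stopifnot(is(stack, "IntensityStack"))
  chs <- stack@channelNames
  perChannel <- !is.null(names(policy)) && all(names(policy) %in% chs) &&
    length(policy) && is.list(policy[[1]])
  contours <- list(); masks <- list()
  for (ch in chs) {
    pol <- if (perChannel) policy[[ch]] else policy
    arr <- stack@voxels[[ch]]
    d <- dim(arr)
    ov <- overrides[[ch]]
    if (!is.null(ov)) {
      bad <- setdiff(as.integer(names(ov)), seq_len(d[3]))
      if (length(bad))
        stop("override references nonexistent slice(s): ",
             paste(bad, collapse = ", "))
    }
    slcs <- vector("list", d[3])
    ext <- array(FALSE, d); int <- array(FALSE, d); tis <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      ovk <- ov[[as.character(k)]]
      if (!is.null(ovk)) {
        polys <- lapply(ovk$polygons, function(p) .closePolygon(as.matrix(p)))
        depth <- as.integer(ovk$roles == "internal") # depth surrogate
        sc <- new("SliceContours", sliceIndex = k, polygons = polys,
                  roles = as.character(ovk$roles), depth = depth,
                  provenance = "manual")
      } else {
        det <- detectSliceContours(arr[, , k],
                                   thresholdPolicy = pol$threshold %||% "auto",
                                   level = pol$level,
                                   minArea = pol$minArea %||% 0)
        sc <- classifyContours(det, sliceIndex = k)
      }
      mk <- fillMasks(sc, d[1:2])
      slcs[[k]] <- sc
      ext[, , k] <- mk@filledExternal
      int[, , k] <- mk@filledInternal
      tis[, , k] <- mk@tissue
    }
    contours[[ch]] <- slcs
    masks[[ch]] <- list(filled_external = ext, filled_internal = int,
                        tissue = tis)
  }
  new("ContourLibrary", contours = contours, masks = masks,
      spacing = stack@spacing, origin = stack@origin, channelNames = chs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a 3D mask from a contour library
#'
#' @param lib a [ContourLibrary-class].
#' @param channel channel name.
#' @param which `"tissue"`, `"filled_external"` or `"filled_internal"`.
#' @return a [VoxelMask-class] on the source grid.
#' @export
libraryMask <- function(lib, channel,
                        which = c("tissue", "filled_external",
                                  "filled_internal")) {
  stopifnot(is(lib, "ContourLibrary"))
  which <- match.arg(which)
  arr <- lib@masks[[channel]][[which]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  VoxelMask(arr, spacing = lib@spacing, origin = lib@origin,
            label = paste(channel, which, sep = ":"))
}

#' Slice accessors for a contour library
#'
#' @param lib a [ContourLibrary-class].
#' @param channel channel name.
#' @param slice 1-based z index.
#' @return `sliceContours`: the stored [SliceContours-class];
#'   `sliceMasks`: the per-slice [SliceMasks-class] reconstructed from the
#'   stacked mask arrays.
#' @name library-slices
NULL

#' @rdname library-slices
#' @export
sliceContours <- function(lib, channel, slice) {
  stopifnot(is(lib, "ContourLibrary"))
  lib@contours[[channel]][[slice]]
}

#' @rdname library-slices
#' @export
sliceMasks <- function(lib, channel, slice) {
  stopifnot(is(lib, "ContourLibrary"))
  mk <- lib@masks[[channel]]
  new("SliceMasks", filledExternal = mk$filled_external[, , slice],
      filledInternal = mk$filled_internal[, , slice],
      tissue = mk$tissue[, , slice])
}

#' Persist a contour library
#'
#' Writes one JSON per channel (polygons, roles, provenance) and the three
#' mask stacks as TIFF + sidecar under `dir`.
#'
#' @param lib a [ContourLibrary-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeContourLibrary <- function(lib, dir) {
  stopifnot(is(lib, "ContourLibrary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in lib@channelNames) {
    js <- lapply(lib@contours[[ch]], function(sc)
      list(slice = sc@sliceIndex,
           provenance = sc@provenance,
           roles = sc@roles,
           polygons = lapply(sc@polygons, function(p) unname(as.matrix(p)))))
    jsonlite::write_json(js, file.path(dir, paste0("contours_", ch, ".json")),
                         auto_unbox = TRUE, digits = NA)
    for (w in c("tissue", "filled_external", "filled_internal")) {
      m <- lib@masks[[ch]][[w]]
      st <- IntensityStack(array(as.integer(m), dim(m)),
                           spacing = lib@spacing, channelNames = w,
                           origin = lib@origin)
      writeStack(st, file.path(dir, paste0(ch, "_", w, ".tif")), bits = 8L)
    }
  }
  invisible(dir)
}

#' Read a per-slice contour override file
#'
#' JSON format: `{ "<channel>": { "<slice>": { "roles": [...],
#' "polygons": [ [[y, x], ...], ... ] } } }`.
#'
#' @param path JSON file path.
#' @return nested override list as consumed by [buildContourLibrary()].
#' @export
readContourOverrides <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(ov, function(chv) lapply(chv, function(sl) {
    list(roles = vapply(sl$roles, as.character, ""),
         polygons = lapply(sl$polygons, function(p)
           do.call(rbind, lapply(p, function(r) as.numeric(unlist(r))))))
  }))
}
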