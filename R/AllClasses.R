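#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib cardiomorph, .registration = TRUE
NULL

## Shared conventions
## - voxel arrays are [y, x, z] (rows, columns, slices), matching how
##   multi-page TIFFs are read slice by slice
## - spacing is the named triple c(dz, dy, dx) in micrometres
## - origin is the physical (x, y, z) position of voxel (1, 1, 1) in
##   micrometres; all meshes, centrelines and point sets live in physical
##   (x, y, z) micrometre coordinates, never in voxel indices

.checkSpacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)))
    return("spacing must be a finite numeric triple (dz, dy, dx)")
  if (any(spacing <= 0)) return("all spacing components must be > 0")
  NULL
}

.checkOrigin <- function(origin) {
  if (length(origin) != 3L || !is.numeric(origin) || any(!is.finite(origin)))
    return("origin must be a finite numeric triple (x, y, z)")
  NULL
}

.namedSpacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  names(spacing) <- c("dz", "dy", "dx")
  spacing
}

.namedOrigin <- function(origin) {
  origin <- as.numeric(origin)
  names(origin) <- c("x", "y", "z")
  origin
}

# ---------------------------------------------------------------------------

#' IntensityStack: a multi-channel 3D fluorescence image
#'
#' Holds one 3D array of non-negative intensities per channel, all of
#' identical dimension, together with the anisotropic voxel spacing and the
#' physical origin. Arrays are indexed `[y, x, z]`; the physical position of
#' voxel `(j, i, k)` (1-based) is
#' `origin + ((i-1)*dx, (j-1)*dy, (k-1)*dz)` in micrometres.
#'
#' @slot voxels named list of 3D numeric/integer arrays, one per channel.
#' @slot spacing named numeric triple `(dz, dy, dx)` in micrometres.
#' @slot channelNames character vector of layer labels.
#' @slot origin named numeric triple `(x, y, z)`, micrometres.
#' @exportClass IntensityStack
setClass("IntensityStack",
  representation(voxels = "list", spacing = "numeric",
                 channelNames = "character", origin = "numeric"),
  validity = function(object) {
    msg <- character(0)
    msg <- c(msg, .checkSpacing(object@spacing), .checkOrigin(object@origin))
    if (length(object@voxels) != length(object@channelNames))
      msg <- c(msg, "one voxel array per channel name is required")
    dims <- lapply(object@voxels, dim)
    if (length(dims) > 0) {
      if (any(vapply(dims, length, 1L) != 3L))
        msg <- c(msg, "channel arrays must be 3D [y, x, z]")
      else if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
        msg <- c(msg, "channel arrays must share an identical shape")
      neg <- vapply(object@voxels, function(a) any(a < 0, na.rm = TRUE), TRUE)
      if (any(neg)) msg <- c(msg, "intensities must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an IntensityStack
#'
#' @param voxels a single 3D array or a list of 3D arrays (`[y, x, z]`), one
#'   per channel.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param channelNames labels for the channels; defaults to `"ch1"`, ...
#' @param origin physical position `(x, y, z)` of voxel (1,1,1), micrometres.
#' @return an [IntensityStack-class] object.
#' @export
IntensityStack <- function(voxels, spacing, channelNames = NULL,
                           origin = c(0, 0, 0)) {
  if (is.array(voxels) && length(dim(voxels)) == 3L) voxels <- list(voxels)
  if (is.null(channelNames))
    channelNames <- if (!is.null(names(voxels)) && all(nzchar(names(voxels))))
      names(voxels) else paste0("ch", seq_along(voxels))
  names(voxels) <- channelNames
  new("IntensityStack", voxels = voxels, spacing = .namedSpacing(spacing),
      channelNames = as.character(channelNames), origin = .namedOrigin(origin))
}

# ---------------------------------------------------------------------------

#' VoxelMask: a binary 3D compartment mask
#'
#' @slot voxels logical 3D array `[y, x, z]`.
#' @slot spacing named `(dz, dy, dx)` micrometre triple of the source stack.
#' @slot origin named `(x, y, z)` micrometre triple of the source stack.
#' @slot label compartment name (e.g. `"tissue"`, `"lumen"`, `"ECM"`).
#' @slot meta free-form diagnostics list (e.g. leak counts).
#' @exportClass VoxelMask
setClass("VoxelMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 label = "character", meta = "list"),
  validity = function(object) {
    msg <- c(.checkSpacing(object@spacing), .checkOrigin(object@origin))
    if (!is.logical(object@voxels) || length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a logical 3D array")
    if (length(msg)) msg else TRUE
  })

#' @param voxels logical 3D array `[y, x, z]`.
#' @param spacing,origin grid geometry, micrometres.
#' @param label compartment name.
#' @param meta optional diagnostics list.
#' @rdname VoxelMask-class
#' @export
VoxelMask <- function(voxels, spacing, origin = c(0, 0, 0), label = "mask",
                      meta = list()) {
  storage.mode(voxels) <- "logical"
  new("VoxelMask", voxels = voxels, spacing = .namedSpacing(spacing),
      origin = .namedOrigin(origin), label = label, meta = meta)
}

# ---------------------------------------------------------------------------

#' SliceContours: classified closed contours of one z-slice
#'
#' Polygons are closed (first vertex repeated last) simple loops in
#' continuous voxel `(y, x)` coordinates; `roles` classifies each as
#' `"external"` (even containment depth) or `"internal"` (odd depth).
#'
#' @slot sliceIndex 1-based z index.
#' @slot polygons list of closed n x 2 matrices, columns `(y, x)`.
#' @slot roles parallel character vector, `"external"` or `"internal"`.
#' @slot depth parallel integer containment depth (0 = outermost).
#' @slot provenance `"auto"` or `"manual"`.
#' @exportClass SliceContours
setClass("SliceContours",
  representation(sliceIndex = "integer", polygons = "list",
                 roles = "character", depth = "integer",
                 provenance = "character"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@polygons)
    if (length(object@roles) != n || length(object@depth) != n)
      msg <- c(msg, "roles and depth must parallel polygons")
    if (n && !all(object@roles %in% c("external", "internal")))
      msg <- c(msg, "roles must be 'external' or 'internal'")
    closed <- vapply(object@polygons, function(p)
      nrow(p) >= 4 && isTRUE(all.equal(p[1, ], p[nrow(p), ])), TRUE)
    if (n && !all(closed))
      msg <- c(msg, "every polygon must be closed (first point = last point)")
    if (length(msg)) msg else TRUE
  })

#' SliceMasks: filled and tissue masks of one z-slice
#'
#' Invariants (enforced): `filledInternal` is a subset of `filledExternal`
#' and `tissue` equals their exclusive disjunction bit-exactly.
#'
#' @slot filledExternal,filledInternal,tissue logical matrices `[y, x]`.
#' @exportClass SliceMasks
setClass("SliceMasks",
  representation(filledExternal = "matrix", filledInternal = "matrix",
                 tissue = "matrix"),
  validity = function(object) {
    msg <- character(0)
    e <- object@filledExternal; i <- object@filledInternal; t <- object@tissue
    if (!identical(dim(e), dim(i)) || !identical(dim(e), dim(t)))
      msg <- c(msg, "mask shapes differ")
    else {
      if (any(i & !e)) msg <- c(msg, "filledInternal must lie inside filledExternal")
      if (!identical(as.vector(t), as.vector(xor(e, i))))
        msg <- c(msg, "tissue must equal filledExternal XOR filledInternal")
    }
    if (length(msg)) msg else TRUE
  })

#' ContourLibrary: per-slice, per-channel contours and derived masks
#'
#' The central segmentation product: for every channel, an ordered list of
#' [SliceContours-class] (one per z-slice) and the stacked filled
#' external / filled internal / tissue masks as 3D logical arrays.
#'
#' @slot contours named list (per channel) of lists of SliceContours.
#' @slot masks named list (per channel) of lists with elements
#'   `filled_external`, `filled_internal`, `tissue` (3D logical arrays).
#' @slot spacing,origin grid geometry of the source stack.
#' @slot channelNames channels present.
#' @exportClass ContourLibrary
setClass("ContourLibrary",
  representation(contours = "list", masks = "list", spacing = "numeric",
                 origin = "numeric", channelNames = "character"),
  validity = function(object) {
    msg <- c(.checkSpacing(object@spacing), .checkOrigin(object@origin))
    for (ch in object@channelNames) {
      mk <- object@masks[[ch]]
      if (is.null(mk) || !all(c("filled_external", "filled_internal",
                                "tissue") %in% names(mk))) {
        msg <- c(msg, sprintf("channel '%s' lacks mask arrays", ch))
        next
      }
      nz <- dim(mk$tissue)[3]
      if (length(object@contours[[ch]]) != nz)
        msg <- c(msg, sprintf("channel '%s': slice count mismatch", ch))
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------

#' SurfaceMesh: a triangulated surface in physical coordinates
#'
#' @slot vertices numeric n x 3 matrix of `(x, y, z)` micrometre positions.
#' @slot faces integer m x 3 matrix of 1-based vertex indices.
#' @slot scalar optional per-vertex scalar field (length 0 or n).
#' @slot scalarName,scalarUnits name/units of the scalar field.
#' @exportClass SurfaceMesh
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix", scalar = "numeric",
                 scalarName = "character", scalarUnits = "character"),
  validity = function(object) {
    msg <- character(0)
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
    if (nrow(object@faces) > 0) {
      rng <- range(object@faces)
      if (rng[1] < 1L || rng[2] > nrow(object@vertices))
        msg <- c(msg, "face indices out of range")
    }
    ns <- length(object@scalar)
    if (ns != 0L && ns != nrow(object@vertices))
      msg <- c(msg, "scalar must have one value per vertex (or none)")
    if (length(msg)) msg else TRUE
  })

#' @param vertices n x 3 `(x, y, z)` micrometre matrix.
#' @param faces m x 3 integer matrix, 1-based.
#' @param scalar optional per-vertex values.
#' @param scalarName,scalarUnits metadata for `scalar`.
#' @rdname SurfaceMesh-class
#' @export
SurfaceMesh <- function(vertices, faces, scalar = numeric(0),
                        scalarName = NA_character_,
                        scalarUnits = NA_character_) {
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices), faces = faces,
      scalar = as.numeric(scalar), scalarName = scalarName,
      scalarUnits = scalarUnits)
}

# ---------------------------------------------------------------------------

#' Centreline: ordered lumen midline between two pole anchors
#'
#' @slot points ordered K x 3 micrometre matrix from pole A (venous) to
#'   pole B (arterial).
#' @slot arclength cumulative arclength per point, `arclength[1] == 0`.
#' @slot inscribedRadius per-point clearance to the lumen wall, micrometres.
#' @slot anchors 2 x 3 matrix, rows `poleA`, `poleB`.
#' @exportClass Centreline
setClass("Centreline",
  representation(points = "matrix", arclength = "numeric",
                 inscribedRadius = "numeric", anchors = "matrix"),
  validity = function(object) {
    msg <- character(0)
    k <- nrow(object@points)
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be K x 3")
    if (length(object@arclength) != k)
      msg <- c(msg, "arclength must parallel points")
    else if (k > 1 && (object@arclength[1] != 0 ||
                       any(diff(object@arclength) <= 0)))
      msg <- c(msg, "arclength must start at 0 and be strictly increasing")
    if (length(object@inscribedRadius) != k)
      msg <- c(msg, "inscribedRadius must parallel points")
    if (!identical(dim(object@anchors), c(2L, 3L)))
      msg <- c(msg, "anchors must be a 2 x 3 matrix")
    if (length(msg)) msg else TRUE
  })

#' @param points,arclength,inscribedRadius,anchors see the class slots.
#' @rdname Centreline-class
#' @export
Centreline <- function(points, arclength, inscribedRadius, anchors) {
  rownames(anchors) <- c("poleA", "poleB")
  new("Centreline", points = as.matrix(points),
      arclength = as.numeric(arclength),
      inscribedRadius = as.numeric(inscribedRadius),
      anchors = as.matrix(anchors))
}

# ---------------------------------------------------------------------------

#' CutDisc: a finite cutting disc separating two chambers
#'
#' @slot centre disc centre `(x, y, z)`, micrometres.
#' @slot normal unit normal vector.
#' @slot radius disc radius, micrometres.
#' @exportClass CutDisc
setClass("CutDisc",
  representation(centre = "numeric", normal = "numeric", radius = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@centre) != 3L) msg <- c(msg, "centre must be length 3")
    if (length(object@normal) != 3L ||
        abs(sqrt(sum(object@normal^2)) - 1) > 1e-6)
      msg <- c(msg, "normal must be a unit 3-vector")
    if (length(object@radius) != 1L || object@radius <= 0)
      msg <- c(msg, "radius must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' @param centre disc centre `(x, y, z)` in micrometres.
#' @param normal normal vector (normalized on construction).
#' @param radius disc radius in micrometres.
#' @rdname CutDisc-class
#' @export
CutDisc <- function(centre, normal, radius) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("disc normal must be non-zero")
  new("CutDisc", centre = as.numeric(centre), normal = n / nn,
      radius = as.numeric(radius))
}

#' ChamberPartition: atrium/ventricle assignment of a mask or mesh
#'
#' `labels` uses 0 = background, 1 = atrium, 2 = ventricle. For `kind ==
#' "mask"` it is a 3D integer array on the source grid; for `kind == "mesh"`
#' a per-face integer vector with the mesh kept alongside.
#'
#' @slot kind `"mask"` or `"mesh"`.
#' @slot labels integer array (mask) or vector (mesh faces).
#' @slot disc the [CutDisc-class] used.
#' @slot cutArea approximate cut cross-section area, square micrometres.
#' @slot spacing,origin grid geometry (mask kind).
#' @slot mesh the partitioned [SurfaceMesh-class] (mesh kind) or `NULL`.
#' @exportClass ChamberPartition
setClass("ChamberPartition",
  representation(kind = "character", labels = "ANY", disc = "CutDisc",
                 cutArea = "numeric", spacing = "numeric", origin = "numeric",
                 mesh = "ANY"))

# ---------------------------------------------------------------------------

#' EllipsoidFit: bounding ellipsoid of a chamber mesh
#'
#' @slot centre ellipsoid centre `(x, y, z)`, micrometres.
#' @slot semiAxes named semi-axis lengths `(width, length, depth)`,
#'   micrometres, along the scene triad.
#' @slot asphericity dimensionless deviation from a sphere (0 for a sphere).
#' @slot triad 3 x 3 matrix whose rows are the width/length/depth axes.
#' @exportClass EllipsoidFit
setClass("EllipsoidFit",
  representation(centre = "numeric", semiAxes = "numeric",
                 asphericity = "numeric", triad = "matrix"),
  validity = function(object) {
    if (any(object@semiAxes <= 0)) "semi-axes must be positive" else TRUE
  })

# ---------------------------------------------------------------------------

#' Heatmap2D: an unrolled (arclength x angle) scalar matrix
#'
#' Rows follow arclength along the (extended) centreline from the venous to
#' the arterial end; columns are circumferential angle bins whose centres
#' cover \[-180, 180) degrees uniformly, with 0 degrees ventral and +/-180
#' degrees dorsal. Missing cells are `NA` and are never imputed.
#'
#' @slot values P x Q numeric matrix (`NA` = missing).
#' @slot arcCenters arclength bin centres, micrometres.
#' @slot angleCenters angle bin centres, degrees in \[-180, 180).
#' @slot count per-cell contributor count (averaged maps) or `NULL`.
#' @slot sd per-cell sample standard deviation (averaged maps) or `NULL`.
#' @slot scalarName,scalarUnits what the cells hold.
#' @slot regionLabels optional named list of arclength bands
#'   (e.g. `list(AOC = c(0, 120))`).
#' @exportClass Heatmap2D
setClass("Heatmap2D",
  representation(values = "matrix", arcCenters = "numeric",
                 angleCenters = "numeric", count = "ANY", sd = "ANY",
                 scalarName = "character", scalarUnits = "character",
                 regionLabels = "list"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@values) != length(object@arcCenters))
      msg <- c(msg, "one arclength centre per row required")
    if (ncol(object@values) != length(object@angleCenters))
      msg <- c(msg, "one angle centre per column required")
    q <- length(object@angleCenters)
    if (q > 1) {
      step <- 360 / q
      expect <- -180 + (seq_len(q) - 0.5) * step
      if (max(abs(object@angleCenters - expect)) > 1e-6)
        msg <- c(msg, "angle bin centres must uniformly cover [-180, 180)")
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------

#' NucleiSet: 3D nuclei centroids with chamber/region labels
#'
#' @slot points N x 3 micrometre coordinates.
#' @slot chamber per-nucleus `"atrium"`, `"ventricle"` or `"unassigned"`.
#' @slot region per-nucleus `"ventral"`, `"dorsal"`, `"outer"`, `"inner"` or
#'   `"unassigned"`.
#' @slot ind per-nucleus mean internuclear distance (`NA` until computed).
#' @exportClass NucleiSet
setClass("NucleiSet",
  representation(points = "matrix", chamber = "character",
                 region = "character", ind = "numeric"),
  validity = function(object) {
    msg <- character(0)
    n <- nrow(object@points)
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be N x 3")
    if (any(!is.finite(object@points))) msg <- c(msg, "coordinates must be finite")
    if (length(object@chamber) != n || length(object@region) != n ||
        length(object@ind) != n)
      msg <- c(msg, "labels must parallel points")
    if (n && !all(object@chamber %in% c("atrium", "ventricle", "unassigned")))
      msg <- c(msg, "invalid chamber label")
    if (n && !all(object@region %in% c("ventral", "dorsal", "outer", "inner",
                                       "unassigned")))
      msg <- c(msg, "invalid region label")
    if (length(msg)) msg else TRUE
  })

#' @param points,chamber,region,ind see the class slots (labels default to
#'   unassigned).
#' @rdname NucleiSet-class
#' @export
NucleiSet <- function(points, chamber = NULL, region = NULL, ind = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  colnames(points) <- c("x", "y", "z")
  new("NucleiSet", points = points,
      chamber = if (is.null(chamber)) rep("unassigned", n) else chamber,
      region = if (is.null(region)) rep("unassigned", n) else region,
      ind = if (is.null(ind)) rep(NA_real_, n) else ind)
}
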