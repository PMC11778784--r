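## Generics shared across modules. Accessors are provided instead of direct
## slot access throughout.

#' Voxel spacing accessor
#'
#' @param x an object with a voxel grid (stack, mask, contour library).
#' @return named numeric triple `(dz, dy, dx)` in micrometres.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin accessor
#'
#' @param x an object with a voxel grid.
#' @return named numeric triple `(x, y, z)` in micrometres.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Channel names accessor
#'
#' @param x a stack or contour library.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Mesh vertices accessor
#' @param x a [SurfaceMesh-class].
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Mesh faces accessor
#' @param x a [SurfaceMesh-class].
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Per-vertex scalar accessor
#' @param x a [SurfaceMesh-class].
#' @export
setGeneric("meshScalar", function(x) standardGeneric("meshScalar"))

#' Heatmap values accessor
#' @param x a [Heatmap2D-class].
#' @export
setGeneric("heatmapValues", function(x) standardGeneric("heatmapValues"))

#' Nuclei coordinates accessor
#' @param x a [NucleiSet-class].
#' @export
setGeneric("nucleiPoints", function(x) standardGeneric("nucleiPoints"))

#' @rdname spacing
#' @export
setMethod("spacing", "IntensityStack", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "VoxelMask", function(x) x@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "ContourLibrary", function(x) x@spacing)

#' @rdname origin
#' @export
setMethod("origin", "IntensityStack", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "VoxelMask", function(x) x@origin)
#' @rdname origin
#' @export
setMethod("origin", "ContourLibrary", function(x) x@origin)

#' @rdname channelNames
#' @export
setMethod("channelNames", "IntensityStack", function(x) x@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "ContourLibrary", function(x) x@channelNames)

#' @rdname vertices
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname faces
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @rdname meshScalar
#' @export
setMethod("meshScalar", "SurfaceMesh", function(x) x@scalar)

#' @rdname heatmapValues
#' @export
setMethod("heatmapValues", "Heatmap2D", function(x) x@values)

#' @rdname nucleiPoints
#' @export
setMethod("nucleiPoints", "NucleiSet", function(x) x@points)

#' Extract one channel array from a stack
#'
#' @param stack an [IntensityStack-class].
#' @param channel channel name or index.
#' @return the 3D intensity array `[y, x, z]`.
#' @export
getChannel <- function(stack, channel) {
  stopifnot(is(stack, "IntensityStack"))
  a <- stack@voxels[[channel]]
  if (is.null(a)) stop("unknown channel: ", channel)
  a
}

#' Mask voxel array accessor
#'
#' @param mask a [VoxelMask-class].
#' @return logical 3D array.
#' @export
maskVoxels <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  mask@voxels
}

#' Centreline point/metric accessors
#'
#' @param cl a [Centreline-class].
#' @return `clPoints`: the ordered K x 3 point matrix; `clArclength`: the
#'   cumulative arclength; `clRadius`: per-point inscribed radius;
#'   `clAnchors`: the 2 x 3 pole anchor matrix.
#' @name centreline-accessors
NULL

#' @rdname centreline-accessors
#' @export
clPoints <- function(cl) { stopifnot(is(cl, "Centreline")); cl@points }
#' @rdname centreline-accessors
#' @export
clArclength <- function(cl) { stopifnot(is(cl, "Centreline")); cl@arclength }
#' @rdname centreline-accessors
#' @export
clRadius <- function(cl) { stopifnot(is(cl, "Centreline")); cl@inscribedRadius }
#' @rdname centreline-accessors
#' @export
clAnchors <- function(cl) { stopifnot(is(cl, "Centreline")); cl@anchors }

# ------------------------------------------------------------- show methods

setMethod("show", "IntensityStack", function(object) {
  d <- dim(object@voxels[[1]])
  cat(sprintf("IntensityStack: %d channel(s) [%s], %d x %d x %d (y,x,z)\n",
              length(object@channelNames),
              paste(object@channelNames, collapse = ", "), d[1], d[2], d[3]))
  cat(sprintf("  spacing (dz,dy,dx): %.4g, %.4g, %.4g um; origin (%.4g, %.4g, %.4g) um\n",
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelMask '%s': %d x %d x %d, %d foreground voxels (%.4g um^3)\n",
              object@label, d[1], d[2], d[3], sum(object@voxels),
              sum(object@voxels) * prod(object@spacing)))
})

setMethod("show", "ContourLibrary", function(object) {
  cat(sprintf("ContourLibrary: channels [%s], %d slices\n",
              paste(object@channelNames, collapse = ", "),
              length(object@contours[[1]])))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (length(object@scalar))
                sprintf(", scalar '%s' [%s]", object@scalarName,
                        object@scalarUnits) else ""))
})

setMethod("show", "Centreline", function(object) {
  cat(sprintf("Centreline: %d points, length %.4g um\n",
              nrow(object@points), max(object@arclength)))
})

setMethod("show", "CutDisc", function(object) {
  cat(sprintf("CutDisc: centre (%.4g, %.4g, %.4g), normal (%.3f, %.3f, %.3f), radius %.4g um\n",
              object@centre[1], object@centre[2], object@centre[3],
              object@normal[1], object@normal[2], object@normal[3],
              object@radius))
})

setMethod("show", "EllipsoidFit", function(object) {
  cat(sprintf("EllipsoidFit: semi-axes (w,l,d) = (%.4g, %.4g, %.4g) um, asphericity %.4f\n",
              object@semiAxes[1], object@semiAxes[2], object@semiAxes[3],
              object@asphericity))
})

setMethod("show", "Heatmap2D", function(object) {
  cat(sprintf("Heatmap2D '%s' [%s]: %d arclength x %d angle bins, %d missing cells\n",
              object@scalarName, object@scalarUnits, nrow(object@values),
              ncol(object@values), sum(is.na(object@values))))
})

setMethod("show", "NucleiSet", function(object) {
  cat(sprintf("NucleiSet: %d nuclei (%d atrial, %d ventricular, %d unassigned)\n",
              nrow(object@points), sum(object@chamber == "atrium"),
              sum(object@chamber == "ventricle"),
              sum(object@chamber == "unassigned")))
})

setMethod("show", "ChamberPartition", function(object) {
  n1 <- sum(object@labels == 1L); n2 <- sum(object@labels == 2L)
  cat(sprintf("ChamberPartition (%s): %d atrium / %d ventricle elements, cut area %.4g um^2\n",
              object@kind, n1, n2, object@cutArea))
})
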