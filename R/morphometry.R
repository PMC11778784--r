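## morphometry: bounding-ellipsoid chamber geometry, ballooning
## (centreline-to-surface) and wall-thickness (surface-to-surface) vertex
## fields.

#' Fit the bounding ellipsoid of a chamber mesh
#'
#' The chamber is projected onto the three scene axes and its largest
#' dimensions define an axis-aligned bounding ellipsoid: semi-axes are half
#' the vertex extents along the triad (width = left-right, length =
#' pole-apex, depth = dorso-ventral), the centre is the extent midpoint.
#' Asphericity quantifies the deviation of the ellipsoid from a sphere as
#' `sqrt(sum((s_i - mean(s))^2)) / mean(s)` over the semi-axes `s`; it is 0
#' exactly when all semi-axes are equal.
#'
#' @param mesh a non-degenerate [SurfaceMesh-class].
#' @param triad 3 x 3 matrix whose rows are the unit width / length / depth
#'   axes of the scene (default: image axes x, y, z).
#' @return an [EllipsoidFit-class].
#' @export
fitEllipsoid <- function(mesh, triad = diag(3)) {
  stopifnot(is(mesh, "SurfaceMesh"))
  triad <- as.matrix(triad)
  triad <- t(apply(triad, 1, .normalize))
  proj <- mesh@vertices %*% t(triad)          # n x 3 coordinates in triad
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  semi <- (hi - lo) / 2
  if (any(semi <= 0)) stop("flat mesh: zero extent along a triad axis")
  names(semi) <- c("width", "length", "depth")
  centreTriad <- (hi + lo) / 2
  centre <- as.numeric(centreTriad %*% triad)  # back to world coordinates
  sbar <- mean(semi)
  new("EllipsoidFit", centre = centre, semiAxes = semi,
      asphericity = sqrt(sum((semi - sbar)^2)) / sbar, triad = triad)
}

#' Ellipsoid accessors
#'
#' @param fit an [EllipsoidFit-class].
#' @name ellipsoid-accessors
NULL

#' @rdname ellipsoid-accessors
#' @export
semiAxes <- function(fit) { stopifnot(is(fit, "EllipsoidFit")); fit@semiAxes }
#' @rdname ellipsoid-accessors
#' @export
asphericity <- function(fit) { stopifnot(is(fit, "EllipsoidFit")); fit@asphericity }
#' @rdname ellipsoid-accessors
#' @export
ellipsoidCentre <- function(fit) { stopifnot(is(fit, "EllipsoidFit")); fit@centre }

#' Ballooning map: centreline-to-surface distance per vertex
#'
#' The scalar at each mesh vertex is its minimum Euclidean distance to the
#' centreline polyline (segment-wise, not point-wise), a readout of
#' regional chamber expansion.
#'
#' @param mesh the carrier [SurfaceMesh-class] (internal or external
#'   tissue mesh; the external is the conventional default carrier).
#' @param cl a [Centreline-class].
#' @return the mesh with per-vertex scalar `"ballooning"` (micrometres).
#' @export
ballooningMap <- function(mesh, cl) {
  stopifnot(is(mesh, "SurfaceMesh"), is(cl, "Centreline"))
  if (nrow(mesh@vertices) == 0) stop("empty mesh")
  if (nrow(cl@points) < 2) stop("degenerate centreline")
  d <- .cpp_points_to_polyline(mesh@vertices, cl@points)
  setMeshScalar(mesh, d, "ballooning", "um")
}

#' Thickness map: surface-to-surface distance per vertex
#'
#' The scalar at each vertex of the carrier mesh is its distance to the
#' closest point on the other mesh's triangles (point-to-triangle, not
#' point-to-vertex). Applied to the inner/outer meshes of one tissue this
#' gives wall thickness; applied to the outer inner-layer mesh and the
#' inner outer-layer mesh it gives ECM thickness.
#'
#' @param inner,outer nested [SurfaceMesh-class] surfaces.
#' @param carrier `"outer"` or `"inner"`: which mesh carries the scalar.
#' @return the carrier mesh with per-vertex scalar `"thickness"`
#'   (micrometres).
#' @export
thicknessMap <- function(inner, outer, carrier = c("outer", "inner")) {
  stopifnot(is(inner, "SurfaceMesh"), is(outer, "SurfaceMesh"))
  carrier <- match.arg(carrier)
  if (nrow(inner@vertices) == 0 || nrow(outer@vertices) == 0)
    stop("empty mesh")
  from <- if (carrier == "outer") outer else inner
  to <- if (carrier == "outer") inner else outer
  d <- .cpp_points_to_mesh(from@vertices, to@vertices, to@faces)
  setMeshScalar(from, d, "thickness", "um")
}

#' Export per-vertex scalars as CSV
#'
#' @param mesh a [SurfaceMesh-class] with a scalar field.
#' @param path output CSV (columns vertex, x, y, z, value).
#' @export
writeScalarCsv <- function(mesh, path) {
  stopifnot(is(mesh, "SurfaceMesh"), length(mesh@scalar) > 0)
  df <- data.frame(vertex = seq_len(nrow(mesh@vertices)),
                   x = mesh@vertices[, 1], y = mesh@vertices[, 2],
                   z = mesh@vertices[, 3], value = mesh@scalar)
  names(df)[5] <- paste0(mesh@scalarName, "_", mesh@scalarUnits)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
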