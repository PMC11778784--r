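## partition: chamber separation by a user-defined cutting disc, left/right
## splitting about the centreline, and chamber orientation angles.

#' Split a mask or mesh into two chambers with a cutting disc
#'
#' Elements are classified by the sign of `(p - centre) . normal`; the side
#' selected by `atrialSide` becomes the atrium, the other the ventricle.
#' Points exactly on the disc plane are assigned to the ventricle
#' (documented tie-break). The finite disc must cover the cut: foreground
#' within half a slab of the plane but radially outside the disc raises an
#' error reporting the measured overhang. Each resulting side must be
#' non-empty and connected.
#'
#' @param target a [VoxelMask-class] or [SurfaceMesh-class].
#' @param disc a [CutDisc-class] (e.g. through the atrioventricular canal).
#' @param atrialSide `"positive"` or `"negative"`: which side of the plane
#'   (sign of the projection onto the normal) is the atrium.
#' @return a [ChamberPartition-class]; `cutArea` estimates the cut
#'   cross-section area in square micrometres.
#' @export
splitByDisc <- function(target, disc, atrialSide = c("positive", "negative")) {
  stopifnot(is(disc, "CutDisc"))
  atrialSide <- match.arg(atrialSide)
  sgnA <- if (atrialSide == "positive") 1 else -1
  if (is(target, "VoxelMask")) {
    arr <- target@voxels
    d <- dim(arr)
    idx <- which(arr, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("empty target mask")
    P <- .voxelToPhys(idx[, 1], idx[, 2], idx[, 3], target@spacing,
                      target@origin)
    s <- (P[, 1] - disc@centre[1]) * disc@normal[1] +
         (P[, 2] - disc@centre[2]) * disc@normal[2] +
         (P[, 3] - disc@centre[3]) * disc@normal[3]
    if (all(s > 0) || all(s < 0))
      stop("disc plane misses the target")
    slab <- max(target@spacing)
    near <- abs(s) <= slab / 2
    if (any(near)) {
      Pn <- P[near, , drop = FALSE]
      rel <- sweep(Pn, 2, disc@centre)
      rad2 <- rowSums(rel^2) - (s[near])^2
      over <- sqrt(pmax(rad2, 0)) - disc@radius
      if (any(over > 0))
        stop(sprintf("disc radius too small for the cut cross-section (overhang %.3g um)",
                     max(over)))
      cutArea <- sum(near) * prod(target@spacing) / slab
    } else cutArea <- 0
    labs <- ifelse(sgnA * s > 0, 1L, 2L)    # on-plane (s == 0) -> ventricle
    if (!any(labs == 1L) || !any(labs == 2L))
      stop("one side of the disc is empty")
    labArr <- array(0L, d)
    labArr[idx] <- labs
    for (side in 1:2) {
      m <- labArr == side
      cc <- array(.cpp_label3d(as.logical(m), d), d)
      if (max(cc) > 1L) {
        # keep it informative but tolerant: disconnected fragments usually
        # mean the disc grazes a curved wall; warn with fragment sizes
        sizes <- sort(tabulate(cc[cc > 0L]), decreasing = TRUE)
        if (sizes[2] > 0.01 * sizes[1])
          warning(sprintf("chamber %d splits into %d components", side,
                          max(cc)))
      }
    }
    new("ChamberPartition", kind = "mask", labels = labArr, disc = disc,
        cutArea = cutArea, spacing = target@spacing, origin = target@origin,
        mesh = NULL)
  } else if (is(target, "SurfaceMesh")) {
    V <- target@vertices
    F <- target@faces
    cen <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
            V[F[, 3], , drop = FALSE]) / 3
    s <- sweep(cen, 2, disc@centre) %*% disc@normal
    if (all(s > 0) || all(s < 0)) stop("disc plane misses the mesh")
    labs <- ifelse(sgnA * s > 0, 1L, 2L)
    new("ChamberPartition", kind = "mesh", labels = as.integer(labs),
        disc = disc, cutArea = NA_real_,
        spacing = c(dz = NA_real_, dy = NA_real_, dx = NA_real_),
        origin = c(x = NA_real_, y = NA_real_, z = NA_real_), mesh = target)
  } else stop("target must be a VoxelMask or SurfaceMesh")
}

#' Chamber voxel mask from a partition
#'
#' @param partition a mask-kind [ChamberPartition-class].
#' @param chamber `"atrium"` or `"ventricle"`.
#' @return a [VoxelMask-class].
#' @export
partitionMask <- function(partition, chamber = c("atrium", "ventricle")) {
  stopifnot(is(partition, "ChamberPartition"), partition@kind == "mask")
  chamber <- match.arg(chamber)
  code <- if (chamber == "atrium") 1L else 2L
  VoxelMask(partition@labels == code, spacing = partition@spacing,
            origin = partition@origin, label = chamber)
}

#' Split a chamber into left and right about the centreline
#'
#' For every foreground voxel the nearest centreline point defines the
#' local tangent `t`; with dorsal reference `d`, the voxel is `"left"` when
#' the triple product `(p - c) . (t x d)` is positive and `"right"`
#' otherwise (voxels exactly on the tangent-dorsal plane go right,
#' documented tie-break). Negating `d` swaps the labels.
#'
#' @param chamber a [VoxelMask-class].
#' @param cl a [Centreline-class] traversing the chamber.
#' @param dorsalRef unit vector pointing dorsally.
#' @return integer array on the chamber grid: 0 background, 1 left,
#'   2 right.
#' @export
splitLeftRight <- function(chamber, cl, dorsalRef) {
  stopifnot(is(chamber, "VoxelMask"), is(cl, "Centreline"))
  dorsalRef <- .normalize(as.numeric(dorsalRef))
  arr <- chamber@voxels
  idx <- which(arr, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty chamber mask")
  P <- .voxelToPhys(idx[, 1], idx[, 2], idx[, 3], chamber@spacing,
                    chamber@origin)
  C <- cl@points
  nn <- FNN::get.knnx(C, P, k = 1)
  ni <- nn$nn.index[, 1]
  if (min(nn$nn.dist) > 2 * max(cl@inscribedRadius) + 2 * max(chamber@spacing))
    stop("centreline does not traverse the chamber")
  tang <- .polylineTangents(C)
  lvec <- cbind(tang[ni, 2] * dorsalRef[3] - tang[ni, 3] * dorsalRef[2],
                tang[ni, 3] * dorsalRef[1] - tang[ni, 1] * dorsalRef[3],
                tang[ni, 1] * dorsalRef[2] - tang[ni, 2] * dorsalRef[1])
  rel <- P - C[ni, , drop = FALSE]
  s <- rowSums(rel * lvec)
  labs <- ifelse(s > 0, 1L, 2L)
  if (!any(labs == 1L) || !any(labs == 2L))
    warning("one of the left/right sides is empty")
  out <- array(0L, dim(arr))
  out[idx] <- labs
  out
}

# unit tangents of a polyline by central differences
.polylineTangents <- function(P) {
  n <- nrow(P)
  if (n < 2) stop("degenerate polyline")
  d <- rbind(P[2, ] - P[1, ],
             P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE],
             P[n, ] - P[n - 1, ])
  d / sqrt(rowSums(d^2))
}

# signed 2D angle (degrees, (-180, 180]) from a to b
.signedAngle2 <- function(a, b) {
  ang <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Chamber orientation angles relative to a reference vector
#'
#' Each chamber's axis runs from its pole (the disc centre) to its apex
#' (the chamber point farthest from the disc centre). Axes and the
#' reference vector are projected onto the view plane — ventral view: the
#' plane perpendicular to the imaging z axis; lateral view: perpendicular
#' to the left-right x axis — and the signed angle from the projected
#' reference to the projected axis is reported in (-180, 180] degrees,
#' positive counter-clockwise in the view. The inter-chamber angle is the
#' absolute difference folded to [0, 180].
#'
#' @param partition a mask-kind [ChamberPartition-class].
#' @param refVector reference vector, physical coordinates.
#' @param view `"ventral"` or `"lateral"`.
#' @return list with `atrium`, `ventricle` (degrees) and `between`.
#' @export
chamberAngles <- function(partition, refVector,
                          view = c("ventral", "lateral")) {
  stopifnot(is(partition, "ChamberPartition"), partition@kind == "mask")
  view <- match.arg(view)
  proj <- if (view == "ventral") c(1L, 2L) else c(2L, 3L)   # (x,y) | (y,z)
  ref2 <- .normalize(as.numeric(refVector)[proj])
  pole <- partition@disc@centre
  ang <- c(atrium = NA_real_, ventricle = NA_real_)
  for (side in 1:2) {
    idx <- which(partition@labels == side, arr.ind = TRUE)
    P <- .voxelToPhys(idx[, 1], idx[, 2], idx[, 3], partition@spacing,
                      partition@origin)
    d2 <- rowSums(sweep(P, 2, pole)^2)
    apex <- P[which.max(d2), ]
    axis <- apex - pole
    if (sqrt(sum(axis^2)) == 0) stop("chamber apex coincides with its pole")
    ang[side] <- .signedAngle2(ref2, axis[proj])
  }
  between <- abs(ang[1] - ang[2])
  if (between > 180) between <- 360 - between
  list(atrium = unname(ang[1]), ventricle = unname(ang[2]),
       between = unname(between))
}
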