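## internal geometry/plumbing helpers

# physical (x,y,z) of voxel (j=row, i=col, k=slice), 1-based
.voxelToPhys <- function(j, i, k, spacing, origin) {
  cbind(x = origin[["x"]] + (i - 1) * spacing[["dx"]],
        y = origin[["y"]] + (j - 1) * spacing[["dy"]],
        z = origin[["z"]] + (k - 1) * spacing[["dz"]])
}

# nearest voxel (j,i,k) of a physical point; no bounds clipping
.physToVoxel <- function(p, spacing, origin) {
  c(j = round((p[2] - origin[["y"]]) / spacing[["dy"]]) + 1,
    i = round((p[1] - origin[["x"]]) / spacing[["dx"]]) + 1,
    k = round((p[3] - origin[["z"]]) / spacing[["dz"]]) + 1)
}

# (x,y,z) coordinates of all TRUE voxels of a logical array
.foregroundPhys <- function(arr, spacing, origin) {
  idx <- which(arr, arr.ind = TRUE)
  .voxelToPhys(idx[, 1], idx[, 2], idx[, 3], spacing, origin)
}

# 0-based linear index (R array order [y,x,z]) of voxel (j,i,k), 1-based
.linearIndex0 <- function(j, i, k, dims) {
  (j - 1) + dims[1] * ((i - 1) + dims[2] * (k - 1))
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# run expr with a fixed RNG state, restoring the caller's state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.stopIfNot3D <- function(arr, what = "array") {
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop(what, " must be a 3D array")
}
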