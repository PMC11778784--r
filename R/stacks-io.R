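## stacks_io: reading, writing, cropping and light filtering of
## multi-channel z-stacks with physical voxel spacing.
##
## Downstream geometry is always computed in physical micrometre
## coordinates; voxel indices never leak past this module.

.sidecarPath <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF z-stack
#'
#' Reads a multi-page 8/16-bit TIFF into an [IntensityStack-class]. Two
#' channel layouts are supported: `"interleaved"` (channel fastest: pages
#' c1z1, c2z1, c1z2, ...) and `"stacked"` (all pages of channel 1, then
#' channel 2, ...). If `spacing` is `NULL` the sidecar JSON written by
#' [writeStack()] is consulted.
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param channelNames labels, one per channel; their number fixes the
#'   channel count (default: single channel).
#' @param layout page layout, `"interleaved"` (default) or `"stacked"`.
#' @param origin physical position of voxel (1,1,1); default from sidecar
#'   or `(0,0,0)`.
#' @return an [IntensityStack-class]; intensities keep the stored integer
#'   values (no rescaling).
#' @export
readStack <- function(path, spacing = NULL, channelNames = NULL,
                      layout = c("interleaved", "stacked"), origin = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- NULL
  if (file.exists(.sidecarPath(path)))
    side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  if (is.null(spacing)) spacing <- side$spacing
  if (is.null(spacing)) stop("spacing not given and no sidecar found")
  err <- .checkSpacing(spacing)
  if (!is.null(err)) stop(err)
  if (is.null(channelNames)) channelNames <- side$channel_names
  if (is.null(channelNames)) channelNames <- "ch1"
  if (is.null(origin)) origin <- if (!is.null(side$origin)) side$origin else c(0, 0, 0)
  layout <- if (!is.null(side$layout) && missing(layout)) side$layout
            else match.arg(layout)

  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channelNames)
  np <- length(pages)
  if (np %% nc != 0L)
    stop(sprintf("page count (%d) not divisible by channel count (%d)",
                 np, nc))
  nz <- np %/% nc
  voxels <- vector("list", nc)
  for (c in seq_len(nc)) {
    sel <- if (layout == "interleaved") seq(c, np, by = nc)
           else seq((c - 1) * nz + 1, c * nz)
    arr <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[sel[k]]]
    voxels[[c]] <- arr
  }
  IntensityStack(voxels, spacing = spacing, channelNames = channelNames,
                 origin = origin)
}

#' Write a stack as multi-page TIFF plus sidecar JSON
#'
#' Pages are written channel-interleaved (or stacked) at the requested bit
#' depth; spacing, origin, channel names and layout go into `<path>.json`.
#' The round trip through [readStack()] preserves integer voxel values
#' bit-exactly.
#'
#' @param stack an [IntensityStack-class].
#' @param path output TIFF path.
#' @param bits 8 or 16 bits per sample.
#' @param layout `"interleaved"` or `"stacked"`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, bits = 16L,
                       layout = c("interleaved", "stacked")) {
  stopifnot(is(stack, "IntensityStack"))
  layout <- match.arg(layout)
  maxval <- 2^bits - 1
  nz <- dim(stack@voxels[[1]])[3]
  nc <- length(stack@voxels)
  pages <- vector("list", nz * nc)
  for (c in seq_len(nc)) {
    arr <- stack@voxels[[c]]
    if (max(arr) > maxval)
      stop(sprintf("intensities exceed %d-bit range", bits))
    for (k in seq_len(nz)) {
      p <- if (layout == "interleaved") (k - 1) * nc + c else (c - 1) * nz + k
      pages[[p]] <- arr[, , k] / maxval
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  jsonlite::write_json(list(spacing = unname(stack@spacing),
                            origin = unname(stack@origin),
                            channel_names = stack@channelNames,
                            layout = layout, bits = bits),
                       .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Crop a stack to an axis-aligned voxel box
#'
#' The origin is shifted by the crop offset times the spacing, so physical
#' coordinates of retained voxels are unchanged.
#'
#' @param stack an [IntensityStack-class].
#' @param roi named list with integer ranges `z`, `y`, `x` (1-based,
#'   inclusive); omitted axes keep their full extent.
#' @return the cropped [IntensityStack-class].
#' @export
cropStack <- function(stack, roi) {
  stopifnot(is(stack, "IntensityStack"))
  d <- dim(stack@voxels[[1]])           # (ny, nx, nz)
  full <- list(y = c(1L, d[1]), x = c(1L, d[2]), z = c(1L, d[3]))
  for (ax in names(roi)) {
    if (!ax %in% names(full)) stop("unknown roi axis: ", ax)
    r <- as.integer(roi[[ax]])
    if (length(r) != 2L || r[1] > r[2]) stop("empty roi on axis ", ax)
    if (r[1] < full[[ax]][1] || r[2] > full[[ax]][2])
      stop("roi out of bounds on axis ", ax)
    full[[ax]] <- r
  }
  ys <- full$y[1]:full$y[2]; xs <- full$x[1]:full$x[2]; zs <- full$z[1]:full$z[2]
  voxels <- lapply(stack@voxels, function(a) a[ys, xs, zs, drop = FALSE])
  sp <- stack@spacing
  newOrigin <- stack@origin + c((full$x[1] - 1) * sp[["dx"]],
                                (full$y[1] - 1) * sp[["dy"]],
                                (full$z[1] - 1) * sp[["dz"]])
  IntensityStack(voxels, spacing = sp, channelNames = stack@channelNames,
                 origin = newOrigin)
}

#' Per-slice median despeckle filter
#'
#' Applies a 2D median filter of the given pixel radius to every z-slice of
#' every channel (the classic despeckle operation). Shape, spacing and
#' integer dtype are unchanged.
#'
#' @param stack an [IntensityStack-class].
#' @param radius filter radius in pixels (>= 1).
#' @return the filtered [IntensityStack-class].
#' @export
despeckle <- function(stack, radius = 1L) {
  stopifnot(is(stack, "IntensityStack"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  voxels <- lapply(stack@voxels, function(arr) {
    maxv <- max(arr, 1)
    out <- arr
    for (k in seq_len(dim(arr)[3])) {
      sl <- arr[, , k] / maxv
      out[, , k] <- round(EBImage::medianFilter(sl, radius) * maxv)
    }
    storage.mode(out) <- storage.mode(arr)
    out
  })
  IntensityStack(voxels, spacing = stack@spacing,
                 channelNames = stack@channelNames, origin = stack@origin)
}
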