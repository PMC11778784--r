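## negative_space: label-free extraction of the compartment between two
## tissue layers (the cardiac extracellular matrix) by boolean mask algebra.
##
## The ECM is the negative space inside the outer layer's lumen that is not
## occupied by the inner layer: combining the filled internal contour of
## the outer layer (myocardium) with the filled external contour of the
## inner layer (endocardium) through AND and XOR,
##   ecm = inner_bound XOR (inner_bound AND outer_bound)
##       = inner_bound AND NOT outer_bound.

.checkSameGrid <- function(a, b) {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop("masks differ in shape")
  if (max(abs(a@spacing - b@spacing)) > 1e-9 ||
      max(abs(a@origin - b@origin)) > 1e-9)
    stop("masks differ in spacing/origin")
}

#' Extract the inter-layer (ECM) compartment
#'
#' `innerBound` is the filled internal contour mask of the outer tissue
#' layer (e.g. the myocardial lumen); `outerBound` is the filled external
#' contour mask of the inner layer (e.g. the whole endocardium). The result
#' is `innerBound XOR (innerBound AND outerBound)`, i.e. the voxels of the
#' outer layer's lumen not claimed by the inner layer. Inner-layer voxels
#' protruding outside `innerBound` (segmentation noise) are clipped and
#' reported as `meta$leak_voxels`, never silently kept.
#'
#' @param innerBound,outerBound [VoxelMask-class] objects on one grid.
#' @param label compartment name for the result.
#' @return a [VoxelMask-class]; `meta$leak_voxels` counts outer-bound
#'   voxels outside the inner bound.
#' @export
ecmMask <- function(innerBound, outerBound, label = "ECM") {
  stopifnot(is(innerBound, "VoxelMask"), is(outerBound, "VoxelMask"))
  .checkSameGrid(innerBound, outerBound)
  a <- innerBound@voxels
  b <- outerBound@voxels
  ecm <- xor(a, a & b)                     # == a & !b
  leak <- sum(b & !a)
  if (leak > 0)
    message(sprintf("ecmMask: %d inner-layer voxels protrude beyond the outer layer's lumen (clipped)", leak))
  VoxelMask(ecm, spacing = innerBound@spacing, origin = innerBound@origin,
            label = label, meta = list(leak_voxels = leak))
}

#' Volume of a voxel mask
#'
#' @param mask a [VoxelMask-class].
#' @return true-voxel count times voxel volume, cubic micrometres.
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  sum(mask@voxels) * prod(mask@spacing)
}

#' Compartment volume table
#'
#' Reports the volumes (and percentage shares of the outer layer's filled
#' external volume) of the four disjoint heart compartments: outer-layer
#' tissue (myocardium), inner-layer tissue (endocardium), lumen (filled
#' internal contour of the inner layer) and ECM. Shares of the disjoint
#' compartments sum to 100% of the outer filled-external volume up to the
#' reported leak residual.
#'
#' @param lib a [ContourLibrary-class] holding both layers.
#' @param ecm the [VoxelMask-class] from [ecmMask()].
#' @param outerChannel,innerChannel channel names of the outer (myocardial)
#'   and inner (endocardial) layer.
#' @return data.frame with columns `compartment`, `volume_um3`,
#'   `share_pct`, plus attribute `leak_um3` for mask-leak residual.
#' @export
compartmentVolumes <- function(lib, ecm, outerChannel = 1L,
                               innerChannel = 2L) {
  stopifnot(is(lib, "ContourLibrary"), is(ecm, "VoxelMask"))
  chs <- lib@channelNames
  if (is.numeric(outerChannel)) outerChannel <- chs[outerChannel]
  if (is.numeric(innerChannel)) innerChannel <- chs[innerChannel]
  vv <- prod(lib@spacing)
  myoT <- lib@masks[[outerChannel]]$tissue
  endoE <- lib@masks[[innerChannel]]$filled_external
  myoI <- lib@masks[[outerChannel]]$filled_internal
  if (!identical(dim(myoT), dim(ecm@voxels)))
    stop("ECM mask grid inconsistent with the contour library")
  # endocardial tissue/lumen clipped to the myocardial lumen, consistent
  # with the leak handling of ecmMask()
  endoTissue <- lib@masks[[innerChannel]]$tissue & myoI
  lumen <- lib@masks[[innerChannel]]$filled_internal & myoI
  vols <- c(myocardium = sum(myoT) * vv,
            endocardium = sum(endoTissue) * vv,
            lumen = sum(lumen) * vv,
            ECM = sum(ecm@voxels) * vv)
  total <- sum(lib@masks[[outerChannel]]$filled_external) * vv
  leak <- sum(endoE & !myoI) * vv
  out <- data.frame(compartment = names(vols),
                    volume_um3 = unname(vols),
                    share_pct = unname(vols) / total * 100,
                    row.names = NULL)
  attr(out, "total_um3") <- total
  attr(out, "leak_um3") <- leak
  out
}

#' Write a volume table as CSV
#'
#' @param volumes data.frame from [compartmentVolumes()].
#' @param path output CSV path.
#' @export
writeVolumesCsv <- function(volumes, path) {
  utils::write.csv(volumes, path, row.names = FALSE)
  invisible(path)
}
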