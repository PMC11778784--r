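## cells: nuclei-level analysis — chamber/region assignment of nuclei
## centroids and internuclear distance (IND) as a proxy for cell size.
## Nuclei coordinates come from an external spot detector; they are
## consumed, never computed here.

#' Load nuclei centroids from CSV
#'
#' Expects numeric columns `x`, `y`, `z` in micrometres (an optional `id`
#' column is ignored). Duplicate points within 0.1 um are merged with a
#' warning; all labels start unassigned.
#'
#' @param path CSV file path.
#' @return a [NucleiSet-class].
#' @export
loadNuclei <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stop("nuclei CSV must have columns x, y, z")
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop("non-numeric value in column '", cn, "', row ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
  }
  if (nrow(df) < 1) stop("nuclei CSV holds no rows")
  P <- as.matrix(df[, need])
  if (any(!is.finite(P))) stop("non-finite nuclei coordinate")
  keep <- rep(TRUE, nrow(P))
  if (nrow(P) > 1) {
    nn <- FNN::get.knn(P, k = 1)
    for (a in seq_len(nrow(P))) {
      b <- nn$nn.index[a, 1]
      if (keep[a] && keep[b] && a > b && nn$nn.dist[a, 1] < 0.1)
        keep[a] <- FALSE
    }
    if (any(!keep))
      warning(sum(!keep), " duplicate nucleus point(s) within 0.1 um merged")
  }
  NucleiSet(P[keep, , drop = FALSE])
}

#' Assign nuclei to chambers with a cutting disc
#'
#' Nuclei are classified by the sign of `(p - centre) . normal` with the
#' same convention as [splitByDisc()]; nuclei exactly on the plane take the
#' ventricular label (documented tie-break). Flipping the normal (or
#' `atrialSide`) swaps the labels.
#'
#' @param nuclei a [NucleiSet-class].
#' @param disc a [CutDisc-class].
#' @param atrialSide `"positive"` or `"negative"` side of the plane.
#' @return the [NucleiSet-class] with chamber labels set; per-chamber
#'   counts are reported as a message.
#' @export
assignChambers <- function(nuclei, disc, atrialSide = c("positive",
                                                        "negative")) {
  stopifnot(is(nuclei, "NucleiSet"), is(disc, "CutDisc"))
  atrialSide <- match.arg(atrialSide)
  sgnA <- if (atrialSide == "positive") 1 else -1
  s <- as.numeric(sweep(nuclei@points, 2, disc@centre) %*% disc@normal)
  nuclei@chamber <- ifelse(sgnA * s > 0, "atrium", "ventricle")
  message(sprintf("assigned %d atrial / %d ventricular nuclei",
                  sum(nuclei@chamber == "atrium"),
                  sum(nuclei@chamber == "ventricle")))
  nuclei
}

#' Assign nuclei to chamber regions about the centreline
#'
#' For each nucleus the nearest centreline point defines the local tangent
#' `t`; with dorsal reference `d` and lateral axis `l = t x d`, the angle
#' of the nucleus offset in the (d, l) frame buckets it into four 90-degree
#' sectors centred on +/-d and +/-l: dorsal, ventral, and the two lateral
#' curvatures. A nucleus exactly on a 45-degree sector boundary joins the
#' counter-clockwise-next sector (documented tie-break). Lateral sectors
#' map to outer/inner curvature via `outerIsLeft`.
#'
#' @param nuclei a [NucleiSet-class] with chamber labels assigned.
#' @param cl a [Centreline-class] traversing the chambers.
#' @param dorsalRef unit dorsal vector.
#' @param outerIsLeft is the outer curvature the left (`+l`) side? Default
#'   `TRUE` (atrial outer curvature on the left in this convention).
#' @return the [NucleiSet-class] with region labels set.
#' @export
assignRegions <- function(nuclei, cl, dorsalRef, outerIsLeft = TRUE) {
  stopifnot(is(nuclei, "NucleiSet"), is(cl, "Centreline"))
  if (all(nuclei@chamber == "unassigned"))
    stop("assign chambers before regions")
  d <- .normalize(as.numeric(dorsalRef))
  P <- nuclei@points
  nn <- FNN::get.knnx(cl@points, P, k = 1)
  ni <- nn$nn.index[, 1]
  tang <- .polylineTangents(cl@points)
  rel <- P - cl@points[ni, , drop = FALSE]
  lmat <- cbind(tang[ni, 2] * d[3] - tang[ni, 3] * d[2],
                tang[ni, 3] * d[1] - tang[ni, 1] * d[3],
                tang[ni, 1] * d[2] - tang[ni, 2] * d[1])
  compD <- rowSums(sweep(rel, 2, d, "*"))
  compL <- rowSums(rel * lmat)
  theta <- atan2(compL, compD) * 180 / pi      # 0 = dorsal, +90 = left
  left <- if (outerIsLeft) "outer" else "inner"
  right <- if (outerIsLeft) "inner" else "outer"
  # half-open sectors [lo, hi): a 45-degree tie joins the CCW-next sector
  nuclei@region <- ifelse(theta >= -45 & theta < 45, "dorsal",
                   ifelse(theta >= 45 & theta < 135, left,
                   ifelse(theta >= -135 & theta < -45, right, "ventral")))
  nuclei
}

#' Internuclear distance per seed nucleus
#'
#' Every nucleus acts as a seed; its IND is the mean 3D Euclidean distance
#' to its `k` nearest neighbours within the same chamber. Per-chamber and
#' per-region averages of the seed INDs are returned alongside. Chambers
#' with too few nuclei are skipped with a warning.
#'
#' @param nuclei a [NucleiSet-class] with chamber labels assigned.
#' @param k number of neighbours per seed (default 4).
#' @return list with `nuclei` (the set with per-seed `ind` filled),
#'   `per_chamber` and `per_region` data.frames of mean IND.
#' @export
internuclearDistance <- function(nuclei, k = 4L) {
  stopifnot(is(nuclei, "NucleiSet"))
  k <- as.integer(k)
  ind <- rep(NA_real_, nrow(nuclei@points))
  for (ch in unique(nuclei@chamber)) {
    sel <- which(nuclei@chamber == ch)
    if (length(sel) <= k) {
      warning("chamber '", ch, "' has <= k nuclei; skipped")
      next
    }
    nn <- FNN::get.knn(nuclei@points[sel, , drop = FALSE], k = k)
    ind[sel] <- rowMeans(nn$nn.dist)
  }
  nuclei@ind <- ind
  ok <- !is.na(ind)
  df <- data.frame(ind = ind[ok], chamber = nuclei@chamber[ok],
                   region = nuclei@region[ok],
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    perCh <- stats::aggregate(ind ~ chamber, data = df, FUN = mean)
    names(perCh)[2] <- "mean_ind_um"
    perRe <- stats::aggregate(ind ~ chamber + region, data = df, FUN = mean)
    names(perRe)[3] <- "mean_ind_um"
    perRe$n <- stats::aggregate(ind ~ chamber + region, data = df,
                                FUN = length)$ind
  } else {
    perCh <- data.frame(chamber = character(0), mean_ind_um = numeric(0))
    perRe <- data.frame(chamber = character(0), region = character(0),
                        mean_ind_um = numeric(0), n = integer(0))
  }
  list(nuclei = nuclei, per_chamber = perCh, per_region = perRe)
}

#' Export nuclei with labels and IND as CSV
#'
#' @param nuclei a [NucleiSet-class].
#' @param path output CSV (id, x, y, z, chamber, region, ind_um).
#' @export
writeNucleiCsv <- function(nuclei, path) {
  stopifnot(is(nuclei, "NucleiSet"))
  df <- data.frame(id = seq_len(nrow(nuclei@points)),
                   x = nuclei@points[, 1], y = nuclei@points[, 2],
                   z = nuclei@points[, 3], chamber = nuclei@chamber,
                   region = nuclei@region, ind_um = nuclei@ind)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
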