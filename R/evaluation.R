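# Deformation-quality and label-overlap metrics: Jacobian determinant maps
# of W(x) = x + u(x), folding counts (negative determinants flag physically
# invalid, space-inverting deformations), nearest-neighbor label
# propagation, and per-region Dice overlap.

# d(arr)/d(axis) by central differences, one-sided at the two faces.
axisGradient <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  sl <- function(i) switch(axis,
    arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
    arr[, , i, drop = FALSE])
  g <- array(0, d)
  asg <- function(i, val) {
    switch(axis,
      g[i, , ] <<- val, g[, i, ] <<- val, g[, , i] <<- val)
  }
  asg(2:(n - 1), (sl(3:n) - sl(1:(n - 2))) / 2)
  asg(1L, sl(2L) - sl(1L))
  asg(n, sl(n) - sl(n - 1L))
  g
}

#' Voxelwise Jacobian determinant of the transform W(x) = x + u(x)
#'
#' det(I + grad u) with the displacement gradient taken by central
#' differences in voxel units (one-sided at the volume faces). Values below
#' 1 mean local contraction, above 1 local expansion, and negative values
#' mean the transform folds space at that voxel.
#'
#' @param field a [DisplacementField]; all dimensions must be >= 3.
#' @return a [Volume] holding the determinant map.
#' @export
jacobianDeterminant <- function(field) {
  d <- dim(field@vectors)[1:3]
  if (any(d < 3L)) stop("degenerate shape: all dimensions must be >= 3")
  J <- vector("list", 9L)  # J[[3*(c-1)+a]] = d u_c / d x_a
  for (cc in 1:3)
    for (ax in 1:3)
      J[[3L * (cc - 1L) + ax]] <-
        axisGradient(array(field@vectors[, , , cc], d), ax)
  E <- function(cc, ax) J[[3L * (cc - 1L) + ax]] + (cc == ax)
  det <- E(1, 1) * (E(2, 2) * E(3, 3) - E(2, 3) * E(3, 2)) -
         E(1, 2) * (E(2, 1) * E(3, 3) - E(2, 3) * E(3, 1)) +
         E(1, 3) * (E(2, 1) * E(3, 2) - E(2, 2) * E(3, 1))
  Volume(det, field@spacing)
}

#' Count folded voxels (negative Jacobian determinant)
#'
#' @param jmap a [Volume] determinant map from [jacobianDeterminant()].
#' @return integer count of voxels with det < 0 (boundary voxels included).
#' @export
countFoldings <- function(jmap) {
  sum(volData(jmap) < 0)
}

#' Propagate a label volume through a displacement field
#'
#' Nearest-neighbor sampling at v + u(v): labels are never interpolated,
#' so only label values present in the input can appear. Out-of-bounds
#' sample locations are clamped to the border voxel.
#'
#' @param labels a [LabelVolume].
#' @param field a [DisplacementField] on the output grid.
#' @return a [LabelVolume] on the field's grid.
#' @export
warpLabels <- function(labels, field) {
  warpVolume(labels, field)
}

#' Per-region Dice overlap between two label volumes
#'
#' Dice(l) = 2 |A_l intersect B_l| / (|A_l| + |B_l|). Regions absent from
#' both volumes are reported as NA (undefined), not 0 or 1, and should be
#' excluded from mean aggregation.
#'
#' @param a,b [LabelVolume]s on the same grid.
#' @param regionIds regions to evaluate; default: all positive labels
#'   present in either volume.
#' @return data.frame with columns \code{region} and \code{dice}.
#' @export
dicePerRegion <- function(a, b, regionIds = NULL) {
  da <- volData(a); db <- volData(b)
  if (!all(dim(da) == dim(db))) stop("label volumes must share a grid")
  if (is.null(regionIds))
    regionIds <- sort(setdiff(unique(c(da, db)), 0))
  dice <- vapply(regionIds, function(l) {
    na <- sum(da == l); nb <- sum(db == l)
    if (na + nb == 0) return(NA_real_)
    2 * sum(da == l & db == l) / (na + nb)
  }, numeric(1))
  data.frame(region = regionIds, dice = dice)
}
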