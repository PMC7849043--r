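# Image containers, trilinear sampling, warping, and the multiresolution
# pyramid. All interpolation runs in double precision; displacement vectors
# are stored in voxel units of the grid they live on, so they scale with
# resolution when moved between pyramid levels.

#' @rdname sampleTrilinear
#' @export
setMethod("sampleTrilinear", "Volume", function(vol, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be a 3-vector or an m x 3 matrix")
  if (any(!is.finite(points))) stop("invalid coordinate: non-finite point")
  cpp_sample_trilinear(vol@data, dim(vol@data), points - 1)
})

#' @rdname warpVolume
#' @export
setMethod("warpVolume", signature("Volume", "DisplacementField"),
  function(src, field) {
    u <- field@vectors
    out <- cpp_warp(src@data, dim(src@data), u, dim(u)[1:3], 0L)
    Volume(array(out, dim(u)[1:3]), field@spacing)
  })

#' @rdname warpVolume
#' @export
setMethod("warpVolume", signature("LabelVolume", "DisplacementField"),
  function(src, field) {
    u <- field@vectors
    out <- cpp_warp(src@data, dim(src@data), u, dim(u)[1:3], 1L)
    LabelVolume(array(out, dim(u)[1:3]), field@spacing)
  })

# Separable Gaussian smoothing with border renormalization (the truncated
# kernel is rescaled to unit mass at the borders, so constants are
# preserved exactly).
gaussianKernelMatrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-(idx^2) / (2 * sigma^2))
  K[idx > r] <- 0
  K / rowSums(K)
}

#' Gaussian-smooth a 3-D array (separable, border-renormalized)
#'
#' @param arr 3-D numeric array.
#' @param sigma standard deviation in voxels; the kernel is truncated at
#'   3 sigma and renormalized at borders.
#' @return smoothed array of the same shape.
#' @export
gaussianSmooth3D <- function(arr, sigma) {
  d <- dim(arr)
  if (sigma <= 0) return(arr)
  # axis 1
  if (d[1] > 1L)
    arr <- array(gaussianKernelMatrix(d[1], sigma) %*%
                   matrix(arr, d[1], d[2] * d[3]), d)
  # axis 2
  if (d[2] > 1L) {
    a <- aperm(arr, c(2, 1, 3))
    a <- array(gaussianKernelMatrix(d[2], sigma) %*%
                 matrix(a, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    arr <- aperm(a, c(2, 1, 3))
  }
  # axis 3
  if (d[3] > 1L) {
    a <- aperm(arr, c(3, 2, 1))
    a <- array(gaussianKernelMatrix(d[3], sigma) %*%
                 matrix(a, d[3], d[2] * d[1]), c(d[3], d[2], d[1]))
    arr <- aperm(a, c(3, 2, 1))
  }
  arr
}

downsampleVolume <- function(vol, sigma = 1) {
  d <- dim(vol@data)
  sm <- gaussianSmooth3D(vol@data, sigma)
  idx <- lapply(d, function(n) seq(1L, n, by = 2L))
  Volume(sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], vol@spacing * 2)
}

#' Build a coarse-to-fine multiresolution pyramid
#'
#' The finest level is the input pair unchanged; every coarser level is
#' Gaussian-smoothed (sigma = 1 voxel) and decimated by 2 per axis, giving
#' the ceil(n/2) dimension recurrence. Building stops with an error if any
#' axis of the coarsest level would drop below 2 voxels.
#'
#' @param target,source [Volume] pair on the same grid.
#' @param nLevels number of levels (>= 1).
#' @return a [VolumePyramid], levels ordered coarse to fine.
#' @export
buildPyramid <- function(target, source, nLevels) {
  nLevels <- as.integer(nLevels)
  if (nLevels < 1L) stop("nLevels must be >= 1")
  if (!all(dim(target) == dim(source)))
    stop("target and source must share a grid")
  d <- dim(target)
  for (k in seq_len(nLevels - 1L)) d <- ceiling(d / 2)
  if (any(d < 2L)) {
    ax <- c("x", "y", "z")[which.min(d)]
    stop(sprintf(
      "nLevels = %d is too large: axis %s would shrink below 2 voxels",
      nLevels, ax))
  }
  tl <- list(target)
  sl <- list(source)
  for (k in seq_len(nLevels - 1L)) {
    tl <- c(list(downsampleVolume(tl[[1L]])), tl)
    sl <- c(list(downsampleVolume(sl[[1L]])), sl)
  }
  new("VolumePyramid", target = tl, source = sl)
}

#' Upsample a displacement field to the next finer pyramid level
#'
#' Each component is trilinearly interpolated onto the finer grid and
#' multiplied by the per-axis shape ratio: displacements are stored in
#' voxel units, so the vectors scale with resolution. The shape ratio must
#' lie in [1.5, 2.5] per axis (guard against passing mismatched levels).
#'
#' @param field a [DisplacementField] at the coarse level.
#' @param targetShape integer(3) fine-grid dimensions.
#' @return a [DisplacementField] on the fine grid.
#' @export
upsampleField <- function(field, targetShape) {
  targetShape <- as.integer(targetShape)
  dc <- dim(field@vectors)[1:3]
  ratio <- targetShape / dc
  if (any(ratio < 1.5 | ratio > 2.5))
    stop("shape ratio outside [1.5, 2.5]: not adjacent pyramid levels")
  # coarse node k sits at fine node 2k-1 (1-based); fine coord f maps to
  # coarse coord (f + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(targetShape[1]),
                             y = seq_len(targetShape[2]),
                             z = seq_len(targetShape[3])))
  pts <- (g + 1) / 2
  out <- array(0, c(targetShape, 3L))
  for (c in 1:3) {
    comp <- Volume(array(field@vectors[, , , c], dc))
    out[, , , c] <- array(sampleTrilinear(comp, pts), targetShape) * ratio[c]
  }
  DisplacementField(out, field@spacing / ratio * 1)
}

# Decimate a fine-level field onto a coarser grid (initialization support):
# keep every 2nd node and scale vectors by the shape ratio.
downsampleField <- function(field) {
  d <- dim(field@vectors)[1:3]
  idx <- lapply(d, function(n) seq(1L, n, by = 2L))
  dc <- vapply(idx, length, 1L)
  v <- field@vectors[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  for (c in 1:3) v[, , , c] <- v[, , , c] * (dc[c] / d[c])
  DisplacementField(v, field@spacing * (d / dc))
}
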