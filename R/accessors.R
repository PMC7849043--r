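#' Construct a Volume
#'
#' @param data 3-D numeric array of finite intensities.
#' @param spacing numeric(3) voxel size, default 1 on every axis.
#' @return a [Volume].
#' @export
Volume <- function(data, spacing = c(1, 1, 1)) {
  storage.mode(data) <- "double"
  new("Volume", data = data, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param data 3-D array of non-negative integer region labels
#'   (0 = background).
#' @param spacing numeric(3) voxel size.
#' @return a [LabelVolume].
#' @export
LabelVolume <- function(data, spacing = c(1, 1, 1)) {
  storage.mode(data) <- "double"
  new("LabelVolume", data = data, spacing = as.numeric(spacing))
}

#' Construct a DisplacementField
#'
#' @param vectors 4-D array (nx, ny, nz, 3) of displacements in voxel units
#'   of the grid the field lives on.
#' @param spacing numeric(3) voxel size.
#' @return a [DisplacementField].
#' @export
DisplacementField <- function(vectors, spacing = c(1, 1, 1)) {
  storage.mode(vectors) <- "double"
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing))
}

#' Construct an all-zero (identity) displacement field
#'
#' @param shape integer(3) grid dimensions.
#' @param spacing numeric(3) voxel size.
#' @return a [DisplacementField] with u == 0.
#' @export
zeroField <- function(shape, spacing = c(1, 1, 1)) {
  DisplacementField(array(0, c(shape, 3L)), spacing)
}

#' Construct a RegistrationConfig
#'
#' Defaults are documented choices, not values claimed to reproduce any
#' published experiment. epsilon = 0.5 gives sub-voxel displacement
#' resolution; radius = 2 yields a 33-node spherical PCC window;
#' blockSize = 16 matches the subregion size the method was designed
#' around. gamma = 4 with alpha = 0.2 penalizes fold-scale neighbor
#' differences (about 1 voxel) at full alpha while single epsilon steps
#' cost only alpha * epsilon^4 = alpha/16, i.e. smoothness acts on large
#' derivatives without freezing sub-voxel refinement. presmoothSigma = 1
#' removes the interpolation noise-smoothing bias of windowed correlation
#' (see the methods vignette).
#'
#' @param alpha data/regularization balance (>= 0).
#' @param gamma regularizer exponent (>= 2, submodularity requirement).
#' @param epsilon move step in voxel units (> 0).
#' @param radius PCC window radius in voxels (>= 1).
#' @param blockSize subregion extent per axis (>= 2).
#' @param nLevels pyramid levels (>= 1).
#' @param maxSweepsPerLevel sweep cap per level.
#' @param metric "pcc" or "ssd".
#' @param presmoothSigma input smoothing in voxels (0 disables).
#' @param convergenceTol relative per-sweep energy decrease below which a
#'   level is declared converged (besides the zero-flip rule).
#' @param nWorkers worker processes for blockwise parallelism.
#' @param seed integer recorded for provenance.
#' @return a [RegistrationConfig].
#' @export
registrationConfig <- function(alpha = 0.2, gamma = 4, epsilon = 0.5,
                               radius = 2L, blockSize = 16L, nLevels = 3L,
                               maxSweepsPerLevel = 12L, metric = "pcc",
                               presmoothSigma = 1, convergenceTol = 1e-4,
                               nWorkers = 1L, seed = 0L) {
  new("RegistrationConfig", alpha = as.numeric(alpha),
      gamma = as.numeric(gamma), epsilon = as.numeric(epsilon),
      radius = as.integer(radius), blockSize = as.integer(blockSize),
      nLevels = as.integer(nLevels),
      maxSweepsPerLevel = as.integer(maxSweepsPerLevel),
      metric = as.character(metric),
      presmoothSigma = as.numeric(presmoothSigma),
      convergenceTol = as.numeric(convergenceTol),
      nWorkers = as.integer(nWorkers), seed = as.integer(seed))
}

#' @rdname Volume-class
#' @export
setMethod("volData", "Volume", function(x) x@data)

#' @rdname Volume-class
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname DisplacementField-class
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' @rdname DisplacementField-class
#' @export
setMethod("fieldVectors", "DisplacementField", function(x) x@vectors)

#' @rdname Volume-class
#' @export
setMethod("dim", "Volume", function(x) dim(x@data))

#' @rdname DisplacementField-class
#' @export
setMethod("dim", "DisplacementField", function(x) dim(x@vectors)[1:3])

#' @rdname RegistrationResult-class
#' @export
setMethod("resultField", "RegistrationResult", function(x) x@field)

#' @rdname RegistrationResult-class
#' @export
setMethod("sweepReports", "RegistrationResult", function(x) x@reports)

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("spacing (%g, %g, %g)", object@spacing[1], object@spacing[2],
              object@spacing[3]),
      sprintf("range [%.4g, %.4g]\n", min(object@data), max(object@data)))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  n <- sqrt(rowSums(matrix(object@vectors, ncol = 3L)^2))
  cat("DisplacementField", sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| max |u| = %.4g voxels\n", max(n)))
})

setMethod("show", "VolumePyramid", function(object) {
  cat("VolumePyramid with", length(object@target), "level(s), coarse to fine:\n")
  for (k in seq_along(object@target)) {
    d <- dim(object@target[[k]]@data)
    cat(sprintf("  level %d: %d x %d x %d\n", k, d[1], d[2], d[3]))
  }
})

setMethod("show", "RegistrationConfig", function(object) {
  cat("RegistrationConfig:",
      sprintf("alpha=%g gamma=%g epsilon=%g radius=%d", object@alpha,
              object@gamma, object@epsilon, object@radius),
      sprintf("blockSize=%d nLevels=%d maxSweeps=%d metric=%s",
              object@blockSize, object@nLevels, object@maxSweepsPerLevel,
              object@metric),
      sprintf("presmooth=%g convTol=%g workers=%d\n",
              object@presmoothSigma, object@convergenceTol,
              object@nWorkers))
})

setMethod("show", "BlockPartition", function(object) {
  cat("BlockPartition:", nrow(object@lo), "block(s) tiling",
      paste(object@shape, collapse = " x "),
      "| offset", paste(object@offset, collapse = ","), "\n")
})

setMethod("show", "RegistrationResult", function(object) {
  r <- object@reports
  cat("RegistrationResult:", nrow(r), "sweep(s) over",
      length(unique(r$level)), "level(s)\n")
  if (nrow(r) > 0) {
    fin <- r[r$level == max(r$level), ]
    cat(sprintf(
      "  finest level: energy %.6g -> %.6g over %d sweep(s); %d voxel updates total\n",
      fin$energyBefore[1], fin$energyAfter[nrow(fin)], nrow(fin),
      sum(r$changedVoxels)))
  }
  show(object@field)
})
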