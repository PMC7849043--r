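#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib gcdeform, .registration = TRUE
NULL

#' Volume: a 3-D scalar image on a regular grid
#'
#' A \code{Volume} holds a dense 3-D array of finite real intensities on a
#' regular voxel grid, together with the per-axis voxel size. Voxel
#' coordinates in this package are 1-based: grid nodes sit at integer
#' coordinates \code{1..n} along each axis, matching R array indexing.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing numeric(3), per-axis voxel size (arbitrary length units).
#'
#' @seealso [Volume()], [sampleTrilinear()], [warpVolume()]
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a 3-D array")
    if (any(dim(d) < 1L)) return("all dimensions must be >= 1")
    if (length(object@spacing) != 3L) return("spacing must have length 3")
    if (any(!is.finite(object@spacing)) || any(object@spacing <= 0))
      return("all spacings must be positive and finite")
    if (any(!is.finite(d))) return("intensities must be finite (no NaN/Inf)")
    TRUE
  })

#' LabelVolume: a 3-D volume of integer region labels
#'
#' Integer-valued [Volume] used for segmentations. Label 0 is reserved for
#' background; positive labels identify regions.
#'
#' @export
setClass("LabelVolume", contains = "Volume",
  validity = function(object) {
    d <- object@data
    if (any(d != round(d))) return("labels must be integer-valued")
    if (any(d < 0)) return("labels must be non-negative (0 = background)")
    TRUE
  })

#' DisplacementField: a dense per-voxel displacement field
#'
#' Stores one 3-vector u(v) per voxel of the associated target grid, in
#' voxel units of that grid. The induced transform is W(v) = v + u(v): the
#' source image is sampled at the displaced location (pull-back convention).
#'
#' @slot vectors 4-D numeric array shaped (nx, ny, nz, 3).
#' @slot spacing numeric(3), voxel size of the grid the field lives on.
#'
#' @seealso [DisplacementField()], [warpVolume()], [jacobianDeterminant()]
#' @export
setClass("DisplacementField",
  representation(vectors = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@vectors
    if (length(dim(v)) != 4L || dim(v)[4] != 3L)
      return("vectors must be a 4-D array with trailing dimension 3")
    if (any(!is.finite(v))) return("all displacement components must be finite")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    TRUE
  })

#' VolumePyramid: a coarse-to-fine multiresolution pyramid of image pairs
#'
#' Levels are ordered coarse to fine; the finest level holds the input
#' target/source pair unchanged. Each coarser level is obtained by Gaussian
#' smoothing followed by decimation by 2, so level k has dimensions
#' ceil(dim(level k+1) / 2).
#'
#' @slot target list of [Volume], coarse to fine.
#' @slot source list of [Volume], coarse to fine.
#'
#' @seealso [buildPyramid()]
#' @export
setClass("VolumePyramid",
  representation(target = "list", source = "list"),
  validity = function(object) {
    if (length(object@target) < 1L) return("at least 1 level required")
    if (length(object@target) != length(object@source))
      return("target and source level counts differ")
    for (k in seq_along(object@target)) {
      if (!is(object@target[[k]], "Volume") || !is(object@source[[k]], "Volume"))
        return("pyramid levels must be Volume objects")
    }
    if (length(object@target) > 1L) {
      for (k in seq_len(length(object@target) - 1L)) {
        df <- dim(object@target[[k + 1L]]@data)
        dc <- dim(object@target[[k]]@data)
        if (!all(dc == ceiling(df / 2)))
          return("level k dims must equal ceiling(level k+1 dims / 2)")
      }
    }
    TRUE
  })

#' RegistrationConfig: tunable parameters of the registration
#'
#' @slot alpha non-negative balance between data term and regularizer; the
#'   objective is f(u) = D(u) + alpha * R(u).
#' @slot gamma regularizer exponent, must be >= 2 (the binary terms of the
#'   move energy are provably submodular only for gamma >= 2; smaller values
#'   would void the exactness guarantee of the graph-cut solver).
#' @slot epsilon move step in voxel units (> 0); displacements are updated
#'   in increments of +/- epsilon along coordinate axes, so epsilon sets the
#'   resolution of the discrete displacement grid (typically sub-voxel).
#' @slot radius integer radius (voxels) of the spherical PCC window.
#' @slot blockSize per-axis extent of the subregions (>= 2).
#' @slot nLevels number of pyramid levels.
#' @slot maxSweepsPerLevel sweep cap per level (a sweep tries all 6 signed
#'   axis moves on every block).
#' @slot metric "pcc" (windowed Pearson correlation) or "ssd".
#' @slot presmoothSigma Gaussian smoothing (voxels) applied to both input
#'   volumes before matching. Off-grid trilinear sampling averages
#'   uncorrelated voxel noise, which biases windowed correlation toward
#'   half-grid displacements; presmoothing correlates the noise and removes
#'   that bias. 0 disables.
#' @slot convergenceTol a pyramid level also stops when a full sweep lowers
#'   the total energy by less than this relative fraction (0 = strict
#'   zero-flip convergence only).
#' @slot nWorkers worker processes for blockwise parallelism (>= 1).
#' @slot seed integer recorded for provenance (the optimizer itself is
#'   deterministic; the seed matters to synthetic-data callers).
#'
#' @seealso [registrationConfig()], [registerVolumes()]
#' @export
setClass("RegistrationConfig",
  representation(alpha = "numeric", gamma = "numeric", epsilon = "numeric",
                 radius = "integer", blockSize = "integer",
                 nLevels = "integer", maxSweepsPerLevel = "integer",
                 metric = "character", presmoothSigma = "numeric",
                 convergenceTol = "numeric", nWorkers = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@alpha) != 1L || !is.finite(object@alpha) ||
        object@alpha < 0) return("alpha must be a single non-negative number")
    if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
        object@gamma < 2)
      return("gamma must be >= 2 (submodularity requirement)")
    if (!is.finite(object@epsilon) || object@epsilon <= 0)
      return("epsilon must be > 0")
    if (object@radius < 1L) return("radius must be >= 1")
    if (object@blockSize < 2L) return("blockSize must be >= 2")
    if (object@nLevels < 1L) return("nLevels must be >= 1")
    if (object@maxSweepsPerLevel < 0L)
      return("maxSweepsPerLevel must be >= 0")
    if (!object@metric %in% c("pcc", "ssd"))
      return("metric must be 'pcc' or 'ssd'")
    if (object@presmoothSigma < 0) return("presmoothSigma must be >= 0")
    if (object@convergenceTol < 0) return("convergenceTol must be >= 0")
    if (object@nWorkers < 1L) return("nWorkers must be >= 1")
    TRUE
  })

#' BlockPartition: decomposition of the voxel grid into subregions
#'
#' Axis-aligned boxes tiling the grid; an offset in [0, blockSize) shifts
#' the tiling so block boundaries move between sweeps. Blocks are pairwise
#' disjoint, jointly cover the grid, and none is empty; border blocks may be
#' smaller than \code{blockSize}.
#'
#' @slot lo integer matrix (n x 3) of 1-based inclusive lower corners.
#' @slot hi integer matrix (n x 3) of 1-based inclusive upper corners.
#' @slot index integer matrix (n x 3), ordinal position of each block along
#'   each axis of the block grid (used for checkerboard coloring).
#' @slot blockSize integer(3).
#' @slot offset integer(3).
#' @slot shape integer(3), the partitioned grid.
#'
#' @seealso [partitionBlocks()]
#' @export
setClass("BlockPartition",
  representation(lo = "matrix", hi = "matrix", index = "matrix",
                 blockSize = "integer", offset = "integer",
                 shape = "integer"),
  validity = function(object) {
    if (nrow(object@lo) != nrow(object@hi)) return("lo/hi row mismatch")
    if (any(object@hi < object@lo)) return("empty block")
    vol <- sum(apply(object@hi - object@lo + 1L, 1L, prod))
    if (vol != prod(object@shape)) return("blocks do not tile the grid")
    TRUE
  })

#' MoveTerms: unary and pairwise energy tables for one candidate move
#'
#' For a block V' and a move delta, the restricted move energy is
#' sum_v phi_v(L(v)) + sum_(v,w) phi_vw(L(v), L(w)). \code{unary} holds the
#' (unweighted) data terms for labels 0/1; \code{innerTerms} holds the
#' alpha-weighted pairwise tables (phi00, phi01, phi10, phi11) for
#' 6-neighbor pairs with both endpoints inside the block (the set N'');
#' \code{boundaryTerms} holds (phi(0,0), phi(1,0)) for pairs with exactly
#' one endpoint inside (N' \\ N''), the outside endpoint's label fixed at 0.
#'
#' @slot lo,hi integer(3), 1-based inclusive block corners.
#' @slot unary numeric matrix (|V'| x 2), data term for labels 0 and 1.
#' @slot pairsInner integer matrix (k x 2) of within-block linear indices.
#' @slot innerTerms numeric matrix (k x 4), alpha-weighted pairwise tables.
#' @slot boundaryIdx integer vector of inside-endpoint linear indices.
#' @slot boundaryTerms numeric matrix (m x 2), alpha-weighted.
#' @slot delta numeric(3), the candidate move.
#' @slot alpha,gamma numeric, the weights used to build the tables.
#'
#' @seealso [buildMoveTerms()], [solveBlockMove()]
#' @export
setClass("MoveTerms",
  representation(lo = "integer", hi = "integer", unary = "matrix",
                 pairsInner = "matrix", innerTerms = "matrix",
                 boundaryIdx = "integer", boundaryTerms = "matrix",
                 delta = "numeric", alpha = "numeric", gamma = "numeric"),
  validity = function(object) {
    n <- prod(object@hi - object@lo + 1L)
    if (nrow(object@unary) != n) return("unary row count != block size")
    if (any(!is.finite(object@unary)) || any(!is.finite(object@innerTerms)) ||
        any(!is.finite(object@boundaryTerms)))
      return("all energy table entries must be finite")
    if (nrow(object@innerTerms) > 0) {
      viol <- object@innerTerms[, 1] + object@innerTerms[, 4] >
        object@innerTerms[, 2] + object@innerTerms[, 3] + 1e-9
      if (any(viol)) return("pairwise table violates submodularity")
    }
    TRUE
  })

#' RegistrationResult: displacement field plus per-sweep diagnostics
#'
#' @slot field the estimated [DisplacementField] on the finest grid.
#' @slot reports data.frame with one row per sweep: level, sweep,
#'   movesAttempted, movesAccepted, changedVoxels, energyBefore,
#'   energyAfter (both recomputed from scratch), deltaSum (sum of the
#'   per-block incremental energy deltas).
#' @slot config the [RegistrationConfig] used.
#'
#' @seealso [registerVolumes()]
#' @export
setClass("RegistrationResult",
  representation(field = "DisplacementField", reports = "data.frame",
                 config = "RegistrationConfig"))
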