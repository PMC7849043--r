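# Synthetic fixtures: Gaussian-blob phantom volumes with matched label
# maps, diffeomorphic ground-truth warps, and registration pairs built so
# that sampling the source at x + truth(x) recovers the target (the same
# pull-back convention the optimizer uses). Everything is a deterministic
# function of the spec, seed included.

# Evaluate expr with a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' PhantomSpec: parameters of the synthetic phantom generator
#'
#' @slot shape integer(3) voxel counts.
#' @slot nBlobs number of Gaussian blobs (= labeled regions).
#' @slot blobSigmaRange numeric(2), min/max blob width in voxels.
#' @slot noiseSigma i.i.d. Gaussian noise sd, in intensity units. Blob
#'   peaks span [0.6, 1] over a zero background, so the noiseless dynamic
#'   range is about 1 and the default 0.02 is about 2 percent of it.
#' @slot warpAmplitude max displacement norm of the ground-truth warp
#'   (voxels).
#' @slot warpSigma smoothing width of the warp (voxels).
#' @slot seed integer driving all randomness.
#'
#' @seealso [phantomSpec()], [makePhantom()], [makeRegistrationPair()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", nBlobs = "integer",
                 blobSigmaRange = "numeric", noiseSigma = "numeric",
                 warpAmplitude = "numeric", warpSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 4L))
      return("shape must be 3 dimensions of at least 4 voxels")
    if (object@nBlobs < 1L) return("nBlobs must be >= 1")
    if (length(object@blobSigmaRange) != 2L ||
        any(object@blobSigmaRange <= 0) ||
        object@blobSigmaRange[1] > object@blobSigmaRange[2])
      return("blobSigmaRange must be 0 < min <= max")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    if (object@warpAmplitude < 0) return("warpAmplitude must be >= 0")
    if (object@warpSigma <= 0) return("warpSigma must be > 0")
    TRUE
  })

#' Construct a PhantomSpec
#'
#' Defaults describe the standard test world: a 48^3 grid, 5 blobs of
#' width 4-8 voxels, noise at ~2 percent of the dynamic range, and a
#' smooth ground-truth warp of 3 voxels maximum displacement.
#'
#' @param shape integer(3) voxel counts.
#' @param nBlobs positive integer.
#' @param blobSigmaRange numeric(2) blob width range, voxels.
#' @param noiseSigma Gaussian noise sd in intensity units.
#' @param warpAmplitude max warp norm, voxels.
#' @param warpSigma warp smoothness, voxels.
#' @param seed integer.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(shape = c(48L, 48L, 48L), nBlobs = 5L,
                        blobSigmaRange = c(4, 8), noiseSigma = 0.02,
                        warpAmplitude = 3, warpSigma = 8, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), nBlobs = as.integer(nBlobs),
      blobSigmaRange = as.numeric(blobSigmaRange),
      noiseSigma = as.numeric(noiseSigma),
      warpAmplitude = as.numeric(warpAmplitude),
      warpSigma = as.numeric(warpSigma), seed = as.integer(seed))
}

# Draw blob centers (min pairwise separation), widths and peak heights.
# Peaks are distinct by construction (0.6 .. 1.0).
drawBlobs <- function(spec) {
  shape <- spec@shape
  margin <- pmax(2, round(0.15 * shape))
  minsep <- 0.25 * min(shape)
  for (attempt in 1:20) {
    centers <- matrix(NA_real_, spec@nBlobs, 3L)
    ok <- TRUE
    for (k in seq_len(spec@nBlobs)) {
      placed <- FALSE
      for (try in 1:200) {
        p <- stats::runif(3, margin + 1, shape - margin)
        if (k == 1L || all(sqrt(rowSums(
          (centers[seq_len(k - 1L), , drop = FALSE] -
             matrix(p, k - 1L, 3L, byrow = TRUE))^2)) >= minsep)) {
          centers[k, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      sigmas <- stats::runif(spec@nBlobs, spec@blobSigmaRange[1],
                             spec@blobSigmaRange[2])
      amps <- if (spec@nBlobs == 1L) 1
        else 0.6 + 0.4 * (seq_len(spec@nBlobs) - 1) / (spec@nBlobs - 1)
      return(list(centers = centers, sigmas = sigmas, amps = amps))
    }
  }
  stop("blobs not placeable within shape (grid too small for nBlobs)")
}

# Analytic phantom: intensity and argmax-blob label at arbitrary points.
phantomAt <- function(blobs, pts) {
  m <- nrow(pts)
  k <- nrow(blobs$centers)
  contrib <- matrix(0, m, k)
  for (j in seq_len(k)) {
    d2 <- (pts[, 1] - blobs$centers[j, 1])^2 +
          (pts[, 2] - blobs$centers[j, 2])^2 +
          (pts[, 3] - blobs$centers[j, 3])^2
    contrib[, j] <- blobs$amps[j] * exp(-d2 / (2 * blobs$sigmas[j]^2))
  }
  best <- max.col(contrib, ties.method = "first")
  peak <- contrib[cbind(seq_len(m), best)]
  labels <- ifelse(peak > 0.05, best, 0L)
  list(intensity = rowSums(contrib), labels = labels)
}

gridPoints <- function(shape) {
  as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                        z = seq_len(shape[3])))
}

#' Generate a phantom volume and its label map
#'
#' A sum of Gaussian blobs with distinct peak intensities over a zero
#' background, plus i.i.d. Gaussian noise. Labels assign each voxel to the
#' blob with the largest (noise-free) contribution where that contribution
#' exceeds a floor of 0.05, and 0 (background) elsewhere; the result has
#' up to nBlobs regions plus background. Deterministic per seed.
#'
#' @param spec a [PhantomSpec].
#' @return list with \code{volume} ([Volume]) and \code{labels}
#'   ([LabelVolume]).
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    blobs <- drawBlobs(spec)
    ph <- phantomAt(blobs, gridPoints(spec@shape))
    noise <- if (spec@noiseSigma > 0)
      stats::rnorm(prod(spec@shape), 0, spec@noiseSigma) else 0
    list(volume = Volume(array(ph$intensity + noise, spec@shape)),
         labels = LabelVolume(array(ph$labels, spec@shape)))
  })
}

#' Generate a smooth, fold-free ground-truth displacement field
#'
#' Gaussian-smoothed white-noise vector field rescaled so the maximum
#' voxel displacement norm equals \code{amplitude}. The result is checked
#' to be orientation-preserving (zero folded voxels); if folds appear the
#' amplitude is reduced by 25 percent with a warning, up to 5 retries.
#'
#' @param shape integer(3) grid dimensions.
#' @param amplitude max displacement norm in voxels (>= 0).
#' @param sigma Gaussian smoothing width in voxels.
#' @param seed integer.
#' @return a fold-free [DisplacementField].
#' @export
makeGroundTruthWarp <- function(shape, amplitude, sigma, seed) {
  shape <- as.integer(shape)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (amplitude == 0) return(zeroField(shape))
  withSeed(seed, {
    raw <- array(stats::rnorm(prod(shape) * 3L), c(shape, 3L))
    for (c in 1:3)
      raw[, , , c] <- gaussianSmooth3D(array(raw[, , , c], shape), sigma)
    nrm <- sqrt(raw[, , , 1]^2 + raw[, , , 2]^2 + raw[, , , 3]^2)
    amp <- amplitude
    for (try in 1:5) {
      u <- DisplacementField(raw * (amp / max(nrm)))
      if (countFoldings(jacobianDeterminant(u)) == 0L) return(u)
      warning(sprintf(
        "warp of amplitude %.3g folds space; retrying at %.3g", amp,
        0.75 * amp))
      amp <- 0.75 * amp
    }
    stop("cannot achieve a fold-free field after 5 retries")
  })
}

# Fixed-point inversion of W(x) = x + u(x): find v with y + v(y) = W^-1(y),
# i.e. v(y) = -u(y + v(y)). Converges for smooth fields with max |grad u|
# below 1 (guaranteed in practice by the fold-free check on u).
invertField <- function(field, iters = 60L, tol = 1e-4) {
  d <- dim(field@vectors)[1:3]
  g <- gridPoints(d)
  comps <- lapply(1:3, function(c) Volume(array(field@vectors[, , , c], d)))
  v <- matrix(0, nrow(g), 3L)
  for (it in seq_len(iters)) {
    pts <- g + v
    vn <- -cbind(sampleTrilinear(comps[[1]], pts),
                 sampleTrilinear(comps[[2]], pts),
                 sampleTrilinear(comps[[3]], pts))
    if (max(abs(vn - v)) < tol) { v <- vn; break }
    v <- vn
  }
  DisplacementField(array(v, c(d, 3L)), field@spacing)
}

#' Generate a registration test pair with known ground truth
#'
#' The target is the (analytic) phantom; the ground-truth field lives on
#' the target grid in the pull-back convention, i.e. sampling the source
#' at x + truth(x) recovers the target. The source is produced by
#' evaluating the analytic phantom at the inverse-warped coordinates, so
#' no resampling error enters the fixture. Labels follow the same
#' geometry with argmax (nearest-region) assignment. Noise is added after
#' warping, independently to target and source, mimicking scan/rescan
#' noise rather than interpolated noise.
#'
#' @param spec a [PhantomSpec].
#' @return list with \code{target}, \code{source} ([Volume]), \code{truth}
#'   ([DisplacementField] on the target grid), \code{targetLabels},
#'   \code{sourceLabels} ([LabelVolume]).
#' @export
makeRegistrationPair <- function(spec) {
  validObject(spec)
  shape <- spec@shape
  truth <- makeGroundTruthWarp(shape, spec@warpAmplitude, spec@warpSigma,
                               spec@seed + 1L)
  withSeed(spec@seed, {
    blobs <- drawBlobs(spec)
    g <- gridPoints(shape)
    tgt <- phantomAt(blobs, g)
    inv <- invertField(truth)
    src <- phantomAt(blobs, g + matrix(inv@vectors, ncol = 3L))
    n <- prod(shape)
    tNoise <- if (spec@noiseSigma > 0) stats::rnorm(n, 0, spec@noiseSigma)
      else 0
    sNoise <- if (spec@noiseSigma > 0) stats::rnorm(n, 0, spec@noiseSigma)
      else 0
    list(target = Volume(array(tgt$intensity + tNoise, shape)),
         source = Volume(array(src$intensity + sNoise, shape)),
         truth = truth,
         targetLabels = LabelVolume(array(tgt$labels, shape)),
         sourceLabels = LabelVolume(array(src$labels, shape)))
  })
}

#' Mean endpoint error between two displacement fields
#'
#' Mean over (optionally masked) voxels of the Euclidean norm of the
#' vector difference, in voxel units.
#'
#' @param est,truth [DisplacementField]s on the same grid.
#' @param mask optional logical 3-D array selecting voxels (e.g. label
#'   foreground).
#' @return mean endpoint error in voxels.
#' @export
endpointError <- function(est, truth, mask = NULL) {
  stopifnot(all(dim(est) == dim(truth)))
  d <- est@vectors - truth@vectors
  n <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  if (!is.null(mask)) mean(n[mask]) else mean(n)
}
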