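# Shared fixtures and independent oracles for the test suite.

# Pure-R scalar trilinear interpolation, written independently of the
# package's compiled kernel (border-replicate clamp, 1-based coords).
refTrilinear <- function(arr, p) {
  d <- dim(arr)
  p <- pmin(pmax(p, 1), d)
  f0 <- pmin(floor(p), pmax(d - 1, 1))
  fr <- p - f0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- min(f0[1] + dx, d[1]); iy <- min(f0[2] + dy, d[2])
    iz <- min(f0[3] + dz, d[3])
    w <- (if (dx) fr[1] else 1 - fr[1]) *
         (if (dy) fr[2] else 1 - fr[2]) *
         (if (dz) fr[3] else 1 - fr[3])
    acc <- acc + w * arr[ix, iy, iz]
  }
  acc
}

# Independent restricted-energy recomputation for one block and labeling,
# going through the R reference routes (dataTermVoxel, binaryTerm) rather
# than the compiled tables.
refBlockEnergy <- function(target, source, field, lo, hi, delta, cfg,
                           labels) {
  d <- dim(target)
  bdim <- hi - lo + 1L
  lab <- array(as.integer(labels), bdim)
  e <- 0
  for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
    l <- lab[x - lo[1] + 1L, y - lo[2] + 1L, z - lo[3] + 1L]
    e <- e + dataTermVoxel(target, source, field, c(x, y, z), cfg, l, delta)
  }
  inB <- function(v) all(v >= lo) && all(v <= hi)
  uAt <- function(v) field@vectors[v[1], v[2], v[3], ]
  labAt <- function(v) lab[v[1] - lo[1] + 1L, v[2] - lo[2] + 1L,
                           v[3] - lo[3] + 1L]
  for (z in lo[3]:hi[3]) for (y in lo[2]:hi[2]) for (x in lo[1]:hi[1]) {
    v <- c(x, y, z)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + s
      if (w[ax] < 1L || w[ax] > d[ax]) next
      if (inB(w)) {
        if (s == 1L)            # count inner pairs once
          e <- e + cfg@alpha * binaryTerm(uAt(v), uAt(w), delta,
                                          labAt(v), labAt(w), cfg@gamma)
      } else {
        e <- e + cfg@alpha * binaryTerm(uAt(v), uAt(w), delta,
                                        labAt(v), 0, cfg@gamma)
      }
    }
  }
  e
}

# Random submodular MoveTerms on a small block, built the way the method
# builds them: pairwise tables from random displacement vectors through
# the binary term (gamma = 2 guarantees submodularity), random unaries.
randomMoveTerms <- function(bdim = c(2L, 2L, 2L), seed = 1) {
  set.seed(seed)
  n <- prod(bdim)
  lin <- array(seq_len(n), bdim)
  pv <- integer(0); pw <- integer(0)
  for (ax in 1:3) {
    if (bdim[ax] < 2L) next
    ia <- slice.index(lin, ax) < bdim[ax]
    ib <- slice.index(lin, ax) > 1L
    pv <- c(pv, lin[ia]); pw <- c(pw, lin[ib])
  }
  k <- length(pv)
  ax <- sample(1:3, k, replace = TRUE)
  delta <- matrix(0, k, 3)
  delta[cbind(seq_len(k), ax)] <- sample(c(-1, 1), k, TRUE) * runif(k, 0.1, 2)
  uv <- matrix(runif(3 * k, -5, 5), k, 3)
  uw <- matrix(runif(3 * k, -5, 5), k, 3)
  tab <- t(vapply(seq_len(k), function(i) c(
    binaryTerm(uv[i, ], uw[i, ], delta[i, ], 0, 0, 2),
    binaryTerm(uv[i, ], uw[i, ], delta[i, ], 0, 1, 2),
    binaryTerm(uv[i, ], uw[i, ], delta[i, ], 1, 0, 2),
    binaryTerm(uv[i, ], uw[i, ], delta[i, ], 1, 1, 2)), numeric(4)))
  alpha <- runif(1, 0.05, 0.5)
  new("MoveTerms", lo = c(1L, 1L, 1L), hi = as.integer(bdim),
      unary = matrix(runif(2 * n, 0, 1), n, 2),
      pairsInner = cbind(pv, pw), innerTerms = alpha * tab,
      boundaryIdx = integer(0), boundaryTerms = matrix(0, 0, 2),
      delta = c(1, 0, 0), alpha = alpha, gamma = 2)
}

# Exhaustive minimum of the block-restricted energy over all labelings.
bruteForceMin <- function(terms) {
  n <- nrow(terms@unary)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code)[1:n])
    e <- moveEnergy(terms, lab)
    if (e < best) best <- e
  }
  best
}

# Small noiseless phantom pair for fast optimizer tests.
smallPair <- function(shape = c(16L, 16L, 16L), amp = 1, seed = 7,
                      noise = 0) {
  makeRegistrationPair(phantomSpec(shape = shape, nBlobs = 2,
    blobSigmaRange = c(2.5, 4), noiseSigma = noise, warpAmplitude = amp,
    warpSigma = 5, seed = seed))
}

# The standard 48^3 test world used by the acceptance suite: registered
# once per seed and cached, because several criteria interrogate the same
# runs (recovery quality, fold fraction, energy trail, determinism).
.acceptanceCache <- new.env(parent = emptyenv())

acceptanceRun <- function(seed, nWorkers = 1L) {
  key <- sprintf("s%d_w%d", seed, nWorkers)
  if (!is.null(.acceptanceCache[[key]])) return(.acceptanceCache[[key]])
  spec <- phantomSpec(seed = seed)   # 48^3, amp 3, sigma 8, noise 2% of DR
  pair <- makeRegistrationPair(spec)
  cfg <- registrationConfig(nWorkers = nWorkers)
  res <- registerVolumes(pair$target, pair$source, cfg)
  out <- list(pair = pair, res = res)
  .acceptanceCache[[key]] <- out
  out
}
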