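# The iterative move-making loop. Each sweep tries the 6 signed axis moves
# delta in {+-epsilon e1, +-epsilon e2, +-epsilon e3}; for each move every
# block of the partition is given the chance to update, with the optimal
# binary labeling found exactly by an s-t minimum cut (igraph::max_flow on
# the standard submodular quadratic-pseudo-Boolean construction). Blocks
# are processed in two checkerboard colors so that no two concurrently
# solved blocks are 6-adjacent; within a color the jobs are independent,
# which makes the worker-pool path bit-identical to serial execution.

#' Partition a voxel grid into axis-aligned blocks
#'
#' Tiles the grid with boxes of extent \code{blockSize}, shifted by
#' \code{offset} (components in [0, blockSize)); border blocks may be
#' smaller but never empty. The blocks are pairwise disjoint and cover the
#' grid.
#'
#' @param shape integer(3) grid dimensions.
#' @param blockSize integer, or integer(3), per-axis extent (>= 1).
#' @param offset integer, or integer(3), shift applied before tiling.
#' @return a [BlockPartition].
#' @export
partitionBlocks <- function(shape, blockSize, offset = c(0L, 0L, 0L)) {
  shape <- as.integer(shape)
  blockSize <- as.integer(rep_len(blockSize, 3L))
  offset <- as.integer(rep_len(offset, 3L))
  if (any(blockSize < 1L)) stop("blockSize components must be >= 1")
  if (any(offset < 0L) || any(offset >= blockSize))
    stop("offset must lie in [0, blockSize)")
  cuts <- lapply(1:3, function(ax) {
    s <- if (offset[ax] + 1L <= shape[ax])
      unique(c(1L, seq.int(offset[ax] + 1L, shape[ax], blockSize[ax])))
    else 1L
    s <- s[s <= shape[ax]]
    e <- c(s[-1L] - 1L, shape[ax])
    cbind(s, e)
  })
  grid <- expand.grid(i = seq_len(nrow(cuts[[1]])),
                      j = seq_len(nrow(cuts[[2]])),
                      k = seq_len(nrow(cuts[[3]])))
  lo <- cbind(cuts[[1]][grid$i, 1L], cuts[[2]][grid$j, 1L],
              cuts[[3]][grid$k, 1L])
  hi <- cbind(cuts[[1]][grid$i, 2L], cuts[[2]][grid$j, 2L],
              cuts[[3]][grid$k, 2L])
  idx <- cbind(grid$i, grid$j, grid$k)
  storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  storage.mode(idx) <- "integer"
  new("BlockPartition", lo = lo, hi = hi, index = idx,
      blockSize = blockSize, offset = offset, shape = shape)
}

# Checkerboard color (0/1) per block: parity of the block-grid index sum.
# Face-adjacent blocks always differ in exactly one ordinal, hence in
# color, so no 6-neighbor voxel pair spans two blocks of the same color.
blockColors <- function(partition) {
  as.integer(rowSums(partition@index) %% 2L)
}

#' Solve the optimal binary move for one block by minimal graph cut
#'
#' Builds the standard s-t graph of the submodular binary labeling problem
#' (after folding boundary terms into the unaries) and runs an exact
#' max-flow/min-cut (igraph). The returned labeling globally minimizes the
#' block-restricted move energy over all 2^|V'| labelings. Since the
#' all-zero labeling is feasible, the energy delta is never positive; ties
#' with the null move (within 1e-9) keep the null labeling to guarantee
#' termination.
#'
#' @param terms a [MoveTerms].
#' @return list with \code{labels} (integer 0/1 per block voxel) and
#'   \code{energyDelta} (<= 0), the restricted-energy change vs all-zero.
#' @export
solveBlockMove <- function(terms) {
  n <- nrow(terms@unary)
  u0 <- terms@unary[, 1L]
  u1 <- terms@unary[, 2L]
  if (length(terms@boundaryIdx) > 0) {
    add <- rowsum(terms@boundaryTerms, terms@boundaryIdx)
    ids <- as.integer(rownames(add))
    u0[ids] <- u0[ids] + add[, 1L]
    u1[ids] <- u1[ids] + add[, 2L]
  }
  if (nrow(terms@innerTerms) > 0) {
    A <- terms@innerTerms[, 1L]; B <- terms@innerTerms[, 2L]
    C <- terms@innerTerms[, 3L]; D <- terms@innerTerms[, 4L]
    cap <- B + C - A - D
    if (any(cap < -1e-9))
      stop("non-submodular pairwise table: refusing to cut")
    cap <- pmax(cap, 0)
    pv <- terms@pairsInner[, 1L]
    pw <- terms@pairsInner[, 2L]
    adj1 <- rowsum(C - A, pv)       # unary_v(1) += C - A
    u1[as.integer(rownames(adj1))] <-
      u1[as.integer(rownames(adj1))] + adj1[, 1L]
    adj2 <- rowsum(D - C, pw)       # unary_w(1) += D - C
    u1[as.integer(rownames(adj2))] <-
      u1[as.integer(rownames(adj2))] + adj2[, 1L]
  } else {
    cap <- numeric(0); pv <- integer(0); pw <- integer(0)
  }
  net <- u1 - u0
  s <- n + 1L; t <- n + 2L
  fromS <- which(net > 0)           # cost of label 1: cut when v on t-side
  toT <- which(net < 0)             # cost of label 0: cut when v on s-side
  keep <- cap > 0
  from <- c(rep(s, length(fromS)), toT, pv[keep])
  to <- c(fromS, rep(t, length(toT)), pw[keep])
  capacity <- c(net[fromS], -net[toT], cap[keep])
  labels <- integer(n)
  if (length(from) > 0 && length(fromS) > 0) {
    g <- igraph::make_empty_graph(n + 2L, directed = TRUE)
    g <- igraph::add_edges(g, rbind(from, to))
    fl <- igraph::max_flow(g, source = s, target = t, capacity = capacity)
    sink_side <- as.integer(fl$partition2)
    labels[sink_side[sink_side <= n]] <- 1L
  }
  e0 <- moveEnergy(terms, integer(n))
  e1 <- moveEnergy(terms, labels)
  delta <- e1 - e0
  if (delta > -1e-9) {              # tie or no gain: keep the null move
    labels <- integer(n)
    delta <- 0
  }
  list(labels = labels, energyDelta = delta)
}

#' Apply an accepted labeling to the displacement field
#'
#' Inside the block, u'(v) = u(v) + L(v) * delta; unchanged elsewhere.
#'
#' @param field a [DisplacementField].
#' @param lo,hi integer(3), 1-based inclusive block corners.
#' @param labels integer 0/1 vector in block order (x fastest).
#' @param delta numeric(3) move vector.
#' @return the updated [DisplacementField].
#' @export
applyLabeling <- function(field, lo, hi, labels, delta) {
  bdim <- hi - lo + 1L
  if (length(labels) != prod(bdim)) stop("labeling does not match block")
  v <- field@vectors
  lab <- array(as.numeric(labels), bdim)
  for (c in 1:3) {
    if (delta[c] == 0) next
    v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c] <-
      v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], c] + lab * delta[c]
  }
  # hot path: labels and delta are finite by construction, skip the full
  # revalidation a fresh DisplacementField() would trigger
  field@vectors <- v
  field
}

# One block job: build terms, solve. Pure function of (images, u, block,
# delta, cfg) - safe to run concurrently for non-adjacent blocks.
blockJob <- function(target, source, field, lo, hi, delta, cfg) {
  terms <- buildMoveTerms(target, source, field, lo, hi, delta, cfg)
  solveBlockMove(terms)
}

# Run the jobs of one checkerboard color. Results are computed (optionally
# in a fork-based worker pool), then applied sequentially in block order,
# so the final field is identical to serial execution regardless of the
# pool's interleaving.
runColor <- function(target, source, field, part, blocksIdx, delta, cfg) {
  jobs <- lapply(blocksIdx, function(b)
    list(lo = part@lo[b, ], hi = part@hi[b, ]))
  worker <- function(j) blockJob(target, source, field, j$lo, j$hi, delta, cfg)
  res <- if (cfg@nWorkers > 1L)
    parallel::mclapply(jobs, worker, mc.cores = cfg@nWorkers)
  else lapply(jobs, worker)
  for (k in seq_along(res)) {
    if (inherits(res[[k]], "try-error") || !is.list(res[[k]]))
      stop("worker failure while processing a block")
  }
  accepted <- 0L; flips <- 0L; deltaSum <- 0
  for (k in seq_along(res)) {
    r <- res[[k]]
    if (r$energyDelta < 0) {
      field <- applyLabeling(field, jobs[[k]]$lo, jobs[[k]]$hi,
                             r$labels, delta)
      accepted <- accepted + 1L
      flips <- flips + sum(r$labels)
      deltaSum <- deltaSum + r$energyDelta
    }
  }
  list(field = field, accepted = accepted, flips = flips,
       deltaSum = deltaSum)
}

#' Run one full sweep (all 6 signed axis moves over all blocks)
#'
#' The block offset alternates with sweep parity (0 vs blockSize/2 per
#' axis) so subregion boundaries move between sweeps. Energy before/after
#' is recomputed from scratch; per-block incremental deltas are accumulated
#' in \code{deltaSum} for bookkeeping checks. The total energy is
#' non-increasing: every block either keeps the null move or strictly
#' lowers its restricted energy.
#'
#' @param target,source [Volume] pair at the current level.
#' @param field current [DisplacementField].
#' @param cfg a [RegistrationConfig].
#' @param sweepIndex 1-based sweep counter (drives offset alternation).
#' @param level pyramid level index recorded in the report.
#' @return list with \code{field} and a one-row \code{report} data.frame.
#' @export
sweepOnce <- function(target, source, field, cfg, sweepIndex = 1L,
                      level = 1L) {
  d <- dim(target)
  bs <- pmin(rep_len(cfg@blockSize, 3L), d)
  off <- if (sweepIndex %% 2L == 0L) bs %/% 2L else rep(0L, 3L)
  off <- off %% bs
  part <- partitionBlocks(d, bs, off)
  colors <- blockColors(part)
  eBefore <- totalEnergy(target, source, field, cfg)
  accepted <- 0L; flips <- 0L; deltaSum <- 0
  moves <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * cfg@epsilon
  for (m in seq_len(nrow(moves))) {
    delta <- moves[m, ]
    for (col in c(0L, 1L)) {
      idx <- which(colors == col)
      if (length(idx) == 0L) next
      r <- runColor(target, source, field, part, idx, delta, cfg)
      field <- r$field
      accepted <- accepted + r$accepted
      flips <- flips + r$flips
      deltaSum <- deltaSum + r$deltaSum
    }
  }
  eAfter <- totalEnergy(target, source, field, cfg)
  if (!is.finite(eAfter))
    stop("divergent (non-finite) energy after sweep ", sweepIndex)
  report <- data.frame(level = level, sweep = sweepIndex,
                       movesAttempted = 6L * nrow(part@lo),
                       movesAccepted = accepted, changedVoxels = flips,
                       energyBefore = eBefore, energyAfter = eAfter,
                       deltaSum = deltaSum)
  list(field = field, report = report)
}

#' Register a source volume to a target volume
#'
#' Coarse-to-fine move-making registration: both inputs are optionally
#' presmoothed (\code{presmoothSigma}), a multiresolution pyramid is
#' built, and at every level sweeps of blockwise graph-cut moves run until
#' a full sweep accepts zero label flips, the relative energy decrease of
#' a sweep falls below \code{convergenceTol}, or
#' \code{maxSweepsPerLevel} is reached; the field is upsampled (and its
#' voxel-unit vectors rescaled) between levels. The procedure is
#' deterministic given the inputs and the configuration. No affine
#' pre-registration is performed: initialization comes from \code{init} or
#' the identity transform.
#'
#' @param target,source [Volume] pair on the same grid.
#' @param cfg a [RegistrationConfig].
#' @param init optional initial [DisplacementField] on the finest grid.
#' @return a [RegistrationResult].
#' @examples
#' pair <- makeRegistrationPair(phantomSpec(shape = c(16, 16, 16),
#'   nBlobs = 2, warpAmplitude = 0, seed = 1))
#' cfg <- registrationConfig(nLevels = 1, blockSize = 8,
#'   maxSweepsPerLevel = 2)
#' res <- registerVolumes(pair$target, pair$source, cfg)
#' @export
registerVolumes <- function(target, source, cfg = registrationConfig(),
                            init = NULL) {
  validObject(cfg)
  if (!all(dim(target) == dim(source)))
    stop("target and source must share a grid")
  if (cfg@presmoothSigma > 0) {
    target <- Volume(gaussianSmooth3D(volData(target), cfg@presmoothSigma),
                     spacing(target))
    source <- Volume(gaussianSmooth3D(volData(source), cfg@presmoothSigma),
                     spacing(source))
  }
  pyr <- buildPyramid(target, source, cfg@nLevels)
  nL <- length(pyr@target)
  if (!is.null(init)) {
    if (!all(dim(init) == dim(target)))
      stop("init field must match the finest grid")
    fields <- list(init)
    for (k in seq_len(nL - 1L))
      fields <- c(list(downsampleField(fields[[1L]])), fields)
    u <- fields[[1L]]
  } else {
    u <- zeroField(dim(pyr@target[[1L]]), pyr@target[[1L]]@spacing)
  }
  reports <- NULL
  for (lev in seq_len(nL)) {
    tgt <- pyr@target[[lev]]
    src <- pyr@source[[lev]]
    if (lev > 1L) u <- upsampleField(u, dim(tgt))
    sweepIdx <- 0L
    while (sweepIdx < cfg@maxSweepsPerLevel) {
      sweepIdx <- sweepIdx + 1L
      r <- sweepOnce(tgt, src, u, cfg, sweepIdx, level = lev)
      u <- r$field
      reports <- rbind(reports, r$report)
      if (r$report$changedVoxels == 0L) break
      rel <- (r$report$energyBefore - r$report$energyAfter) /
        max(abs(r$report$energyBefore), .Machine$double.eps)
      if (rel < cfg@convergenceTol) break
    }
  }
  if (nL >= 1L && !all(dim(u) == dim(target)))
    u <- upsampleField(u, dim(target))  # unreachable guard
  new("RegistrationResult", field = u,
      reports = if (is.null(reports)) data.frame() else reports,
      config = cfg)
}
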