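# Data term (windowed PCC / SSD), diffusion regularizer, and construction
# of the per-move unary/pairwise energy tables with a submodularity guard.
#
# The move energy for a block V' and step delta is
#   sum_{v in V'} phi_v(L(v)) + sum_{(v,w)} phi_vw(L(v), L(w)),
# where phi_v is the (unweighted) data term of the voxel under label L(v)
# and phi_vw = alpha * ||(u(v)+L(v) delta) - (u(w)+L(w) delta)||^gamma.
# Pairs with one endpoint outside the block keep that endpoint at label 0.

#' Pearson correlation coefficient of two intensity patches
#'
#' Plain Pearson correlation, with the convention that a patch of zero
#' variance (a flat window carries no matching evidence) yields 0 rather
#' than NaN.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @examples
#' pcc(c(1, 2, 3, 4), c(2, 4, 6, 8))  # exact linear relation: 1
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("patches must have equal length")
  if (length(a) < 2L) stop("patches must have length >= 2")
  va <- a - mean(a)
  vb <- b - mean(b)
  da <- sum(va * va)
  db <- sum(vb * vb)
  if (da <= 1e-24 || db <= 1e-24) return(0)
  r <- sum(va * vb) / sqrt(da * db)
  max(-1, min(1, r))
}

# Integer offsets of the spherical window of radius r (includes origin).
windowOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g <- g[rowSums(g^2) <= r^2, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

#' Per-voxel data term
#'
#' For metric "pcc": one half of (1 - PCC) between the target patch on the
#' spherical window omega(v, r) (truncated at image borders) and the source
#' sampled at w + u(v) + label * delta for every window node w. The window
#' is assumed rigid with respect to the centre voxel: the centre's
#' displacement applies to the whole patch. For metric "ssd": the squared
#' intensity difference at v alone.
#'
#' This is the reference (pure R) route; the optimizer uses an equivalent
#' compiled kernel, and the two are cross-checked in the test suite.
#'
#' @param target a [Volume].
#' @param source a [Volume].
#' @param field a [DisplacementField] on the target grid (NULL = identity).
#' @param v integer(3), 1-based voxel coordinate.
#' @param cfg a [RegistrationConfig] (radius, metric).
#' @param label 0 or 1; adds label * delta to the centre displacement.
#' @param delta numeric(3) candidate move (only used when label = 1).
#' @return data term in [0, 1] for "pcc"; non-negative for "ssd".
#' @export
dataTermVoxel <- function(target, source, field = NULL, v, cfg,
                          label = 0, delta = c(0, 0, 0)) {
  v <- as.numeric(v)
  u <- if (is.null(field)) c(0, 0, 0) else field@vectors[v[1], v[2], v[3], ]
  off <- u + label * delta
  if (cfg@metric == "ssd") {
    d <- target@data[v[1], v[2], v[3]] - sampleTrilinear(source, v + off)
    return(d * d)
  }
  w <- sweep(windowOffsets(cfg@radius), 2L, v, "+")
  d <- dim(target@data)
  keep <- w[, 1] >= 1 & w[, 2] >= 1 & w[, 3] >= 1 &
    w[, 1] <= d[1] & w[, 2] <= d[2] & w[, 3] <= d[3]
  w <- w[keep, , drop = FALSE]
  tp <- target@data[w]
  sp <- sampleTrilinear(source, sweep(w, 2L, off, "+"))
  0.5 * (1 - pcc(tp, sp))
}

#' Diffusion regularizer for one neighbor pair
#'
#' @param uv,uw numeric(3) displacement vectors of two 6-neighbors.
#' @param gamma exponent, must be >= 2 (submodularity of the induced
#'   binary terms is only guaranteed for gamma >= 2).
#' @return ||uv - uw||^gamma.
#' @export
regularizerPair <- function(uv, uw, gamma) {
  if (gamma < 2) stop("gamma must be >= 2 (submodularity requirement)")
  sum((uv - uw)^2)^(gamma / 2)
}

#' Pairwise (binary) term of the move energy
#'
#' @param uv,uw numeric(3) current displacements of a 6-neighbor pair.
#' @param delta numeric(3) candidate move.
#' @param lv,lw labels in {0, 1}.
#' @param gamma exponent >= 2.
#' @return ||(uv + lv delta) - (uw + lw delta)||^gamma.
#' @export
binaryTerm <- function(uv, uw, delta, lv, lw, gamma) {
  regularizerPair(uv + lv * delta, uw + lw * delta, gamma)
}

# ||d||^gamma for rows of a matrix
rowNormPow <- function(d, gamma) {
  (d[, 1]^2 + d[, 2]^2 + d[, 3]^2)^(gamma / 2)
}

#' Diffusion regularization energy of a whole field
#'
#' Sum of ||u(v) - u(w)||^gamma over all unordered 6-neighbor pairs.
#'
#' @param field a [DisplacementField].
#' @param gamma exponent >= 2.
#' @return non-negative total.
#' @export
regEnergy <- function(field, gamma) {
  if (gamma < 2) stop("gamma must be >= 2 (submodularity requirement)")
  v <- field@vectors
  d <- dim(v)[1:3]
  tot <- 0
  for (ax in 1:3) {
    if (d[ax] < 2L) next
    n <- d[ax]
    ia <- switch(ax,
      list(2:n, TRUE, TRUE), list(TRUE, 2:n, TRUE), list(TRUE, TRUE, 2:n))
    ib <- switch(ax,
      list(1:(n - 1), TRUE, TRUE), list(TRUE, 1:(n - 1), TRUE),
      list(TRUE, TRUE, 1:(n - 1)))
    dif <- v[ia[[1]], ia[[2]], ia[[3]], , drop = FALSE] -
      v[ib[[1]], ib[[2]], ib[[3]], , drop = FALSE]
    dif <- matrix(dif, ncol = 3L)
    tot <- tot + sum(rowNormPow(dif, gamma))
  }
  tot
}

#' Total registration energy f(u) = D(u) + alpha R(u)
#'
#' Recomputed from scratch: the data term is summed over every voxel of the
#' target grid at the current displacement, the regularizer over all
#' 6-neighbor pairs.
#'
#' @param target,source [Volume] pair.
#' @param field a [DisplacementField] on the target grid.
#' @param cfg a [RegistrationConfig].
#' @return the scalar objective value.
#' @export
totalEnergy <- function(target, source, field, cfg) {
  met <- if (cfg@metric == "ssd") 1L else 0L
  de <- cpp_data_energy(target@data, dim(target@data), source@data,
                        dim(source@data), field@vectors,
                        windowOffsets(cfg@radius), met)
  de + cfg@alpha * regEnergy(field, cfg@gamma)
}

# Linear indices of a block's voxels laid out x-fastest, as an array for
# slicing out neighbor pairs.
blockLinearIndex <- function(bdim) array(seq_len(prod(bdim)), bdim)

#' Build the unary/pairwise energy tables for one block and one move
#'
#' Unary entries are the (unweighted) per-voxel data terms for labels 0/1;
#' inner pairwise tables (both endpoints in the block) and boundary tables
#' (outside endpoint fixed at label 0) are alpha-weighted diffusion terms.
#' delta must be axis-aligned (+/- epsilon along one coordinate axis).
#'
#' @param target,source [Volume] pair at the current pyramid level.
#' @param field current [DisplacementField].
#' @param lo,hi integer(3), 1-based inclusive block corners.
#' @param delta numeric(3), +/- epsilon times a coordinate unit vector.
#' @param cfg a [RegistrationConfig].
#' @return a [MoveTerms].
#' @export
buildMoveTerms <- function(target, source, field, lo, hi, delta, cfg) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (sum(delta != 0) != 1L)
    stop("delta must be axis-aligned (a single non-zero component)")
  met <- if (cfg@metric == "ssd") 1L else 0L
  unary <- cpp_block_unary(target@data, dim(target@data), source@data,
                           dim(source@data), field@vectors,
                           lo - 1L, hi - 1L, as.numeric(delta),
                           windowOffsets(cfg@radius), met)
  u <- field@vectors
  d <- dim(u)[1:3]
  bdim <- hi - lo + 1L
  ub <- u[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  lin <- blockLinearIndex(bdim)
  g <- cfg@gamma
  a <- cfg@alpha

  # inner pairs along each axis; pair (v, w) with d = u(v) - u(w):
  # phi00 = phi11 = ||d||^g, phi01 = ||d - delta||^g, phi10 = ||d + delta||^g
  pv <- integer(0); pw <- integer(0); dm <- NULL
  for (ax in 1:3) {
    n <- bdim[ax]
    if (n < 2L) next
    ia <- switch(ax, list(1:(n - 1), TRUE, TRUE),
                 list(TRUE, 1:(n - 1), TRUE), list(TRUE, TRUE, 1:(n - 1)))
    ib <- switch(ax, list(2:n, TRUE, TRUE),
                 list(TRUE, 2:n, TRUE), list(TRUE, TRUE, 2:n))
    pv <- c(pv, as.vector(lin[ia[[1]], ia[[2]], ia[[3]]]))
    pw <- c(pw, as.vector(lin[ib[[1]], ib[[2]], ib[[3]]]))
    dif <- matrix(ub[ia[[1]], ia[[2]], ia[[3]], , drop = FALSE] -
                    ub[ib[[1]], ib[[2]], ib[[3]], , drop = FALSE], ncol = 3L)
    dm <- rbind(dm, dif)
  }
  if (is.null(dm)) dm <- matrix(0, 0, 3)
  A <- a * rowNormPow(dm, g)
  B <- a * rowNormPow(sweep(dm, 2L, delta, "-"), g)
  C <- a * rowNormPow(sweep(dm, 2L, delta, "+"), g)
  inner <- cbind(A, B, C, A)
  colnames(inner) <- c("phi00", "phi01", "phi10", "phi11")

  # boundary pairs: block voxel v with 6-neighbor w outside the block but
  # inside the grid; contributes phi(lv, 0) with d = u(v) - u(w)
  bIdx <- integer(0); bD <- NULL
  for (ax in 1:3) {
    for (side in c(-1L, 1L)) {
      face <- if (side < 0) lo[ax] else hi[ax]
      out <- face + side
      if (out < 1L || out > d[ax]) next
      sl <- function(pos) switch(ax,
        list(pos, lo[2]:hi[2], lo[3]:hi[3]),
        list(lo[1]:hi[1], pos, lo[3]:hi[3]),
        list(lo[1]:hi[1], lo[2]:hi[2], pos))
      si <- sl(face)
      so <- sl(out)
      uin <- matrix(u[si[[1]], si[[2]], si[[3]], , drop = FALSE], ncol = 3L)
      uout <- matrix(u[so[[1]], so[[2]], so[[3]], , drop = FALSE], ncol = 3L)
      li <- switch(ax,
        lin[if (side < 0) 1L else bdim[1], , ],
        lin[, if (side < 0) 1L else bdim[2], ],
        lin[, , if (side < 0) 1L else bdim[3]])
      bIdx <- c(bIdx, as.vector(li))
      bD <- rbind(bD, uin - uout)
    }
  }
  if (is.null(bD)) bD <- matrix(0, 0, 3)
  bT <- cbind(a * rowNormPow(bD, g),
              a * rowNormPow(sweep(bD, 2L, delta, "+"), g))
  colnames(bT) <- c("phi00", "phi10")

  new("MoveTerms", lo = lo, hi = hi, unary = unary,
      pairsInner = cbind(pv, pw), innerTerms = inner,
      boundaryIdx = bIdx, boundaryTerms = bT,
      delta = as.numeric(delta), alpha = a, gamma = g)
}

#' Evaluate the block-restricted move energy of a labeling
#'
#' Sums the stored tables under the given 0/1 labeling: unary data terms,
#' inner pairwise terms, and boundary terms (outside label fixed at 0).
#' Used both by the optimizer (energy deltas) and as the bookkeeping route
#' checked against globally recomputed energies.
#'
#' @param terms a [MoveTerms].
#' @param labels integer vector of 0/1, one per block voxel (x fastest).
#' @return the restricted energy value.
#' @export
moveEnergy <- function(terms, labels) {
  labels <- as.integer(labels)
  e <- sum(terms@unary[cbind(seq_along(labels), labels + 1L)])
  if (nrow(terms@innerTerms) > 0) {
    lv <- labels[terms@pairsInner[, 1]]
    lw <- labels[terms@pairsInner[, 2]]
    col <- 1L + 2L * lv + lw  # (0,0)->1 (0,1)->2 (1,0)->3 (1,1)->4
    e <- e + sum(terms@innerTerms[cbind(seq_along(col), col)])
  }
  if (length(terms@boundaryIdx) > 0) {
    lv <- labels[terms@boundaryIdx]
    e <- e + sum(terms@boundaryTerms[cbind(seq_along(lv), lv + 1L)])
  }
  e
}
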