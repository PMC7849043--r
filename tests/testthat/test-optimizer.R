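test_that("block partitions tile the grid under size and offset choices", {
  p <- partitionBlocks(c(32L, 32L, 32L), 16L)
  expect_equal(nrow(p@lo), 8L)
  expect_true(all(p@hi - p@lo + 1L == 16L))
  # remainder blocks at the border
  p2 <- partitionBlocks(c(20L, 20L, 20L), 16L)
  expect_equal(nrow(p2@lo), 8L)
  expect_setequal(unique(as.vector(p2@hi - p2@lo + 1L)), c(16L, 4L))
  # shifted tiling splits a single block in two
  p3 <- partitionBlocks(c(16L, 16L, 16L), 16L, offset = c(8L, 0L, 0L))
  expect_equal(nrow(p3@lo), 2L)
  expect_equal(sort((p3@hi - p3@lo + 1L)[, 1]), c(8L, 8L))
  # property: disjoint cover for random shapes and offsets
  set.seed(13)
  for (i in 1:20) {
    shape <- sample(3:25, 3, replace = TRUE)
    bs <- sample(2:9, 1)
    off <- sample(0:(bs - 1), 1)
    pp <- partitionBlocks(shape, bs, off)
    seen <- array(0L, shape)
    for (b in seq_len(nrow(pp@lo)))
      seen[pp@lo[b, 1]:pp@hi[b, 1], pp@lo[b, 2]:pp@hi[b, 2],
           pp@lo[b, 3]:pp@hi[b, 3]] <-
        seen[pp@lo[b, 1]:pp@hi[b, 1], pp@lo[b, 2]:pp@hi[b, 2],
             pp@lo[b, 3]:pp@hi[b, 3]] + 1L
    expect_true(all(seen == 1L))
  }
  expect_error(partitionBlocks(c(8L, 8L, 8L), 4L, offset = 4L), "offset")
})

test_that("checkerboard colors never put 6-adjacent blocks together", {
  for (shape in list(c(32L, 32L, 32L), c(20L, 17L, 23L))) {
    p <- partitionBlocks(shape, 8L, 3L)
    cols <- gcdeform:::blockColors(p)
    expect_setequal(unique(cols), c(0L, 1L))
    for (a in seq_len(nrow(p@lo))) for (b in seq_len(nrow(p@lo))) {
      if (a >= b) next
      touching <- sum(abs(p@index[a, ] - p@index[b, ])) == 1L
      if (touching) expect_true(cols[a] != cols[b])
    }
  }
})

test_that("graph-cut block moves match exhaustive enumeration", {
  # decoupled problem: zero pairwise tables, independent unary argmin
  n <- 8L
  terms <- new("MoveTerms", lo = c(1L, 1L, 1L), hi = c(2L, 2L, 2L),
               unary = cbind(rep(0.2, n), c(0.5, 0.1, 0.5, 0.1, 0.5, 0.1,
                                            0.5, 0.1)),
               pairsInner = matrix(integer(0), 0, 2),
               innerTerms = matrix(0, 0, 4), boundaryIdx = integer(0),
               boundaryTerms = matrix(0, 0, 2), delta = c(1, 0, 0),
               alpha = 0, gamma = 2)
  r <- solveBlockMove(terms)
  expect_identical(r$labels, rep(c(0L, 1L), 4))
  expect_equal(r$energyDelta, 4 * (0.1 - 0.2))
  # random submodular instances vs brute force over all 256 labelings
  for (seed in 1:40) {
    tm <- randomMoveTerms(seed = seed)
    sol <- solveBlockMove(tm)
    expect_lte(sol$energyDelta, 0)                       # null-move safety
    expect_equal(moveEnergy(tm, sol$labels),
                 bruteForceMin(tm), tolerance = 1e-9)
  }
  # a non-submodular table is refused, never silently cut
  bad <- randomMoveTerms(seed = 1)
  bad@innerTerms[1, ] <- c(5, 0.1, 0.1, 5)
  expect_error(solveBlockMove(bad), "submodular")
})

test_that("labelings are applied per Eq-style pointwise update", {
  u <- zeroField(c(6, 6, 6))
  lo <- c(2L, 2L, 2L); hi <- c(4L, 5L, 4L)
  n <- prod(hi - lo + 1L)
  # all-zero labeling leaves the field untouched
  expect_identical(
    fieldVectors(applyLabeling(u, lo, hi, integer(n), c(0.5, 0, 0))),
    fieldVectors(u))
  # all-one labeling adds delta inside the block only
  u1 <- applyLabeling(u, lo, hi, rep(1L, n), c(0.5, 0, 0))
  expect_equal(u1@vectors[3, 3, 3, 1], 0.5)
  expect_equal(sum(u1@vectors != 0), n)
  # mixed labeling: elementwise recomputation
  set.seed(2)
  lab <- sample(0:1, n, replace = TRUE)
  um <- applyLabeling(u, lo, hi, lab, c(0, -0.5, 0))
  labArr <- array(lab, hi - lo + 1L)
  for (k in seq(1, n, by = 7)) {
    idx <- arrayInd(k, hi - lo + 1L)
    v <- idx + lo - 1L
    expect_equal(um@vectors[v[1], v[2], v[3], 2], -0.5 * labArr[k])
  }
})

test_that("sweeps never increase the energy and fix identical images", {
  pair <- smallPair(shape = c(12L, 12L, 12L), amp = 1, seed = 5)
  cfg <- registrationConfig(blockSize = 6L, presmoothSigma = 0,
                            nLevels = 1L)
  # identical images: the identity is already optimal, zero flips
  r <- sweepOnce(pair$target, pair$target, zeroField(c(12, 12, 12)), cfg)
  expect_equal(r$report$changedVoxels, 0L)
  expect_equal(r$report$energyAfter, r$report$energyBefore)
  # source exactly one move step away: energy strictly decreases in a sweep
  shifted <- warpVolume(pair$target, DisplacementField(
    array(rep(c(cfg@epsilon, 0, 0), each = 12^3), c(12, 12, 12, 3))))
  r2 <- sweepOnce(pair$target, shifted, zeroField(c(12, 12, 12)), cfg)
  expect_lt(r2$report$energyAfter, r2$report$energyBefore)
  expect_gt(r2$report$changedVoxels, 0L)
  # incremental bookkeeping matches the global recomputation
  expect_equal(r2$report$energyAfter - r2$report$energyBefore,
               r2$report$deltaSum, tolerance = 1e-8)
})

test_that("registration is deterministic, serial and parallel alike", {
  pair <- smallPair(shape = c(16L, 16L, 16L), amp = 1.2, seed = 9,
                    noise = 0.01)
  cfg <- registrationConfig(blockSize = 8L, nLevels = 2L,
                            maxSweepsPerLevel = 4L)
  res1 <- registerVolumes(pair$target, pair$source, cfg)
  res1b <- registerVolumes(pair$target, pair$source, cfg)
  expect_identical(fieldVectors(resultField(res1)),
                   fieldVectors(resultField(res1b)))
  cfg4 <- registrationConfig(blockSize = 8L, nLevels = 2L,
                             maxSweepsPerLevel = 4L, nWorkers = 2L)
  res4 <- registerVolumes(pair$target, pair$source, cfg4)
  expect_identical(fieldVectors(resultField(res1)),
                   fieldVectors(resultField(res4)))
  # the energy trail is monotone within every level
  rep <- sweepReports(res1)
  for (lev in unique(rep$level)) {
    e <- rep[rep$level == lev, ]
    expect_true(all(e$energyAfter <= e$energyBefore + 1e-9))
    if (nrow(e) > 1)
      expect_true(all(diff(e$energyAfter) <= 1e-9))
  }
})

test_that("degenerate configurations behave as contracts say", {
  pair <- smallPair(shape = c(10L, 10L, 10L), amp = 0.5, seed = 3)
  # zero sweeps returns the initial field unchanged
  cfg0 <- registrationConfig(nLevels = 1L, maxSweepsPerLevel = 0L)
  res <- registerVolumes(pair$target, pair$source, cfg0)
  expect_equal(max(abs(fieldVectors(resultField(res)))), 0)
  init <- DisplacementField(array(0.25, c(10, 10, 10, 3)))
  res2 <- registerVolumes(pair$target, pair$source, cfg0, init = init)
  expect_identical(fieldVectors(resultField(res2)), fieldVectors(init))
  expect_error(registerVolumes(pair$target, pair$source, cfg0,
                               init = zeroField(c(8, 8, 8))),
               "finest grid")
  expect_error(registerVolumes(pair$target,
                               Volume(array(1, c(8, 8, 8)))),
               "share a grid")
})
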