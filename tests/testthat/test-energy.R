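test_that("pcc matches closed forms and is affine-invariant", {
  expect_equal(pcc(c(1, 2, 3, 4), c(2, 4, 6, 8)), 1.0)
  a <- c(0.3, 1.7, -0.2, 5)
  expect_equal(pcc(a, a), 1.0)
  expect_equal(pcc(a, -a), -1.0)
  expect_equal(pcc(a, rep(2, 4)), 0)        # zero-variance convention
  expect_error(pcc(a, c(1, 2)), "equal length")
  expect_error(pcc(1, 2), "length >= 2")
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pcc(x, y), pcc(y, x))
    s <- runif(1, 0.1, 10); o <- rnorm(1)
    expect_equal(pcc(x, s * y + o), pcc(x, y), tolerance = 1e-12)
  }
})

test_that("the windowed data term hits its closed-form anchors", {
  set.seed(3)
  arr <- array(rnorm(6^3), c(6, 6, 6))
  T <- Volume(arr)
  cfg <- registrationConfig(presmoothSigma = 0)
  # identical target and source, u = 0: perfect correlation, term 0
  expect_equal(dataTermVoxel(T, T, NULL, c(3, 3, 3), cfg), 0)
  # negated source: PCC -1, term 1
  expect_equal(dataTermVoxel(T, Volume(-arr), NULL, c(3, 3, 3), cfg), 1)
  # constant source window vs non-constant target: PCC 0, term 0.5
  expect_equal(dataTermVoxel(T, Volume(array(2, c(6, 6, 6))), NULL,
                             c(3, 3, 3), cfg), 0.5)
  # ssd metric is the squared centre difference
  cfgS <- registrationConfig(metric = "ssd", presmoothSigma = 0)
  S <- Volume(arr + 0.25)
  expect_equal(dataTermVoxel(T, S, NULL, c(4, 4, 4), cfgS), 0.0625)
  # data term lies in [0,1] for pcc at borders and everywhere
  for (v in list(c(1, 1, 1), c(6, 6, 6), c(1, 3, 6))) {
    dt <- dataTermVoxel(T, Volume(arr[ , , 6:1]), NULL, v, cfg)
    expect_gte(dt, 0); expect_lte(dt, 1)
  }
})

test_that("regularizer and binary term follow the diffusion closed forms", {
  expect_equal(regularizerPair(c(1, 2, 3), c(1, 2, 3), 2), 0)
  expect_equal(regularizerPair(c(1, 0, 0), c(0, 0, 0), 2), 1)
  expect_equal(regularizerPair(c(3, 4, 0), c(0, 0, 0), 2), 25)
  expect_error(regularizerPair(c(1, 0, 0), c(0, 0, 0), 1.5), "gamma")
  # direct substitution table for uv = uw = 0, delta = e1, gamma 2
  z <- c(0, 0, 0); d <- c(1, 0, 0)
  expect_equal(binaryTerm(z, z, d, 0, 0, 2), 0)
  expect_equal(binaryTerm(z, z, d, 1, 1, 2), 0)
  expect_equal(binaryTerm(z, z, d, 1, 0, 2), 1)
  expect_equal(binaryTerm(z, z, d, 0, 1, 2), 1)
})

test_that("binary terms are submodular for gamma >= 2 (random sweep)", {
  set.seed(99)
  for (i in 1:1000) {
    uv <- runif(3, -5, 5); uw <- runif(3, -5, 5)
    delta <- c(0, 0, 0)
    delta[sample(1:3, 1)] <- sample(c(-1, 1), 1) * runif(1, 0.05, 3)
    g <- sample(c(2, 4), 1)
    p00 <- binaryTerm(uv, uw, delta, 0, 0, g)
    p01 <- binaryTerm(uv, uw, delta, 0, 1, g)
    p10 <- binaryTerm(uv, uw, delta, 1, 0, g)
    p11 <- binaryTerm(uv, uw, delta, 1, 1, g)
    expect_lte(p00 + p11, p01 + p10 + 1e-9)
  }
})

test_that("move-term tables agree with an independent restricted-energy oracle", {
  set.seed(21)
  pair <- smallPair(shape = c(10L, 10L, 10L), amp = 1, seed = 4)
  cfg <- registrationConfig(alpha = 0.3, gamma = 2, presmoothSigma = 0)
  u <- DisplacementField(array(0.3 * rnorm(10^3 * 3), c(10, 10, 10, 3)))
  # interior and border blocks, all six move directions among the cases
  cases <- list(
    list(lo = c(3L, 3L, 3L), hi = c(5L, 5L, 5L), delta = c(0.5, 0, 0)),
    list(lo = c(1L, 1L, 1L), hi = c(3L, 2L, 4L), delta = c(0, -0.5, 0)),
    list(lo = c(8L, 6L, 7L), hi = c(10L, 8L, 9L), delta = c(0, 0, 0.5)))
  for (cs in cases) {
    terms <- buildMoveTerms(pair$target, pair$source, u, cs$lo, cs$hi,
                            cs$delta, cfg)
    expect_true(all(terms@unary >= 0 & terms@unary <= 1))
    # Eq-style submodularity of every stored inner row
    expect_true(all(terms@innerTerms[, 1] + terms@innerTerms[, 4] <=
                    terms@innerTerms[, 2] + terms@innerTerms[, 3] + 1e-9))
    n <- prod(cs$hi - cs$lo + 1L)
    for (rep in 1:4) {
      lab <- sample(0:1, n, replace = TRUE)
      expect_equal(moveEnergy(terms, lab),
                   refBlockEnergy(pair$target, pair$source, u, cs$lo,
                                  cs$hi, cs$delta, cfg, lab),
                   tolerance = 1e-6)
    }
  }
  expect_error(buildMoveTerms(pair$target, pair$source, u, c(1L, 1L, 1L),
                              c(3L, 3L, 3L), c(0.5, 0.5, 0), cfg),
               "axis-aligned")
})

test_that("identical images prefer the null move on every labeling", {
  set.seed(8)
  arr <- array(rnorm(8^3), c(8, 8, 8))
  T <- Volume(arr)
  cfg <- registrationConfig(alpha = 0.1, presmoothSigma = 0)
  terms <- buildMoveTerms(T, T, zeroField(c(8, 8, 8)), c(4L, 4L, 4L),
                          c(5L, 5L, 5L), c(0.5, 0, 0), cfg)
  e0 <- moveEnergy(terms, integer(8))
  for (code in 1:255) {
    lab <- as.integer(intToBits(code)[1:8])
    expect_gte(moveEnergy(terms, lab), e0)
  }
})

test_that("total energy decomposes into data term plus weighted regularizer", {
  set.seed(31)
  pair <- smallPair(shape = c(8L, 8L, 8L), amp = 0.8, seed = 12)
  cfg <- registrationConfig(alpha = 0.15, gamma = 2, presmoothSigma = 0)
  u <- DisplacementField(array(0.2 * rnorm(8^3 * 3), c(8, 8, 8, 3)))
  ref <- 0
  for (z in 1:8) for (y in 1:8) for (x in 1:8)
    ref <- ref + dataTermVoxel(pair$target, pair$source, u, c(x, y, z), cfg)
  ref <- ref + cfg@alpha * regEnergy(u, cfg@gamma)
  expect_equal(totalEnergy(pair$target, pair$source, u, cfg), ref,
               tolerance = 1e-9)
  # a constant field has zero regularization energy
  cst <- DisplacementField(array(0.7, c(8, 8, 8, 3)))
  expect_equal(regEnergy(cst, 2), 0)
})
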