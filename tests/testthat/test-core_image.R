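test_that("trilinear sampling reproduces grid values and clamps at borders", {
  set.seed(42)
  v <- Volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)))
  # every grid node exactly (machine epsilon)
  g <- as.matrix(expand.grid(1:5, 1:4, 1:3))
  expect_equal(sampleTrilinear(v, g), v@data[g], tolerance = 1e-15)
  # midpoint of two nodes along x with values a, b -> (a + b)/2
  expect_equal(sampleTrilinear(v, c(1.5, 2, 2)),
               (v@data[1, 2, 2] + v@data[2, 2, 2]) / 2)
  # far out of bounds clamps to the first voxel
  expect_equal(sampleTrilinear(v, c(-5, -5, -5)), v@data[1, 1, 1])
  expect_equal(sampleTrilinear(v, c(100, 100, 100)), v@data[5, 4, 3])
  expect_error(sampleTrilinear(v, c(NA, 1, 1)), "invalid coordinate")
  expect_error(sampleTrilinear(v, c(Inf, 1, 1)), "invalid coordinate")
})

test_that("warpVolume matches the identity and an independent interpolation oracle", {
  set.seed(7)
  src <- Volume(array(rnorm(64), c(4, 4, 4)))
  # zero field is the identity, bitwise
  expect_identical(volData(warpVolume(src, zeroField(c(4, 4, 4)))),
                   volData(src))
  # unit shift on a volume linear in x raises every interior value by the slope
  lin <- Volume(array(rep(2 * (1:6), 36), c(6, 6, 6)))
  u1 <- DisplacementField(array(rep(c(1, 0, 0), each = 216), c(6, 6, 6, 3)))
  w <- warpVolume(lin, u1)
  expect_equal(volData(w)[1:5, , ], volData(lin)[1:5, , ] + 2)
  # half-voxel shift against a hand-rolled scalar oracle, every voxel
  uh <- zeroField(c(4, 4, 4))
  uh@vectors[, , , 1] <- 0.5
  w2 <- warpVolume(src, uh)
  for (z in 1:4) for (y in 1:4) for (x in 1:4)
    expect_equal(volData(w2)[x, y, z],
                 refTrilinear(volData(src), c(x + 0.5, y, z)),
                 tolerance = 1e-12)
  # grid mismatch is an error
  expect_error(warpVolume(src, zeroField(c(3, 3, 3))), NA)  # field defines grid
})

test_that("label warping is nearest-neighbor with border replication", {
  lab <- LabelVolume(array(rep(1:4, each = 16), c(4, 4, 4)))
  expect_identical(volData(warpLabels(lab, zeroField(c(4, 4, 4)))),
                   volData(lab))
  # sub-half-voxel displacement rounds back to the same node
  u <- zeroField(c(4, 4, 4)); u@vectors[, , , 1] <- 0.4
  expect_identical(volData(warpLabels(lab, u)), volData(lab))
  # integer shift along z moves labels with border replication
  uz <- zeroField(c(4, 4, 4)); uz@vectors[, , , 3] <- 1
  wl <- volData(warpLabels(lab, uz))
  expect_identical(wl[, , 1:3], volData(lab)[, , 2:4])
  expect_identical(wl[, , 4], volData(lab)[, , 4])
  # no interpolation: only input label values appear
  set.seed(1)
  ur <- DisplacementField(array(runif(4^3 * 3, -2, 2), c(4, 4, 4, 3)))
  expect_true(all(volData(warpLabels(lab, ur)) %in% 1:4))
})

test_that("pyramid construction follows the ceil(n/2) recurrence", {
  # one level is a no-op pyramid
  v <- Volume(array(rnorm(8^3), c(8, 8, 8)))
  p1 <- buildPyramid(v, v, 1)
  expect_identical(volData(p1@target[[1]]), volData(v))
  # constant volumes stay constant at every level (border-renormalized kernel)
  cst <- Volume(array(3.5, c(16, 16, 16)))
  p <- buildPyramid(cst, cst, 3)
  for (k in 1:3) expect_equal(range(volData(p@target[[k]])), c(3.5, 3.5))
  # 16^3 over three levels gives 16, 8, 4
  expect_equal(t(vapply(p@target, dim, integer(3)))[, 1], c(4L, 8L, 16L))
  # ceil recurrence for odd and prime sizes
  for (n in c(5L, 9L, 13L, 21L, 33L)) {
    vol <- Volume(array(rnorm(n * n * 8), c(n, n, 8)))
    pn <- buildPyramid(vol, vol, 2)
    expect_identical(dim(pn@target[[1]]), as.integer(ceiling(c(n, n, 8) / 2)))
  }
  # too many levels errors and names the limiting axis
  thin <- Volume(array(rnorm(16 * 16 * 4), c(16, 16, 4)))
  expect_error(buildPyramid(thin, thin, 3), "axis z")
})

test_that("field upsampling scales voxel-unit vectors and round-trips", {
  # zero field stays zero at any scale
  z8 <- upsampleField(zeroField(c(4, 4, 4)), c(8, 8, 8))
  expect_equal(max(abs(fieldVectors(z8))), 0)
  # constant (1,1,1) at 4^3 becomes (2,2,2) at 8^3
  c4 <- DisplacementField(array(1, c(4, 4, 4, 3)))
  c8 <- upsampleField(c4, c(8, 8, 8))
  expect_equal(range(fieldVectors(c8)), c(2, 2))
  # a linear ramp interpolates to the analytic ramp at interior fine nodes
  r4 <- zeroField(c(4, 4, 4))
  r4@vectors[, , , 1] <- array(rep(0.2 * (1:4), 16), c(4, 4, 4))
  r8 <- upsampleField(r4, c(8, 8, 8))
  # coarse coord of fine node f is (f+1)/2; component scales by 2
  for (f in 1:7)
    expect_equal(r8@vectors[f, 4, 4, 1], 2 * 0.2 * (f + 1) / 2,
                 tolerance = 1e-12)
  # upsample then decimate recovers the field at shared nodes
  set.seed(11)
  u <- DisplacementField(array(rnorm(4^3 * 3), c(4, 4, 4, 3)))
  back <- gcdeform:::downsampleField(upsampleField(u, c(8, 8, 8)))
  expect_equal(fieldVectors(back), fieldVectors(u), tolerance = 1e-6)
  # non-adjacent level shapes are rejected
  expect_error(upsampleField(u, c(13, 8, 8)), "ratio")
  expect_error(upsampleField(u, c(4, 4, 4)), "ratio")
})

test_that("containers validate their invariants", {
  expect_error(Volume(array(c(1, NA, 3, 4, 5, 6, 7, 8), c(2, 2, 2))),
               "finite")
  expect_error(Volume(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(LabelVolume(array(0.5, c(2, 2, 2))), "integer")
  expect_error(DisplacementField(array(1, c(2, 2, 2, 2))), "trailing")
  expect_error(registrationConfig(gamma = 1.5), "submodularity")
  expect_error(registrationConfig(epsilon = 0), "epsilon")
  expect_error(registrationConfig(metric = "mi"), "metric")
})
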