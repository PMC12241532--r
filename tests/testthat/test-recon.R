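test_that("reconstruction of an all-zero scan is an all-zero volume", {
  g <- patchGeom(1.6, 128L)
  zero <- RFScan(g, array(0, c(16, 16, 128)))
  expect_true(all(voxels(kspaceReconstruct(zero)) == 0))
  tv <- timeReversal(zero, ReconParams(nIter = 2L))
  expect_true(all(voxels(tv) == 0))
})

test_that("k-space reconstruction is linear and validates its sound speed", {
  g <- patchGeom(1.6, 128L)
  scan <- forwardProject(matrix(c(0.8, 0.8, 1.2, 1), 1), g)
  v1 <- voxels(kspaceReconstruct(scan))
  scan2 <- RFScan(g, 2 * traces(scan))
  expect_equal(voxels(kspaceReconstruct(scan2)), 2 * v1, tolerance = 1e-12)
  expect_error(kspaceReconstruct(scan, c = -1), "parameter error")
})

test_that("point sources reconstruct at their true position", {
  g <- patchGeom(3.2, 256L, c0 = 1500)
  for (src in list(c(1.6, 1.5, 2.0), c(1.1, 2.0, 1.2), c(2.2, 0.9, 2.8))) {
    scan <- forwardProject(matrix(c(src, 1), 1), g)
    vol <- kspaceReconstruct(scan, c = 1500)
    err <- abs(argmaxPos(vol) - src) / spacing(vol)
    expect_true(all(err <= 1))
  }
})

test_that("iterative time reversal refines toward the k-space solution on lossless data", {
  g <- patchGeom(1.6, 128L, c0 = 1500)
  scan <- forwardProject(matrix(c(0.8, 0.8, 1.0, 1), 1), g)
  ks <- kspaceReconstruct(scan, c = 1500)
  tv <- timeReversal(scan, ReconParams(c = 1500, nIter = 3L, nonneg = FALSE))
  res <- volInfo(tv)$residuals
  expect_gte(length(res), 1L)
  expect_true(all(diff(res) <= 1e-9))       # non-increasing residuals
  expect_lt(relL2(voxels(tv), voxels(ks)), 0.2)
})

test_that("attenuation compensation restores the point-source amplitude", {
  g <- patchGeom(3.2, 256L, c0 = 1500)
  att <- AttenuationModel(0.5, 1.1)
  pt <- matrix(c(1.6, 1.5, 2.0, 1), 1)
  lossless <- timeReversal(forwardProject(pt, g),
                           ReconParams(c = 1500, nIter = 3L))
  comped <- timeReversal(forwardProject(pt, g, atten = att),
                         ReconParams(c = 1500, atten = att, nIter = 3L))
  expect_equal(max(voxels(comped)), max(voxels(lossless)), tolerance = 0.2)
})

test_that("sharpness is zero iff constant, homogeneous, and reduced by blurring", {
  expect_identical(sharpness(Volume(array(3, c(5, 5, 5)), 0.1)), 0)
  set.seed(5)
  v <- array(runif(6^3), c(6, 6, 6))
  expect_equal(sharpness(Volume(2.5 * v, 0.1)),
               2.5 * sharpness(Volume(v, 0.1)), tolerance = 1e-12)
  ## sharp-edged cube vs its blurred copy (blurring redistributes the
  ## gradient across axes, where the Euclidean norm is subadditive)
  v <- array(0, c(12, 12, 12)); v[5:9, 5:9, 5:9] <- 1
  blur <- v
  shift <- function(a, d, s) {
    i <- pmin(pmax(seq_len(12) + s, 1), 12)
    switch(d, a[i, , ], a[, i, ], a[, , i])
  }
  for (d in 1:3) blur <- (shift(blur, d, -1) + blur + shift(blur, d, 1)) / 3
  expect_gt(sharpness(Volume(v, 0.1)), sharpness(Volume(blur, 0.1)))
})

test_that("autofocus honours tie-breaks and singleton grids", {
  g <- patchGeom(1.6, 128L)
  zero <- RFScan(g, array(0, c(16, 16, 128)))
  af <- autofocusSoS(zero, c(1500, 1480, 1520))
  expect_identical(af$cBest, 1480)          # all-zero scores: smallest wins
  expect_identical(nrow(af$scores), 3L)
  one <- autofocusSoS(zero, 1540)
  expect_identical(one$cBest, 1540)
  expect_error(autofocusSoS(zero, numeric(0)), "non-empty")
})

test_that("autofocus recovers the simulated sound speed", {
  fx <- vesselFixture(3)
  scan <- forwardProject(fx$mu, fx$geom)
  af <- autofocusSoS(scan, seq(1480, 1600, by = 10))
  expect_lte(abs(af$cBest - 1540), 10)
})

test_that("profile FWHM measurement is exact on a Gaussian peak", {
  x <- seq(-2, 2, by = 0.05)
  sigma <- 0.23
  prof <- exp(-x^2 / (2 * sigma^2))
  v <- array(rep(prof, times = 9), c(length(x), 3, 3))
  vol <- Volume(v, c(0.05, 0.1, 0.1), origin = c(-2, 0, 0))
  expect_equal(lateralFWHM(vol, 1), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.02)
})

test_that("trilinear resampling preserves constants and linear ramps", {
  const <- Volume(array(4, c(8, 8, 8)), 0.1)
  rc <- resampleVolume(const, 0.05)
  expect_true(all(abs(voxels(rc) - 4) < 1e-12))
  ramp <- Volume(array(rep(seq_len(8), times = 64), c(8, 8, 8)), 0.1)
  rr <- resampleVolume(ramp, 0.04)
  d <- dim(voxels(rr))
  xs <- (seq_len(d[1]) - 1) * 0.04 / 0.1 + 1
  expect_equal(voxels(rr)[, 1, 1], xs, tolerance = 1e-9)
})
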