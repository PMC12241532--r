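test_that("fluence model matches its analytic form", {
  vol <- Volume(array(1, c(41, 41, 41)), 0.05)
  ## identity limit: no depth decay, beam much wider than the volume
  pf <- applyFluence(vol, IlluminationModel(beamDiameter = 1e6, muEff = 0))
  expect_equal(voxels(pf), voxels(vol), tolerance = 1e-9)
  ## on-axis voxel at z = 1/muEff decays to e^-1
  pf2 <- applyFluence(vol, IlluminationModel(beamDiameter = 2, muEff = 1))
  expect_equal(voxels(pf2)[21, 21, 21], exp(-1), tolerance = 1e-12)
  ## lateral radius beamDiameter/2 gives the 1/e^2 intensity factor
  expect_equal(voxels(pf2)[41, 21, 1], exp(-2), tolerance = 1e-12)
})

test_that("broadband arrival lands at the analytic sample index", {
  ## 5 mm depth at 1500 m/s sampled at 60 MHz: sample 200 (0-based)
  g <- ScanGeometry(extentX = 1.1, extentY = 1.1, step = 0.1, nBeams = 11L,
                    nSamples = 512L, c0 = 1500)
  scan <- forwardProject(matrix(c(0.5, 0.5, 5, 1), 1), g, bandpass = FALSE)
  expect_identical(which.max(abs(traces(scan)[6, 6, ])), 201L)
})

test_that("spherical spreading gives 1/sqrt(2) amplitude at 5 mm lateral offset", {
  g <- ScanGeometry(extentX = 10.1, extentY = 1.1, step = 0.1, nBeams = 101L,
                    nSamples = 1024L, c0 = 1500)
  scan <- forwardProject(matrix(c(0.5, 0.5, 5, 1), 1), g)
  onax <- max(abs(traces(scan)[6, 6, ]))
  offax <- max(abs(traces(scan)[56, 6, ]))
  expect_equal(offax / onax, 1 / sqrt(2), tolerance = 0.05)
})

test_that("the forward projection is linear and rejects sources at the sensor plane", {
  g <- tinyGeom(256L)
  s1 <- forwardProject(matrix(c(0.1, 0.1, 2, 1), 1), g)
  s2 <- forwardProject(matrix(c(0.1, 0.1, 2, 2), 1), g)
  expect_identical(2 * traces(s1), traces(s2))
  expect_error(forwardProject(matrix(c(0.1, 0.1, 0, 1), 1), g),
               "geometry error")
})

test_that("the forward model is laterally translation covariant", {
  g <- ScanGeometry(extentX = 2.0, extentY = 0.5, step = 0.1, nBeams = 4L,
                    nSamples = 256L, c0 = 1500)
  sA <- forwardProject(matrix(c(0.6, 0.2, 1.5, 1), 1), g)
  sB <- forwardProject(matrix(c(0.8, 0.2, 1.5, 1), 1), g)  # +2 pitches in x
  expect_equal(traces(sA)[3:16, , ], traces(sB)[5:18, , ], tolerance = 1e-12)
})

test_that("cross-correlation delays between detectors match path-length differences", {
  g <- ScanGeometry(extentX = 3.2, extentY = 0.2, step = 0.1, nBeams = 32L,
                    nSamples = 512L, c0 = 1500)
  set.seed(3)
  for (k in 1:5) {
    src <- c(runif(1, 0.8, 2.4), 0.1, runif(1, 1.5, 3.5))
    scan <- forwardProject(matrix(c(src, 1), 1), g)
    i1 <- 6L; i2 <- 26L
    t1 <- traces(scan)[i1, 1, ]; t2 <- traces(scan)[i2, 1, ]
    lags <- -80:80
    cc <- vapply(lags, function(l) {
      idx <- seq_len(512)
      ok <- idx + l >= 1 & idx + l <= 512
      sum(t1[idx[ok]] * t2[idx[ok] + l])
    }, numeric(1))
    measured <- lags[which.max(cc)]
    r1 <- sqrt(((i1 - 1) * 0.1 - src[1])^2 + (0 - src[2])^2 + src[3]^2)
    r2 <- sqrt(((i2 - 1) * 0.1 - src[1])^2 + (0 - src[2])^2 + src[3]^2)
    predicted <- (r2 - r1) / 1500 * 60e6 / 1000
    expect_lt(abs(measured - predicted), 1)
  }
})

test_that("sensor inhomogeneity applies per-detector gains", {
  g <- tinyGeom(64L)
  scan <- randomScan(g, 4)
  ones <- SensitivityMap(matrix(1, 2, 2))
  expect_identical(traces(applySensorInhomogeneity(scan, ones)),
                   traces(scan))
  gmap <- SensitivityMap(matrix(c(0.5, 1, 1, 1), 2, 2))
  out <- applySensorInhomogeneity(scan, gmap)
  expect_equal(traces(out)[1, 1, ], 0.5 * traces(scan)[1, 1, ])
  expect_identical(traces(out)[2, , ], traces(scan)[2, , ])
  expect_error(applySensorInhomogeneity(scan, SensitivityMap(matrix(1, 3, 2))),
               "shape")
})

test_that("the factory sensitivity map shows exactly three vertical band plateaus", {
  g <- patchGeom(3.2, 64L)
  map <- defaultSensitivityMap(g)
  scan <- RFScan(g, array(1, c(32, 32, 64)))
  out <- applySensorInhomogeneity(scan, map)
  colEnergy <- apply(traces(out)^2, 1, mean)
  expect_identical(length(unique(round(colEnergy, 9))), 3L)
  expect_equal(max(gains(map)), 1)
})

test_that("additive noise hits the requested SNR and is seed-deterministic", {
  g <- tinyGeom(512L)
  scan <- RFScan(g, array(sin(2 * pi * 5e6 * (0:511) / 60e6),
                          dim = c(2, 2, 512)))
  expect_identical(traces(addNoise(scan, Inf, 1)), traces(scan))
  n1 <- addNoise(scan, 20, 11)
  n2 <- addNoise(scan, 20, 11)
  expect_identical(traces(n1), traces(n2))
  noise <- traces(n1) - traces(scan)
  psig <- mean(traces(scan)^2)
  expect_equal(mean(noise^2), psig / 100, tolerance = 0.12)
  zero <- RFScan(g, array(0, c(2, 2, 512)))
  expect_error(addNoise(zero, 20, 1), "all-zero")
})
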