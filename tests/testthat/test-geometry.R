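test_that("the stepped-scan schedule reproduces the system's acquisition arithmetic", {
  g <- ScanGeometry()                       # 19 x 16 mm, 0.1 mm, 32 beams, 100 Hz
  s <- scanSchedule(g)
  expect_identical(nALines(s), 190L * 160L)
  expect_identical(alineRate(s), 3200)
  expect_identical(nPulses(s), 950L)
  expect_equal(scanDuration(s), 9.5)
  expect_equal(scanDuration(s, rounded = TRUE), 10)
})

test_that("a single-line scan has a trivial schedule", {
  s <- scanSchedule(ScanGeometry(extentX = 1, extentY = 1, step = 1,
                                 nBeams = 1L, prf = 1, fs = 60e6,
                                 nSamples = 16L, bandLo = 2e6, bandHi = 15e6))
  expect_identical(nALines(s), 1L)
  expect_equal(scanDuration(s), 1)
})

test_that("schedule invariants hold across a parameter grid", {
  for (ext in c(1.2, 2.5, 6.4)) for (nb in c(1L, 3L, 8L)) for (prf in c(20, 100)) {
    g <- ScanGeometry(extentX = ext, extentY = 2.0, step = 0.1, nBeams = nb,
                      prf = prf, nSamples = 64L)
    s <- scanSchedule(g)
    n <- gridDims(g)
    expect_identical(nALines(s), as.integer(n[1] * n[2]))
    expect_identical(alineRate(s), nb * prf)
    expect_identical(nPulses(s), as.integer(ceiling(nALines(s) / nb)))
    expect_equal(scanDuration(s), nPulses(s) / prf)
  }
})

test_that("invalid geometries are rejected", {
  expect_error(ScanGeometry(extentX = 1.05, step = 0.1), "not an integer multiple")
  expect_error(ScanGeometry(extentX = 0.2, extentY = 0.2, nBeams = 32L),
               "nBeams")
  expect_error(ScanGeometry(bandLo = 16e6, bandHi = 15e6), "bandLo < bandHi")
  expect_error(ScanGeometry(bandHi = 40e6), "fs/2")
  expect_error(ScanGeometry(step = -0.1), "positive")
})

test_that("disassemble/assemble is a bit-exact round trip", {
  g <- ScanGeometry(extentX = 0.7, extentY = 0.5, step = 0.1, nBeams = 3L,
                    nSamples = 32L)
  scan <- randomScan(g, seed = 42)
  blocks <- disassembleScan(scan)
  expect_identical(traces(assembleScan(blocks, g)), traces(scan))
})

test_that("block delivery order does not matter", {
  g <- ScanGeometry(extentX = 0.7, extentY = 0.5, step = 0.1, nBeams = 3L,
                    nSamples = 32L)
  scan <- randomScan(g, seed = 7)
  blocks <- disassembleScan(scan)
  set.seed(1)
  shuffled <- blocks[sample(length(blocks))]
  expect_identical(traces(assembleScan(shuffled, g)), traces(scan))
})

test_that("assembly is bijective over random scans", {
  g <- ScanGeometry(extentX = 0.4, extentY = 0.3, step = 0.1, nBeams = 2L,
                    nSamples = 8L)
  for (seed in 1:5) {
    scan <- randomScan(g, seed)
    expect_identical(traces(assembleScan(disassembleScan(scan), g)),
                     traces(scan))
  }
  ## a 1 x 1 grid: the single block is the single trace
  g1 <- ScanGeometry(extentX = 0.1, extentY = 0.1, step = 0.1, nBeams = 1L,
                     nSamples = 8L)
  s1 <- randomScan(g1, 3)
  b <- disassembleScan(s1)
  expect_length(b, 1L)
  expect_identical(traces(assembleScan(b, g1)), traces(s1))
})

test_that("coverage violations name the first offending grid index", {
  g <- ScanGeometry(extentX = 0.4, extentY = 0.3, step = 0.1, nBeams = 2L,
                    nSamples = 8L)
  blocks <- disassembleScan(randomScan(g, 1))
  expect_error(assembleScan(blocks[-2], g), "coverage error.*3.*not covered")
  dup <- c(blocks, blocks[1])
  expect_error(assembleScan(dup, g), "coverage error.*1.*more than once")
})
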