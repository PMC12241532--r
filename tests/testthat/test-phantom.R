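test_that("the vessel-tree generator is a pure function of its seed", {
  a <- makeVesselTree(99)
  b <- makeVesselTree(99)
  expect_identical(absorbers(a), absorbers(b))
  expect_false(identical(absorbers(a), absorbers(makeVesselTree(100))))
})

test_that("absorber depths stay inside their declared layer ranges", {
  spec <- defaultLayerSpec()
  for (seed in c(1, 17, 203)) {
    a <- absorbers(makeVesselTree(seed, spec))
    for (layer in names(spec)) {
      z <- unlist(a[a$layer == layer, c("z1", "z2")])
      expect_true(all(z >= spec[[layer]]$depth[1] - 1e-9))
      expect_true(all(z <= spec[[layer]]$depth[2] + 1e-9))
    }
    expect_true(all(c("superficial", "mid", "deep") %in% a$layer))
  }
})

test_that("superficial vessels are thinner than deep vessels on average", {
  supR <- deepR <- numeric(0)
  for (seed in 1:200) {
    a <- absorbers(makeVesselTree(seed))
    supR <- c(supR, a$radius[a$layer == "superficial"])
    deepR <- c(deepR, a$radius[a$layer == "deep"])
  }
  expect_lt(mean(supR), mean(deepR))
  ## superficial web stays below 100 um diameter before branching shrinkage
  expect_lt(max(supR), 0.1)
})

test_that("layer specifications are validated", {
  expect_error(makeVesselTree(1, list()), "configuration error")
  expect_error(makeVesselTree(1, list(bogus = list(depth = c(0, 1)))),
               "configuration error")
  overlap <- list(superficial = list(depth = c(0.05, 1.0), radius = c(0.02, 0.05),
                                     n = 1L, length = c(1, 2), branchProb = 0),
                  mid = list(depth = c(0.5, 1.5), radius = c(0.06, 0.2),
                             n = 1L, length = c(1, 2), branchProb = 0))
  expect_error(makeVesselTree(1, overlap), "disjoint")
})

test_that("requested lateral clearance between trunks is honoured", {
  ls <- list(superficial = list(depth = c(0.9, 1.4), radius = c(0.1, 0.14),
                                n = 3L, length = c(1.0, 1.4),
                                branchProb = 0, motifProb = 0))
  for (seed in 1:8) {
    a <- absorbers(makeVesselTree(seed, ls,
                                  box = list(x = c(0.6, 2.6), y = c(0.6, 2.6)),
                                  minSeparation = 0.7))
    for (i in 1:2) for (j in (i + 1):3) {
      cl <- fptomo:::.minLateralClearance(
        c(a$x1[i], a$y1[i]), c(a$x2[i], a$y2[i]),
        matrix(c(a$x1[j], a$y1[j], a$x2[j], a$y2[j]), 1))
      expect_gte(cl, 0.7 - 1e-9)
    }
  }
})

test_that("rasterized sphere volume matches the analytic volume within 5%", {
  ph <- new("VesselPhantom", absorbers = data.frame(
    kind = "sphere", x1 = 1, y1 = 1, z1 = 1, x2 = 1, y2 = 1, z2 = 1,
    radius = 0.5, strength = 1, layer = "mid", vessel = 1L))
  vol <- rasterize(ph, 0.05, box = list(x = c(0, 2), y = c(0, 2), z = c(0, 2)))
  expect_equal(sum(voxels(vol)) * 0.05^3, 4 / 3 * pi * 0.5^3,
               tolerance = 0.05)
})

test_that("rasterization is linear in strength and zero for empty phantoms", {
  mk <- function(s) new("VesselPhantom", absorbers = data.frame(
    kind = "cylinder", x1 = 0.3, y1 = 0.5, z1 = 0.5, x2 = 0.8, y2 = 0.5,
    z2 = 0.5, radius = 0.15, strength = s, layer = "mid", vessel = 1L))
  box <- list(x = c(0, 1), y = c(0, 1), z = c(0, 1))
  v1 <- rasterize(mk(1), 0.05, box)
  v2 <- rasterize(mk(2), 0.05, box)
  expect_equal(voxels(v2), 2 * voxels(v1))
  empty <- new("VesselPhantom",
               absorbers = absorbers(mk(1))[integer(0), ])
  expect_true(all(voxels(rasterize(empty, 0.05, box)) == 0))
})

test_that("rasterization warns on clipping and unresolved radii", {
  ph <- new("VesselPhantom", absorbers = data.frame(
    kind = "sphere", x1 = 0.1, y1 = 0.5, z1 = 0.5, x2 = 0.1, y2 = 0.5,
    z2 = 0.5, radius = 0.3, strength = 1, layer = "mid", vessel = 1L))
  expect_warning(
    rasterize(ph, 0.1, box = list(x = c(0, 1), y = c(0, 1), z = c(0, 1))),
    "clipped")
  ph2 <- new("VesselPhantom", absorbers = data.frame(
    kind = "sphere", x1 = 0.5, y1 = 0.5, z1 = 0.5, x2 = 0.5, y2 = 0.5,
    z2 = 0.5, radius = 0.08, strength = 1, layer = "mid", vessel = 1L))
  expect_warning(
    rasterize(ph2, 0.1, box = list(x = c(0, 1), y = c(0, 1), z = c(0, 1))),
    "does not resolve")
})
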