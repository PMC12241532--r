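test_that("fluence compensation inverts the illumination model below the cap", {
  set.seed(8)
  vol <- Volume(array(runif(21^3, 0.5, 1), c(21, 21, 21)), 0.05)
  il <- IlluminationModel(beamDiameter = 4, muEff = 0.8)
  fwd <- applyFluence(vol, il)
  back <- fluenceCompensate(fwd, EnhanceParams(muEff = 0.8, compCap = 1e6),
                            beamDiameter = 4)
  expect_lt(max(abs(voxels(back) - voxels(vol))), 1e-6 * max(voxels(vol)))

  ## identity limit and capping
  ident <- fluenceCompensate(vol, EnhanceParams(muEff = 0),
                             beamDiameter = 1e9)
  expect_equal(voxels(ident), voxels(vol), tolerance = 1e-9)
  capped <- fluenceCompensate(fwd, EnhanceParams(muEff = 0.8, compCap = 2),
                              beamDiameter = 4)
  expect_lte(max(voxels(capped) / voxels(fwd)), 2 + 1e-12)
})

test_that("a uniform slab is flat in depth after compensation", {
  slab <- Volume(array(1, c(21, 21, 30)), 0.05)
  il <- IlluminationModel(beamDiameter = 30, muEff = 0.7)
  lit <- applyFluence(slab, il)
  fixed <- fluenceCompensate(lit, EnhanceParams(muEff = 0.7, compCap = 10),
                             beamDiameter = 30)
  prof <- apply(voxels(fixed), 3, mean)
  expect_lt(diff(range(prof)) / mean(prof), 0.1)
})

test_that("sigmoid normalization is a strictly monotone (0,1) map with midpoint 0.5", {
  v <- array(seq(-3, 3, length.out = 64), c(4, 4, 4))
  out <- voxels(sigmoidNormalize(Volume(v, 0.1), sigK = 2, sigX0 = 0.5))
  expect_true(all(out > 0 & out < 1))
  expect_false(is.unsorted(as.vector(out)))
  mid <- voxels(sigmoidNormalize(Volume(array(0.5, c(2, 2, 2)), 0.1),
                                 sigK = 3, sigX0 = 0.5))
  expect_equal(mid, array(0.5, c(2, 2, 2)))
  sat <- voxels(sigmoidNormalize(Volume(array(c(-1e3, 1e3), c(2, 2, 2)), 0.1),
                                 sigK = 1, sigX0 = 0))
  expect_equal(range(sat), c(0, 1), tolerance = 1e-12)
})

test_that("log compression maps the dynamic range onto [0, 1]", {
  v <- array(c(1, 0.1, 10^(-40 / 20), 1e-9), c(2, 2, 1))
  out <- voxels(logCompress(Volume(v, 0.1), dynRangeDb = 40))
  expect_equal(out[1, 1, 1], 1)
  expect_equal(out[2, 1, 1], 0.5)           # vmax/10 at 40 dB
  expect_equal(out[1, 2, 1], 0)             # exactly at the floor
  expect_equal(out[2, 2, 1], 0)             # below the floor
  expect_error(logCompress(Volume(array(0, c(2, 2, 2)), 0.1)), "all-zero")
  expect_error(logCompress(Volume(array(-1, c(2, 2, 2)), 0.1)),
               "non-negative")
})

test_that("the enhancement chain preserves intensity ordering within a depth slice", {
  set.seed(13)
  vol <- Volume(array(runif(16 * 16 * 8), c(16, 16, 8)), 0.05)
  ## laterally flat illumination so the per-slice maps are strictly monotone
  enh <- enhanceVolume(vol, EnhanceParams(muEff = 0.5, sigK = 5, sigX0 = 0.4),
                       beamDiameter = 1e9)
  for (k in c(1, 4, 8)) {
    o1 <- order(voxels(vol)[, , k])
    v2 <- voxels(enh)[, , k][o1]
    expect_false(is.unsorted(round(v2, 12)))
  }
  expect_true(all(voxels(enh) >= 0 & voxels(enh) <= 1))
})

test_that("slab MIPs take per-pixel maxima with their depth of max", {
  v <- array(0, c(6, 5, 10))
  v[2, 3, 7] <- 2
  vol <- Volume(v, 0.1)
  mip <- slabMip(vol, "z")
  expect_equal(mip$image[2, 3], 2)
  expect_equal(mip$posOfMax[2, 3], 0.6)     # (7 - 1) * 0.1 mm
  expect_error(slabMip(vol, "z", c(2, 3)), "empty slab")

  ## stacked sources: a slab excluding the brighter one reports the dimmer
  v[2, 3, 2] <- 1
  vol <- Volume(v, 0.1)
  shallow <- slabMip(vol, "z", c(0, 0.55))
  expect_equal(shallow$image[2, 3], 1)
  expect_equal(shallow$posOfMax[2, 3], 0.1)

  ## full-range MIP dominates slab MIPs; disjoint slabs compose by max
  full <- slabMip(vol, "z")
  s1 <- slabMip(vol, "z", c(0, 0.5))
  s2 <- slabMip(vol, "z", c(0.5, 1.1))
  expect_true(all(full$image >= s1$image))
  expect_equal(full$image, pmax(s1$image, s2$image))
})

test_that("lateral MIPs project along x or y", {
  v <- array(0, c(4, 5, 6))
  v[3, 2, 5] <- 1
  mip <- slabMip(Volume(v, 0.1), "x")
  expect_equal(dim(mip$image), c(5, 6))
  expect_equal(mip$image[2, 5], 1)
  expect_equal(mip$posOfMax[2, 5], 0.2)
})

test_that("depth-encoded MIPs are decodable up to colormap quantization", {
  v <- array(0, c(8, 8, 20))
  v[3, 3, 4] <- 1
  v[6, 6, 16] <- 0.8
  vol <- Volume(v, 0.1)
  enc <- depthEncodedMip(vol)
  dec <- decodeDepthMip(enc)
  expect_equal(dec$intensity[3, 3], 1, tolerance = 1e-6)
  expect_equal(dec$intensity[6, 6], 0.8, tolerance = 1e-6)
  binWidth <- diff(enc$depthRange) / (enc$nBins - 1)
  expect_lt(abs(dec$depth[3, 3] - 0.3), binWidth + 1e-9)
  expect_lt(abs(dec$depth[6, 6] - 1.5), binWidth + 1e-9)
  ## distinct depths get distinct hues
  expect_gt(sum(abs(enc$rgb[3, 3, ] / sum(enc$rgb[3, 3, ]) -
                    enc$rgb[6, 6, ] / sum(enc$rgb[6, 6, ]))), 0.05)
  ## uniform depth: one hue
  u <- array(0, c(4, 4, 6)); u[, , 3] <- 1
  encU <- depthEncodedMip(Volume(u, 0.1))
  chroma <- matrix(encU$rgb, 16, 3)
  expect_lt(max(apply(chroma, 2, function(col) diff(range(col)))), 1e-9)
  expect_error(depthEncodedMip(vol, colormap = "no-such-map"),
               "unknown colormap")
})

test_that("surface cropping zeroes exactly the first z layers", {
  v <- array(1, c(4, 4, 6))
  v[2, 2, 3] <- 5
  vol <- Volume(v, 0.1)
  expect_identical(voxels(cropSurface(vol, 0L)), v)
  out <- voxels(cropSurface(vol, 3L))
  expect_true(all(out[, , 1:3] == 0))
  expect_identical(out[, , 4:6], v[, , 4:6])
  expect_error(cropSurface(vol, 6L), "nLayers")
})

test_that("component counting separates well-separated blobs", {
  img <- matrix(0, 20, 20)
  img[3:5, 3:5] <- 1
  img[14:16, 12:15] <- 0.8
  img[9, 18] <- 0.2                          # below half-max
  expect_identical(componentCount(img), 2L)
  expect_identical(componentCount(matrix(0, 5, 5)), 0L)
})
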