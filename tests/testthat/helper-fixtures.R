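# shared fixtures: everything is generated in code at test time

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

tinyGeom <- function(nSamples = 1024L, nxy = 0.2, c0 = 1540)
  ScanGeometry(extentX = nxy, extentY = nxy, step = 0.1, nBeams = 2L,
               nSamples = as.integer(nSamples), c0 = c0)

patchGeom <- function(extent = 3.2, nSamples = 256L, c0 = 1540)
  ScanGeometry(extentX = extent, extentY = extent, step = 0.1,
               nBeams = as.integer(min(32, round(extent / 0.1))),
               nSamples = as.integer(nSamples), c0 = c0)

randomScan <- function(geom, seed = 1) {
  n <- gridDims(geom)
  set.seed(seed)
  RFScan(geom, array(rnorm(n[1] * n[2] * geom@nSamples),
                     dim = c(n[1], n[2], geom@nSamples)))
}

## three well-separated short vessels at ~1 mm depth under a 32 x 32 patch;
## the standard end-to-end fixture
vesselFixture <- function(seed, c0 = 1540) {
  geom <- patchGeom(3.2, 256L, c0)
  ls <- list(superficial = list(depth = c(0.9, 1.4), radius = c(0.1, 0.14),
                                n = 3L, length = c(1.0, 1.4),
                                branchProb = 0, motifProb = 0))
  ph <- makeVesselTree(seed, ls,
                       box = list(x = c(0.6, 2.6), y = c(0.6, 2.6)),
                       minSeparation = 0.7)
  mu <- suppressWarnings(rasterize(ph, spacing = 0.05,
                                   box = list(x = c(0, 3.2), y = c(0, 3.2),
                                              z = c(0, 2.0))))
  list(geom = geom, phantom = ph, mu = mu)
}

argmaxPos <- function(vol) {
  ijk <- arrayInd(which.max(voxels(vol)), dim(voxels(vol)))
  origin(vol) + (ijk - 1) * spacing(vol)
}
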