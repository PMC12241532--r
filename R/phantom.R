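#' @include AllClasses.R geometry.R
NULL

## Run expr with a local RNG state: deterministic in `seed`, restores the
## caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default layered vessel specification
#'
#' Three depth layers emulating the vasculature of a hollow-organ wall:
#' a superficial web of fine vessels (0.05-0.5 mm deep, radii 20-50 um,
#' i.e. diameters below 100 um), a mid layer (0.5-1.5 mm, radii 60-200 um)
#' and a deep layer of large branching vessels (1.5-5 mm, radii
#' 0.25-0.75 mm). Radii grow and vessel counts shrink with depth;
#' branching probability grows with depth; the mid and deep layers may
#' emit parallel-vessel pairs/triplets (one trunk plus one or two offset
#' companions, the artery-and-veins motif).
#'
#' @return named list of per-layer specs, each with \code{depth} (mm),
#'   \code{radius} (mm), \code{n}, \code{length} (mm), \code{branchProb}
#'   and \code{motifProb}.
#' @export
defaultLayerSpec <- function() {
  list(
    superficial = list(depth = c(0.05, 0.5), radius = c(0.02, 0.05),
                       n = 8L, length = c(1.5, 4), branchProb = 0.3,
                       motifProb = 0),
    mid = list(depth = c(0.5, 1.5), radius = c(0.06, 0.2),
               n = 5L, length = c(3, 8), branchProb = 0.45,
               motifProb = 0.25),
    deep = list(depth = c(1.5, 5), radius = c(0.25, 0.75),
                n = 3L, length = c(6, 14), branchProb = 0.6,
                motifProb = 0.25)
  )
}

.segmentRow <- function(kind, p1, p2, radius, strength, layer, vessel) {
  data.frame(kind = kind, x1 = p1[1], y1 = p1[2], z1 = p1[3],
             x2 = p2[1], y2 = p2[2], z2 = p2[3],
             radius = radius, strength = strength, layer = layer,
             vessel = vessel)
}

#' Generate a layered vessel-tree phantom
#'
#' Draws, deterministically for a given seed, straight cylinder-segment
#' vessels layer by layer: each trunk gets a random lateral position,
#' orientation, length and a depth inside its layer's range; with
#' probability \code{branchProb} a thinner child segment branches off the
#' trunk end, and with probability \code{motifProb} one or two thinner
#' companion vessels run parallel to the trunk (pairs/triplets motif).
#'
#' @param seed integer seed; the phantom is a pure function of
#'   \code{(seed, layerSpec, box, minSeparation)}.
#' @param layerSpec per-layer specification as from [defaultLayerSpec()];
#'   depth ranges must be disjoint and ordered.
#' @param box lateral simulation box, \code{list(x = c(lo, hi),
#'   y = c(lo, hi))} in mm.
#' @param minSeparation minimum lateral clearance between trunk
#'   centrelines, mm (rejection-sampled; 0 disables).
#' @return a [VesselPhantom-class].
#' @export
makeVesselTree <- function(seed, layerSpec = defaultLayerSpec(),
                           box = list(x = c(0, 19), y = c(0, 16)),
                           minSeparation = 0) {
  if (!length(layerSpec))
    stop("configuration error: layerSpec must declare at least one layer")
  if (is.null(names(layerSpec)) ||
      !all(names(layerSpec) %in% c("superficial", "mid", "deep")))
    stop("configuration error: layers must be named superficial/mid/deep")
  depths <- t(vapply(layerSpec, function(l) l$depth, numeric(2)))
  if (any(depths[, 1] >= depths[, 2]))
    stop("configuration error: each depth range needs lo < hi")
  if (nrow(depths) > 1) {
    o <- order(depths[, 1])
    if (any(depths[o[-1], 1] < depths[o[-nrow(depths)], 2]))
      stop("configuration error: layer depth ranges must be disjoint")
  }
  .withSeed(seed, {
    rows <- list()
    segs <- matrix(numeric(0), ncol = 4)   # lateral trunk segments (x1 y1 x2 y2)
    vid <- 0L
    for (layer in names(layerSpec)) {
      sp <- layerSpec[[layer]]
      for (v in seq_len(sp$n)) {
        best <- NULL
        bestCl <- -Inf
        for (try in 1:400) {
          len <- stats::runif(1, sp$length[1], sp$length[2])
          ang <- stats::runif(1, 0, 2 * pi)
          u <- c(cos(ang), sin(ang))
          ctr <- c(stats::runif(1, box$x[1], box$x[2]),
                   stats::runif(1, box$y[1], box$y[2]))
          a1 <- pmin(pmax(ctr - len / 2 * u, c(box$x[1], box$y[1])),
                     c(box$x[2], box$y[2]))
          a2 <- pmin(pmax(ctr + len / 2 * u, c(box$x[1], box$y[1])),
                     c(box$x[2], box$y[2]))
          cl <- if (minSeparation <= 0) Inf
                else .minLateralClearance(a1, a2, segs)
          if (cl > bestCl) {
            bestCl <- cl
            best <- list(a1 = a1, a2 = a2, ang = ang, len = len)
          }
          if (cl >= minSeparation) break
        }
        a1 <- best$a1; a2 <- best$a2; ang <- best$ang; len <- best$len
        if (bestCl < minSeparation)
          warning("could not place a vessel with the requested ",
                  minSeparation, " mm clearance (best ",
                  signif(bestCl, 3), " mm)")
        segs <- rbind(segs, c(a1, a2))
        r <- stats::runif(1, sp$radius[1], sp$radius[2])
        zpad <- min(r, diff(sp$depth) / 4)
        z1 <- stats::runif(1, sp$depth[1] + zpad, sp$depth[2] - zpad)
        z2 <- min(max(z1 + stats::runif(1, -0.2, 0.2) * diff(sp$depth),
                      sp$depth[1] + zpad), sp$depth[2] - zpad)
        p1 <- c(a1, z1)
        p2 <- c(a2, z2)
        strength <- stats::runif(1, 0.8, 1.2)
        vid <- vid + 1L
        rows[[length(rows) + 1L]] <-
          .segmentRow("cylinder", p1, p2, r, strength, layer, vid)
        if (stats::runif(1) < sp$branchProb) {
          dev <- stats::runif(1, pi / 9, pi / 3) * sample(c(-1, 1), 1)
          ub <- c(cos(ang + dev), sin(ang + dev))
          lenb <- len * stats::runif(1, 0.4, 0.7)
          zb <- min(max(z2 + stats::runif(1, -0.1, 0.1) * diff(sp$depth),
                        sp$depth[1] + zpad), sp$depth[2] - zpad)
          p3 <- c(pmin(pmax(p2[1:2] + lenb * ub,
                            c(box$x[1], box$y[1])),
                       c(box$x[2], box$y[2])), zb)
          rows[[length(rows) + 1L]] <-
            .segmentRow("cylinder", p2, p3, r * 0.7, strength, layer, vid)
        }
        if (!is.null(sp$motifProb) && stats::runif(1) < sp$motifProb) {
          nComp <- sample(1:2, 1)
          perp <- c(-u[2], u[1])
          for (k in seq_len(nComp)) {
            off <- 2.5 * r * k * sample(c(-1, 1), 1)
            vid <- vid + 1L
            rows[[length(rows) + 1L]] <-
              .segmentRow("cylinder",
                          c(p1[1:2] + off * perp, p1[3]),
                          c(p2[1:2] + off * perp, p2[3]),
                          r * 0.6, strength * 0.9, layer, vid)
          }
        }
      }
    }
    new("VesselPhantom", absorbers = do.call(rbind, rows))
  })
}

## Minimum lateral (xy) distance between segment (a1, a2) and the stored
## trunk segments, approximated by sampling points along the candidate.
.minLateralClearance <- function(a1, a2, segs) {
  if (nrow(segs) == 0) return(Inf)
  t <- seq(0, 1, length.out = 17)
  px <- a1[1] + t * (a2[1] - a1[1])
  py <- a1[2] + t * (a2[2] - a1[2])
  mind <- Inf
  for (i in seq_len(nrow(segs))) {
    d2 <- .pointSegmentDist2(px, py, 0,
                             c(segs[i, 1], segs[i, 2], 0),
                             c(segs[i, 3], segs[i, 4], 0))
    mind <- min(mind, sqrt(min(d2)))
  }
  mind
}

.pointSegmentDist2 <- function(px, py, pz, a, b) {
  ab <- b - a
  ab2 <- sum(ab^2)
  if (ab2 < 1e-12) {
    (px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2
  } else {
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / ab2
    t <- pmin(pmax(t, 0), 1)
    (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
      (pz - (a[3] + t * ab[3]))^2
  }
}

#' Rasterize a phantom to an absorption map
#'
#' Voxelises the absorber list onto a cell-centred grid: each voxel gets
#' the absorber strength weighted by the fraction of a 3x3x3 subsample
#' falling inside the absorber (partial-volume handling); overlapping
#' absorbers add.
#'
#' @param phantom a [VesselPhantom-class].
#' @param spacing isotropic voxel size, mm. A warning is issued when it
#'   does not resolve the smallest radius with at least 2 voxels.
#' @param box \code{list(x =, y =, z = c(lo, hi))} in mm; defaults to the
#'   phantom bounding box padded by the largest radius, with z floored at
#'   0. Absorbers extending outside the box are clipped with a warning.
#' @return a [Volume-class] absorption map (origin at the first voxel
#'   centre).
#' @export
rasterize <- function(phantom, spacing, box = NULL) {
  a <- phantom@absorbers
  if (is.null(box)) {
    if (!nrow(a)) stop("cannot derive a box from an empty phantom")
    pad <- max(a$radius) + spacing
    box <- list(x = c(min(a$x1, a$x2) - pad, max(a$x1, a$x2) + pad),
                y = c(min(a$y1, a$y2) - pad, max(a$y1, a$y2) + pad),
                z = c(max(0, min(a$z1, a$z2) - pad),
                      max(a$z1, a$z2) + pad))
  }
  if (nrow(a) && spacing > min(a$radius) / 2)
    warning("voxel spacing ", spacing,
            " mm does not resolve the smallest radius (",
            min(a$radius), " mm) with >= 2 voxels")
  n <- pmax(1L, as.integer(round(c(diff(box$x), diff(box$y), diff(box$z)) /
                                   spacing)))
  orig <- c(box$x[1], box$y[1], box$z[1]) + spacing / 2
  vol <- array(0, dim = n)
  xs <- orig[1] + (seq_len(n[1]) - 1) * spacing
  ys <- orig[2] + (seq_len(n[2]) - 1) * spacing
  zs <- orig[3] + (seq_len(n[3]) - 1) * spacing
  sub <- spacing * c(-1, 0, 1) / 3
  clipped <- FALSE
  for (i in seq_len(nrow(a))) {
    r <- a$radius[i]
    p1 <- c(a$x1[i], a$y1[i], a$z1[i])
    p2 <- if (a$kind[i] == "sphere") p1 else c(a$x2[i], a$y2[i], a$z2[i])
    lo <- pmin(p1, p2) - r - spacing
    hi <- pmax(p1, p2) + r + spacing
    if (any(pmin(p1, p2) - r < c(box$x[1], box$y[1], box$z[1]) - 1e-9) ||
        any(pmax(p1, p2) + r > c(box$x[2], box$y[2], box$z[2]) + 1e-9))
      clipped <- TRUE
    ix <- which(xs >= lo[1] & xs <= hi[1])
    iy <- which(ys >= lo[2] & ys <= hi[2])
    iz <- which(zs >= lo[3] & zs <= hi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    px <- rep(xs[ix], times = length(iy) * length(iz))
    py <- rep(rep(ys[iy], each = length(ix)), times = length(iz))
    pz <- rep(zs[iz], each = length(ix) * length(iy))
    frac <- numeric(length(px))
    for (ox in sub) for (oy in sub) for (oz in sub) {
      d2 <- .pointSegmentDist2(px + ox, py + oy, pz + oz, p1, p2)
      frac <- frac + (d2 <= r^2)
    }
    frac <- frac / 27
    vol[ix, iy, iz] <- vol[ix, iy, iz] +
      array(a$strength[i] * frac, dim = c(length(ix), length(iy), length(iz)))
  }
  if (clipped)
    warning("phantom extends outside the rasterization box; clipped")
  Volume(vol, spacing = spacing, origin = orig,
         info = list(kind = "absorption"))
}

#' Apply the illumination/fluence model
#'
#' Converts an absorption map into an initial-pressure map:
#' \code{p0 = mu_a * G(x, y) * exp(-muEff * z)}, with G the unit-peak
#' Gaussian beam profile centred on the lateral midpoint of the volume
#' (1/e^2 intensity diameter \code{beamDiameter}). The Grueneisen factor is
#' absorbed into the arbitrary units.
#'
#' @param volume absorption-map [Volume-class].
#' @param illum an [IlluminationModel-class].
#' @return initial-pressure [Volume-class].
#' @export
applyFluence <- function(volume, illum) {
  f <- .fluenceFactor(volume, illum@beamDiameter, illum@muEff)
  Volume(volume@values * f, spacing = volume@spacing,
         origin = volume@origin,
         info = c(volume@info[setdiff(names(volume@info), "kind")],
                  list(kind = "p0", mu_eff = illum@muEff,
                       beam_diameter = illum@beamDiameter)))
}

## fluence factor array G(x,y) * exp(-mu z) on the volume grid
.fluenceFactor <- function(volume, beamDiameter, muEff) {
  d <- dim(volume@values)
  s <- volume@spacing
  o <- volume@origin
  xs <- o[1] + (seq_len(d[1]) - 1) * s[1]
  ys <- o[2] + (seq_len(d[2]) - 1) * s[2]
  zs <- o[3] + (seq_len(d[3]) - 1) * s[3]
  cx <- (xs[1] + xs[d[1]]) / 2
  cy <- (ys[1] + ys[d[2]]) / 2
  g <- exp(-8 * outer((xs - cx)^2, (ys - cy)^2, "+") / beamDiameter^2)
  dec <- exp(-muEff * zs)
  array(rep(g, times = d[3]) * rep(dec, each = d[1] * d[2]), dim = d)
}
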