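#' @include AllClasses.R geometry.R forward.R
NULL

## ---- FFT helpers ----------------------------------------------------------

## FFT along one dimension of a 3-D array (mvfft over a reshaped matrix).
.fftDim <- function(a, dim, inverse = FALSE) {
  d <- dim(a)
  perm <- c(dim, setdiff(1:3, dim))
  m <- matrix(aperm(a, perm), nrow = d[dim])
  m <- stats::mvfft(m, inverse = inverse)
  if (inverse) m <- m / d[dim]
  aperm(array(m, dim = d[perm]), order(perm))
}

## Interpolation gather along dim 3 at signed fractional FFT bins u:
## 4-point Lagrange interpolation on the uniformly sampled spectrum (the
## spectra are oscillatory in omega, so linear interpolation is too lossy
## for a consistent forward/backward operator pair). Bins whose 4-point
## stencil leaves the coherent half-spectrum (or NA) contribute zero.
.gatherDim3 <- function(P, u) {
  d <- dim(P)
  n3 <- d[3]
  half <- n3 %/% 2
  s12 <- d[1] * d[2]
  pos <- ifelse(u < 0, n3 + u, u)          # 0-based position in FFT layout
  i0 <- floor(pos)
  t <- as.vector(pos - i0)
  valid <- !is.na(u) &
    ((u >= 0 & i0 >= 1 & i0 + 2 <= half) |
     (u < 0 & i0 - 1 >= half & i0 + 2 <= n3 - 1))
  i0[!valid] <- 1
  base <- rep.int(seq_len(s12), n3)
  idx <- base + as.vector(i0) * s12
  out <- (-t * (t - 1) * (t - 2) / 6)       * P[idx - s12] +
         ((t + 1) * (t - 1) * (t - 2) / 2)  * P[idx] +
         (-(t + 1) * t * (t - 2) / 2)       * P[idx + s12] +
         ((t + 1) * t * (t - 1) / 6)        * P[idx + 2 * s12]
  out[!valid] <- 0
  array(out, dim = d)
}

## Sinc (zero-pad) upsampling of spectral dimension 1 by an integer factor
## (the Nyquist bin is split across the +/- Nyquist slots of the wider grid).
.padSpectralDim1 <- function(Q, f) {
  d <- dim(Q)
  n <- d[1]
  if (n %% 2 != 0)
    stop("lateral upsampling requires an even grid dimension")
  out <- array(0 + 0i, dim = c(f * n, d[2], d[3]))
  half <- n / 2
  out[1:half, , ] <- Q[1:half, , ]
  out[half + 1, , ] <- Q[half + 1, , ] / 2
  out[f * n - half + 1, , ] <- Q[half + 1, , ] / 2
  if (half >= 2)
    out[(f * n - half + 2):(f * n), , ] <- Q[(half + 2):n, , ]
  out
}

.padSpectralDim <- function(Q, dim, f) {
  if (dim == 1) return(.padSpectralDim1(Q, f))
  perm <- c(dim, setdiff(1:3, dim))
  aperm(.padSpectralDim1(aperm(Q, perm), f), order(perm))
}

## ---- planar k-space operators ---------------------------------------------

## Backward (adjoint/inverse) map: trace array (nx, ny, nt) -> volume
## spectrum in (kx, ky, z) with dz = c/fs; caller finishes the lateral ifft.
.kspaceAdjointSpectral <- function(tr, geom, c, padFactor = 2) {
  d <- dim(tr)
  nt <- d[3]
  tp <- padFactor * nt
  if (tp %% 2 != 0) tp <- tp + 1
  dx <- geom@step
  dz <- c * 1000 / geom@fs                 # mm per time sample
  A <- array(0, dim = c(d[1], d[2], tp))
  A[, , seq_len(nt)] <- tr
  A <- .fftDim(.fftDim(.fftDim(A, 1), 2), 3)
  kx <- 2 * pi * .fftfreq(d[1], dx)
  ky <- 2 * pi * .fftfreq(d[2], dx)
  kz <- 2 * pi * .fftfreq(tp, dz)
  dkz <- 2 * pi / (tp * dz)
  klat2 <- outer(kx^2, ky^2, "+")
  K <- sqrt(outer(klat2, kz^2, "+"))
  u <- sweep(K, 3, sign(kz), "*") / dkz    # omega expressed in kz-grid bins
  G <- .gatherDim3(A, u)
  W <- array(0, dim = dim(K))
  nz0 <- K > 0
  W[nz0] <- 1 / K[nz0]
  W <- sweep(W, 3, abs(kz), "*")           # |kz| / |k|
  Q <- .fftDim(G * W, 3, inverse = TRUE)
  list(Q = Q[, , seq_len(nt), drop = FALSE], dz = dz)
}

.kspaceAdjointVol <- function(tr, geom, c, padFactor = 2) {
  a <- .kspaceAdjointSpectral(tr, geom, c, padFactor)
  vol <- Re(.fftDim(.fftDim(a$Q, 1, inverse = TRUE), 2, inverse = TRUE))
  list(vol = vol, dz = a$dz)
}

## Forward map matching .kspaceAdjointVol: volume array (nx, ny, nt) with
## dz = c/fs -> predicted trace array (nx, ny, nt).
.kspaceForwardTraces <- function(vol, geom, c, padFactor = 2,
                                 weightCap = 100) {
  d <- dim(vol)
  nt <- d[3]
  tp <- padFactor * nt
  if (tp %% 2 != 0) tp <- tp + 1
  dx <- geom@step
  dz <- c * 1000 / geom@fs
  V <- array(0, dim = c(d[1], d[2], tp))
  V[, , seq_len(nt)] <- vol
  V <- .fftDim(.fftDim(.fftDim(V, 1), 2), 3)
  kx <- 2 * pi * .fftfreq(d[1], dx)
  ky <- 2 * pi * .fftfreq(d[2], dx)
  kap <- 2 * pi * .fftfreq(tp, dz)         # omega / c grid
  dkz <- 2 * pi / (tp * dz)
  klat2 <- outer(kx^2, ky^2, "+")
  D <- outer(klat2, kap^2, function(a, b) b - a)   # kz^2 of the wave
  valid <- D > 0
  S <- sqrt(pmax(D, 0))
  u <- sweep(S, 3, sign(kap), "*") / dkz
  u[!valid] <- NA
  W <- array(0, dim = dim(S))
  W[valid] <- 1 / S[valid]
  W <- sweep(W, 3, abs(kap), "*")          # |k| / |kz|
  W <- pmin(W, weightCap)
  Q <- .fftDim(.gatherDim3(V, u) * W, 3, inverse = TRUE)
  Re(.fftDim(.fftDim(Q[, , seq_len(nt), drop = FALSE], 1, inverse = TRUE),
             2, inverse = TRUE))
}

## Time-varying power-law attenuation filter (filter bank over nb rectangular
## frequency bands; propagation distance taken as c * t). inverse = TRUE
## amplifies (compensation, capped), FALSE attenuates (loss, uncapped).
.attenFilter <- function(tr, geom, atten, c, inverse = FALSE, gainCap = 10,
                         nBands = 12) {
  d <- dim(tr)
  nt <- d[3]
  fs <- geom@fs
  f <- abs(.fftfreq(nt, 1 / fs))
  edges <- seq(0, fs / 2, length.out = nBands + 1)
  tsec <- (seq_len(nt) - 1) / fs
  rcm <- c * tsec * 100                    # one-way path, cm
  m <- t(matrix(tr, nrow = d[1] * d[2]))   # nt x ndet
  X <- stats::mvfft(m)
  acc <- matrix(0, nrow = nt, ncol = d[1] * d[2])
  for (b in seq_len(nBands)) {
    mask <- f >= edges[b] & (f < edges[b + 1] | b == nBands)
    if (!any(mask)) next
    fc <- (edges[b] + edges[b + 1]) / 2 / 1e6
    xb <- Re(stats::mvfft(X * mask, inverse = TRUE)) / nt
    g <- 10^((if (inverse) 1 else -1) * atten@alpha0 * fc^atten@power *
               rcm / 20)
    if (inverse) g <- pmin(g, gainCap)
    acc <- acc + xb * g
  }
  array(t(acc), dim = d)
}

## ---- user-facing reconstruction -------------------------------------------

#' Planar k-space (FFT) reconstruction
#'
#' One-step inversion for planar detection: spatial FFT over the detector
#' grid and temporal FFT of the traces, remapping of temporal frequency to
#' axial wavenumber through the acoustic dispersion relation
#' \code{omega = c * sqrt(kx^2 + ky^2 + kz^2)} with the standard Jacobian
#' weighting \code{kz / |k|}, evanescent components zeroed, and inverse FFT
#' to the \code{(x, y, z)} initial-pressure volume. Linear in the input.
#' The native grid is the detector grid laterally and \code{c / fs} per
#' sample axially; time is zero-padded by \code{padFactor} to suppress
#' wrap-around.
#'
#' @param scan an [RFScan-class].
#' @param c sound speed, m/s (default: the geometry's \code{c0}).
#' @param padFactor temporal zero-padding factor.
#' @param lateralUpsample integer band-limited (spectral zero-pad) lateral
#'   upsampling factor of the output grid.
#' @return a [Volume-class]; \code{volInfo()} records method and c.
#' @export
kspaceReconstruct <- function(scan, c = NULL, padFactor = 2,
                              lateralUpsample = 1L) {
  if (is.null(c)) c <- scan@geometry@c0
  if (c <= 0) stop("parameter error: sound speed must be positive")
  f <- as.integer(lateralUpsample)
  a <- .kspaceAdjointSpectral(scan@traces, scan@geometry, c, padFactor)
  Q <- a$Q
  if (f > 1)
    Q <- .padSpectralDim(.padSpectralDim(Q, 1, f), 2, f) * f^2
  vol <- Re(.fftDim(.fftDim(Q, 1, inverse = TRUE), 2, inverse = TRUE))
  Volume(vol, spacing = c(scan@geometry@step / f, scan@geometry@step / f,
                          a$dz),
         origin = c(0, 0, 0),
         info = list(method = "kspace", c = c))
}

#' Iterative time reversal with attenuation compensation
#'
#' Back-propagates the (optionally attenuation-compensated) traces with the
#' planar k-space propagator, then refines iteratively: re-project the
#' current estimate with the forward propagator (applying power-law
#' attenuation loss when modelled), back-propagate the trace residual, add
#' the correction, and optionally project onto non-negative values.
#' Attenuation compensation amplifies each frequency band by the power-law
#' loss over the time-equivalent path \code{c * t}, capped at +20 dB to
#' bound noise amplification. Stops after \code{nIter} iterations or when
#' the relative trace residual falls below \code{tol}; if the residual
#' increases over two consecutive iterations a warning is raised and the
#' best iterate is returned.
#'
#' @param scan an [RFScan-class].
#' @param params a [ReconParams-class].
#' @param padFactor temporal zero-padding factor.
#' @return a [Volume-class]; \code{volInfo()$residuals} logs the
#'   per-iteration relative residual.
#' @export
timeReversal <- function(scan, params = ReconParams(), padFactor = 2) {
  validObject(params)
  g <- scan@geometry
  c <- params@c
  tr0 <- scan@traces
  norm0 <- sqrt(sum(tr0^2))
  comp <- function(x) {
    if (is.null(params@atten)) x
    else .attenFilter(x, g, params@atten, c, inverse = TRUE, gainCap = 10)
  }
  loss <- function(x) {
    if (is.null(params@atten)) x
    else .attenFilter(x, g, params@atten, c, inverse = FALSE)
  }
  proj <- function(v) if (params@nonneg) pmax(v, 0) else v
  b0 <- .kspaceAdjointVol(comp(tr0), g, c, padFactor)
  dz <- b0$dz
  mkvol <- function(v, residuals) {
    Volume(v, spacing = c(g@step, g@step, dz), origin = c(0, 0, 0),
           info = list(method = "time_reversal", c = c,
                       residuals = residuals))
  }
  if (norm0 == 0) return(mkvol(b0$vol, numeric(0)))
  v <- proj(b0$vol)
  residuals <- numeric(0)
  best <- v
  bestRes <- Inf
  for (it in seq_len(params@nIter)) {
    res <- tr0 - loss(.kspaceForwardTraces(v, g, c, padFactor))
    relres <- sqrt(sum(res^2)) / norm0
    residuals <- c(residuals, relres)
    if (relres <= bestRes) {
      bestRes <- relres
      best <- v
    }
    if (relres < params@tol) break
    n <- length(residuals)
    if (n >= 3 && residuals[n] > residuals[n - 1] &&
        residuals[n - 1] > residuals[n - 2]) {
      warning("time reversal diverging; returning the best iterate ",
              "(relative residual ", signif(bestRes, 3), ")")
      return(mkvol(best, residuals))
    }
    v <- proj(v + .kspaceAdjointVol(comp(res), g, c, padFactor)$vol)
  }
  mkvol(best, residuals)
}

## ---- sharpness and autofocus ----------------------------------------------

.gradDim <- function(a, dim) {
  n <- dim(a)[dim]
  if (n < 2) return(array(0, dim = dim(a)))
  ip <- c(2:n, n)
  im <- c(1, 1:(n - 1))
  den <- c(1, rep(2, max(0, n - 2)), 1)
  idx <- function(i) {
    args <- list(quote(expr =), quote(expr =), quote(expr =))
    args[[dim]] <- i
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
  }
  sweep(idx(ip) - idx(im), dim, den, "/")
}

#' Global gradient sharpness of a volume
#'
#' Sum over voxels of the Euclidean norm of the central-difference
#' intensity gradient (one-sided at the array edges). Non-negative, zero
#' iff the volume is constant, and positively homogeneous:
#' \code{sharpness(a * V) = a * sharpness(V)} for \code{a > 0}. This is the
#' focus metric maximised by the autofocus sound-speed search.
#'
#' @param volume a [Volume-class].
#' @return a non-negative scalar.
#' @export
sharpness <- function(volume) {
  v <- volume@values
  sum(sqrt(.gradDim(v, 1)^2 + .gradDim(v, 2)^2 + .gradDim(v, 3)^2))
}

#' Autofocus focus score of a volume
#'
#' The focus functional maximised by the autofocus sound-speed search: the
#' global squared gradient of the modulus image, normalised by the image
#' energy, \code{sum(|grad |v||^2) / sum(|v|^2)}. The modulus and the
#' normalisation make the score comparable across reconstructions at
#' different assumed sound speeds: the band-passed initial-pressure image
#' is sign-oscillating and its overall amplitude varies systematically
#' with the assumed speed, so the raw total gradient of the signed image
#' is dominated by those effects rather than by focus quality.
#'
#' @param volume a [Volume-class].
#' @return a non-negative, scale-invariant scalar (0 for an all-zero
#'   volume).
#' @export
focusScore <- function(volume) {
  a <- abs(volume@values)
  en <- sum(a^2)
  if (en == 0) return(0)
  sum(.gradDim(a, 1)^2 + .gradDim(a, 2)^2 + .gradDim(a, 3)^2) / en
}

#' Autofocus sound-speed selection
#'
#' Reconstructs the scan (k-space method) at each candidate sound speed
#' and returns the candidate maximising the global image-gradient focus
#' functional [focusScore()], ties broken toward the smallest candidate.
#' The full score table is returned for audit.
#'
#' @param scan an [RFScan-class].
#' @param cGrid numeric vector of candidate sound speeds, m/s.
#' @param padFactor temporal zero-padding factor for the reconstructions.
#' @return \code{list(cBest =, scores =)} with \code{scores} a data.frame
#'   of candidates and focus scores.
#' @export
autofocusSoS <- function(scan, cGrid = seq(1450, 1630, by = 10),
                         padFactor = 2) {
  if (!length(cGrid)) stop("cGrid must be non-empty")
  cGrid <- sort(as.numeric(cGrid))
  scores <- vapply(cGrid, function(cc)
    focusScore(kspaceReconstruct(scan, c = cc, padFactor = padFactor)),
    numeric(1))
  list(cBest = cGrid[which.max(scores)],
       scores = data.frame(c = cGrid, score = scores))
}

## ---- volume utilities -----------------------------------------------------

#' Trilinear resampling of a volume
#'
#' Resamples onto a grid with the requested spacing covering the same
#' extent (origin preserved).
#'
#' @param volume a [Volume-class].
#' @param spacing target per-axis spacing, mm (scalar recycled).
#' @return a [Volume-class].
#' @export
resampleVolume <- function(volume, spacing = 0.05) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  v <- volume@values
  d <- dim(v)
  s0 <- volume@spacing
  n2 <- pmax(1L, as.integer(floor((d - 1) * s0 / spacing)) + 1L)
  ax <- lapply(1:3, function(k) {
    pos <- (seq_len(n2[k]) - 1) * spacing[k] / s0[k] + 1
    i0 <- pmin(floor(pos), d[k] - ifelse(d[k] > 1, 1, 0))
    i0 <- pmax(i0, 1)
    list(i0 = i0, w = pos - i0)
  })
  out <- array(0, dim = n2)
  for (dx in 0:1) for (dy in 0:1) for (dzi in 0:1) {
    wx <- if (dx == 0) 1 - ax[[1]]$w else ax[[1]]$w
    wy <- if (dy == 0) 1 - ax[[2]]$w else ax[[2]]$w
    wz <- if (dzi == 0) 1 - ax[[3]]$w else ax[[3]]$w
    ix <- pmin(ax[[1]]$i0 + dx, d[1])
    iy <- pmin(ax[[2]]$i0 + dy, d[2])
    iz <- pmin(ax[[3]]$i0 + dzi, d[3])
    w3 <- outer(outer(wx, wy), wz)
    out <- out + w3 * v[ix, iy, iz, drop = FALSE]
  }
  Volume(out, spacing = spacing, origin = volume@origin, info = volume@info)
}

.profileFWHM <- function(x, y, upsample = 10) {
  n <- length(x)
  sp <- stats::spline(x, y, n = n * upsample)
  ipk <- which.max(sp$y)
  half <- sp$y[ipk] / 2
  below <- function(ord) {
    idx <- ord
    for (i in idx) if (sp$y[i] < half) return(i)
    NA_integer_
  }
  il <- below(rev(seq_len(ipk)))
  ir <- below(seq(ipk, length(sp$y)))
  if (is.na(il) || is.na(ir)) return(NA_real_)
  xl <- stats::approx(sp$y[c(il, il + 1)], sp$x[c(il, il + 1)],
                      xout = half)$y
  xr <- stats::approx(sp$y[c(ir - 1, ir)], sp$x[c(ir - 1, ir)],
                      xout = half)$y
  xr - xl
}

#' Lateral full width at half maximum of a reconstructed peak
#'
#' Extracts the profile along the given axis through the global maximum of
#' the volume, interpolates it 10-fold with a cubic spline, and measures
#' the width between the half-maximum crossings nearest the peak.
#'
#' @param volume a [Volume-class].
#' @param axis axis of the profile (1 = x, 2 = y, 3 = z).
#' @param upsample interpolation factor.
#' @return FWHM in mm (NA when no half-maximum crossing exists).
#' @export
lateralFWHM <- function(volume, axis = 1, upsample = 10) {
  v <- volume@values
  ijk <- arrayInd(which.max(v), dim(v))
  prof <- switch(axis,
                 v[, ijk[2], ijk[3]],
                 v[ijk[1], , ijk[3]],
                 v[ijk[1], ijk[2], ])
  coord <- volume@origin[axis] +
    (seq_len(dim(v)[axis]) - 1) * volume@spacing[axis]
  .profileFWHM(coord, prof, upsample)
}
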