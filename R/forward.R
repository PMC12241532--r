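#' @include AllClasses.R AllGenerics.R geometry.R
NULL

## FFT-ordered frequencies (Hz or cycles/mm) for n samples at spacing d.
.fftfreq <- function(n, d) {
  (((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)) / (n * d)
}

## Detector band-pass amplitude response on FFT-ordered frequencies:
## raised-cosine ramps centred on the passband edges (-6 dB at bandLo and
## bandHi), flat in between; ramp widths bandLo/2 and bandHi/5.
.bandpassResponse <- function(fHz, bandLo, bandHi, nyquist) {
  f <- abs(fHz)
  twLo <- bandLo / 2
  twHi <- min(bandHi / 5, 2 * (nyquist - bandHi))
  h <- numeric(length(f))
  lo1 <- bandLo - twLo / 2; lo2 <- bandLo + twLo / 2
  hi1 <- bandHi - twHi / 2; hi2 <- bandHi + twHi / 2
  h[f >= lo2 & f <= hi1] <- 1
  i <- f > lo1 & f < lo2
  h[i] <- 0.5 * (1 - cos(pi * (f[i] - lo1) / twLo))
  i <- f > hi1 & f < hi2
  h[i] <- 0.5 * (1 + cos(pi * (f[i] - hi1) / twHi))
  h
}

.volumeToPoints <- function(p0) {
  idx <- which(p0@values != 0)
  if (!length(idx))
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x", "y", "z", "amplitude"))))
  d <- dim(p0@values)
  ijk <- arrayInd(idx, d)
  cbind(x = p0@origin[1] + (ijk[, 1] - 1) * p0@spacing[1],
        y = p0@origin[2] + (ijk[, 2] - 1) * p0@spacing[2],
        z = p0@origin[3] + (ijk[, 3] - 1) * p0@spacing[3],
        amplitude = p0@values[idx])
}

.forwardPoints <- function(pts, geometry, atten, bandpass) {
  n <- gridDims(geometry)
  nt <- geometry@nSamples
  ndet <- n[1] * n[2]
  det <- detectorPositions(geometry)
  if (nrow(pts) && any(pts[, "z"] <= 0))
    stop("geometry error: sources must lie strictly below the sensor plane (z > 0)")
  fs <- geometry@fs
  cmm <- geometry@c0 * 1000      # mm/s
  f <- .fftfreq(nt, 1 / fs)      # Hz, FFT order
  ## The pressure wave of an impulsive point absorber is the time
  ## derivative of the delayed delta (N-wave); the derivative is folded
  ## into the band-limited detection kernel (normalised by the upper band
  ## edge to keep amplitudes of order 1/r). bandpass = FALSE keeps raw
  ## delayed deltas for arrival-time diagnostics.
  H <- if (bandpass)
    .bandpassResponse(f, geometry@bandLo, geometry@bandHi, fs / 2) *
      (2i * pi * f) / (2 * pi * geometry@bandHi)
  else rep(1, nt)
  if (is.null(atten)) {
    acc <- matrix(0, nrow = nt, ncol = ndet)
    for (i in seq_len(nrow(pts))) {
      r <- sqrt((det[, 1] - pts[i, "x"])^2 + (det[, 2] - pts[i, "y"])^2 +
                  pts[i, "z"]^2)
      u <- r / cmm * fs                     # fractional sample delay (0-based)
      i0 <- floor(u)
      w <- u - i0
      amp <- pts[i, "amplitude"] / r
      ok0 <- i0 >= 0 & i0 <= nt - 1
      ok1 <- i0 >= -1 & i0 <= nt - 2
      j <- seq_len(ndet)
      idx0 <- (i0 + 1) + (j - 1) * nt
      acc[idx0[ok0]] <- acc[idx0[ok0]] + ((1 - w) * amp)[ok0]
      acc[(idx0 + 1)[ok1]] <- acc[(idx0 + 1)[ok1]] + (w * amp)[ok1]
    }
    if (bandpass) {
      acc <- stats::mvfft(acc) * H
      acc <- Re(stats::mvfft(acc, inverse = TRUE)) / nt
    }
  } else {
    ## spectral path: exact per-path power-law loss (intended for compact
    ## sources; cost ~ nt * ndet per source voxel)
    fMHz <- abs(f) / 1e6
    accF <- matrix(0 + 0i, nrow = nt, ncol = ndet)
    for (i in seq_len(nrow(pts))) {
      r <- sqrt((det[, 1] - pts[i, "x"])^2 + (det[, 2] - pts[i, "y"])^2 +
                  pts[i, "z"]^2)
      t0 <- r / cmm                          # seconds
      lossDb <- outer(atten@alpha0 * fMHz^atten@power, r / 10)  # dB (r in cm)
      phase <- exp(-2i * pi * outer(f, t0))
      accF <- accF + phase * 10^(-lossDb / 20) *
        rep(pts[i, "amplitude"] / r, each = nt)
    }
    acc <- Re(stats::mvfft(accF * H, inverse = TRUE)) / nt
  }
  RFScan(geometry, array(t(acc), dim = c(n[1], n[2], nt)))
}

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature(p0 = "Volume"),
  function(p0, geometry, atten = NULL, bandpass = TRUE) {
    .forwardPoints(.volumeToPoints(p0), geometry, atten, bandpass)
  })

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature(p0 = "matrix"),
  function(p0, geometry, atten = NULL, bandpass = TRUE) {
    stopifnot(ncol(p0) == 4)
    colnames(p0) <- c("x", "y", "z", "amplitude")
    .forwardPoints(p0, geometry, atten, bandpass)
  })

#' Factory FPI sensitivity map
#'
#' The default inhomogeneity pattern of the sensor: three vertical bands of
#' relative gain 1.0 / 0.7 / 0.85 (x split in thirds) modulated by a smooth
#' low-frequency ripple along y, renormalised so the best detector has
#' gain 1.
#'
#' @param geometry a [ScanGeometry-class].
#' @return a [SensitivityMap-class].
#' @export
defaultSensitivityMap <- function(geometry) {
  n <- gridDims(geometry)
  third <- ceiling(n[1] / 3)
  bandId <- pmin((seq_len(n[1]) - 1) %/% third + 1, 3)
  bandGain <- c(1.0, 0.7, 0.85)[bandId]
  ripple <- 1 - 0.04 * (1 + sin(4 * pi * (seq_len(n[2]) - 1) / n[2])) / 2
  g <- outer(bandGain, ripple)
  SensitivityMap(g / max(g))
}

#' Apply per-detector sensitivity gains
#'
#' Multiplies every trace by its detector's relative gain, emulating the
#' sensitivity inhomogeneity of the FPI sensor.
#'
#' @param scan an [RFScan-class].
#' @param map a [SensitivityMap-class] matching the grid.
#' @return an [RFScan-class].
#' @export
applySensorInhomogeneity <- function(scan, map) {
  g <- map@gains
  if (!all(dim(g) == dim(scan@traces)[1:2]))
    stop("sensitivity map shape does not match the detector grid")
  RFScan(scan@geometry,
         scan@traces * array(rep(g, times = dim(scan@traces)[3]),
                             dim = dim(scan@traces)))
}

#' Add white Gaussian noise at a target SNR
#'
#' Adds zero-mean white Gaussian noise scaled so the realised
#' \code{10*log10(signal power / noise power)} equals \code{snrDb}
#' exactly (the drawn noise is renormalised to the target power).
#' Deterministic per seed; \code{snrDb = Inf} is the identity.
#'
#' @param scan an [RFScan-class].
#' @param snrDb target signal-to-noise ratio, dB.
#' @param seed integer seed.
#' @return an [RFScan-class].
#' @export
addNoise <- function(scan, snrDb, seed) {
  if (is.infinite(snrDb) && snrDb > 0) return(scan)
  psig <- mean(scan@traces^2)
  if (psig == 0)
    stop("cannot set a finite SNR on an all-zero scan")
  .withSeed(seed, {
    noise <- array(stats::rnorm(length(scan@traces)),
                   dim = dim(scan@traces))
    noise <- noise * sqrt(psig / 10^(snrDb / 10)) / sqrt(mean(noise^2))
    RFScan(scan@geometry, scan@traces + noise)
  })
}
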