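#' @include AllClasses.R geometry.R dwt.R
NULL

#' Zero-phase high-pass filtering of RF traces
#'
#' Removes the DC / low-frequency content of every trace with a 4th-order
#' Butterworth high-pass applied forward and backward (zero phase, so
#' arrival times are preserved). DC rejection is better than -60 dB and
#' the amplitude change above twice the cutoff is below 1 percent.
#'
#' @param scan an [RFScan-class].
#' @param cutoffHz cutoff frequency, Hz (must lie in \code{(0, fs/2)}).
#' @param order filter order.
#' @return an [RFScan-class].
#' @export
highpass <- function(scan, cutoffHz = 0.5e6, order = 4L) {
  fs <- scan@geometry@fs
  if (cutoffHz <= 0 || cutoffHz >= fs / 2)
    stop("parameter error: cutoff must lie strictly between 0 and fs/2")
  flt <- signal::butter(order, cutoffHz / (fs / 2), type = "high")
  d <- dim(scan@traces)
  n <- d[3]
  ## zero-phase pass: odd-reflection padding long enough for the filter
  ## transient to die out, forward and reverse recursive filtering
  pad <- min(n - 1, max(3L * ceiling(fs / cutoffHz), 8L * order))
  onepass <- function(x) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- signal::filter(flt, xp)
    y <- rev(signal::filter(flt, rev(y)))
    y[(pad + 1):(pad + n)]
  }
  tr <- matrix(scan@traces, nrow = d[1] * d[2])
  out <- t(apply(tr, 1, onepass))
  RFScan(scan@geometry, array(out, dim = d))
}

#' Wavelet soft-threshold denoising of RF traces
#'
#' Per-trace periodized orthonormal Daubechies (4-tap) decomposition with
#' soft thresholding of all detail coefficients at the universal threshold
#' \code{sigma_hat * sqrt(2 log n)}, where \code{sigma_hat} is the median
#' absolute deviation of the finest-scale details divided by 0.6745. The
#' transform is orthonormal, so trace energy never increases.
#'
#' @param scan an [RFScan-class].
#' @param family wavelet family; only the Daubechies 4-tap \code{"d4"} is
#'   provided.
#' @param levels decomposition levels; requires \code{nSamples >= 2^levels}.
#' @return an [RFScan-class].
#' @export
waveletDenoise <- function(scan, family = "d4", levels = 4L) {
  if (!identical(family, "d4"))
    stop("parameter error: unsupported wavelet family '", family, "'")
  nt <- scan@geometry@nSamples
  if (nt < 2^levels)
    stop("parameter error: need nSamples >= 2^levels")
  d <- dim(scan@traces)
  tr <- matrix(scan@traces, nrow = d[1] * d[2])
  out <- t(apply(tr, 1, .waveletDenoiseTrace, levels = levels))
  RFScan(scan@geometry, array(out, dim = d))
}

#' Sensitivity correction of RF traces
#'
#' Divides every trace by its detector's relative gain, floored to bound
#' noise amplification in dead zones: the exact inverse of
#' [applySensorInhomogeneity()] wherever the gain is at least \code{floor}.
#'
#' @param scan an [RFScan-class].
#' @param map a [SensitivityMap-class].
#' @param floor minimum gain used in the division, in \code{(0, 1]}.
#' @return an [RFScan-class].
#' @export
sensitivityCorrect <- function(scan, map, floor = 0.2) {
  if (floor <= 0 || floor > 1)
    stop("parameter error: floor must lie in (0, 1]")
  g <- map@gains
  if (!all(dim(g) == dim(scan@traces)[1:2]))
    stop("sensitivity map shape does not match the detector grid")
  inv <- 1 / pmax(g, floor)
  RFScan(scan@geometry,
         scan@traces * array(rep(inv, times = dim(scan@traces)[3]),
                             dim = dim(scan@traces)))
}
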