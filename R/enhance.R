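#' @include AllClasses.R geometry.R phantom.R
NULL

#' Fluence compensation
#'
#' Divides the reconstructed volume by the modelled illumination pattern
#' \code{G(x, y) * exp(-muEff * z)} (Gaussian lateral beam profile times
#' exponential depth decay), so intensity reflects absorption rather than
#' light delivery. The combined correction factor is capped at
#' \code{compCap} to bound noise amplification; below the cap this is the
#' exact inverse of [applyFluence()].
#'
#' @param volume a [Volume-class].
#' @param params an [EnhanceParams-class] (uses \code{muEff},
#'   \code{compCap}).
#' @param beamDiameter 1/e^2 beam diameter of the excitation beam, mm.
#' @return a [Volume-class].
#' @export
fluenceCompensate <- function(volume, params = EnhanceParams(),
                              beamDiameter = 30) {
  f <- .fluenceFactor(volume, beamDiameter, params@muEff)
  corr <- pmin(1 / f, params@compCap)
  Volume(volume@values * corr, spacing = volume@spacing,
         origin = volume@origin, info = volume@info)
}

#' Sigmoid normalization
#'
#' Voxelwise logistic contrast stretch
#' \code{1 / (1 + exp(-sigK * (v - sigX0)))}: strictly monotone, output in
#' (0, 1). Defaults centre the stretch on the volume median with slope
#' \code{4 / IQR}.
#'
#' @param volume a [Volume-class].
#' @param sigK slope (NULL: \code{4 / IQR} of the voxel values).
#' @param sigX0 midpoint (NULL: voxel median).
#' @return a [Volume-class].
#' @export
sigmoidNormalize <- function(volume, sigK = NULL, sigX0 = NULL) {
  v <- volume@values
  if (is.null(sigX0)) sigX0 <- stats::median(v)
  if (is.null(sigK)) {
    iqr <- stats::IQR(v)
    sigK <- if (iqr > 0) 4 / iqr else 1
  }
  if (sigK <= 0) stop("parameter error: sigK must be positive")
  Volume(1 / (1 + exp(-sigK * (v - sigX0))), spacing = volume@spacing,
         origin = volume@origin, info = volume@info)
}

#' Logarithmic compression
#'
#' Decibel display scaling to a dynamic-range floor:
#' \code{v -> max(0, 1 + 20 * log10(v / vmax) / dynRangeDb)}. The maximum
#' maps to 1; values more than \code{dynRangeDb} below it map to 0.
#'
#' @param volume a non-negative [Volume-class] with a positive maximum.
#' @param dynRangeDb dynamic range, dB.
#' @return a [Volume-class] with values in \[0, 1\].
#' @export
logCompress <- function(volume, dynRangeDb = 40) {
  v <- volume@values
  if (any(v < 0)) stop("logCompress requires a non-negative volume")
  vmax <- max(v)
  if (vmax == 0) stop("logCompress is undefined for an all-zero volume")
  out <- pmax(1 + 20 * log10(pmax(v, .Machine$double.xmin) / vmax) /
                dynRangeDb, 0)
  Volume(out, spacing = volume@spacing, origin = volume@origin,
         info = volume@info)
}

#' Full enhancement chain
#'
#' Fluence compensation, then sigmoid normalization, then logarithmic
#' compression, in that fixed order.
#'
#' @param volume a [Volume-class].
#' @param params an [EnhanceParams-class].
#' @param beamDiameter 1/e^2 beam diameter, mm.
#' @return a [Volume-class] with values in \[0, 1\].
#' @export
enhanceVolume <- function(volume, params = EnhanceParams(),
                          beamDiameter = 30) {
  v <- fluenceCompensate(volume, params, beamDiameter)
  v <- sigmoidNormalize(v, params@sigK, params@sigX0)
  logCompress(v, params@dynRangeDb)
}
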