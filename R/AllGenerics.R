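#' @include AllClasses.R
NULL

#' @describeIn RFScan-class scan geometry accessor
#' @param x an object with a geometry.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @describeIn RFScan-class trace array accessor
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @describeIn Volume-class voxel array accessor
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @describeIn Volume-class voxel spacing (mm) accessor
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @describeIn Volume-class origin (mm) accessor
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @describeIn Volume-class auxiliary info list accessor
#' @export
setGeneric("volInfo", function(x) standardGeneric("volInfo"))

#' @describeIn SensitivityMap-class gain matrix accessor
#' @export
setGeneric("gains", function(x) standardGeneric("gains"))

#' @describeIn VesselPhantom-class absorber table accessor
#' @export
setGeneric("absorbers", function(x) standardGeneric("absorbers"))

#' Band-limited spherical-wave forward projection
#'
#' Computes the RF traces an ideal point-detector grid on the \code{z = 0}
#' plane would record from an initial-pressure distribution at \code{z > 0}:
#' each source contributes a spherical wave with amplitude proportional to
#' \code{1/r} and delay \code{r / c0}, convolved with the detector band-pass
#' impulse response (raised-cosine edged passband, -6 dB at
#' \code{bandLo}/\code{bandHi}), optionally with frequency-dependent
#' power-law attenuation over each propagation path. Linear in the source.
#'
#' @param p0 initial pressure: a [Volume-class], or a numeric matrix with
#'   columns \code{x, y, z, amplitude} (mm, arbitrary units) of point
#'   sources.
#' @param geometry a [ScanGeometry-class].
#' @param atten an [AttenuationModel-class] or NULL (lossless).
#' @param bandpass apply the detector band-pass (set FALSE for broadband
#'   diagnostics).
#' @return an [RFScan-class].
#' @export
setGeneric("forwardProject",
  function(p0, geometry, atten = NULL, bandpass = TRUE)
    standardGeneric("forwardProject"))
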