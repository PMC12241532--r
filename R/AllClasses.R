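setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Scan geometry of the planar FPI sensor
#'
#' Describes the detector grid, interrogation-beam multiplexing and trace
#' sampling of a planar Fabry-Perot scanner. Detector \code{(ix, iy)}
#' (zero-based) sits at \code{(ix * step, iy * step)} millimetres on the
#' \code{z = 0} sensor plane; the grid is half-open so
#' \code{nx = round(extentX / step)}.
#'
#' @slot extentX,extentY scanned sensor area, mm.
#' @slot step detector pitch, mm.
#' @slot nBeams number of parallel interrogation beams.
#' @slot prf excitation pulse repetition frequency, Hz.
#' @slot fs trace sampling frequency, Hz.
#' @slot nSamples samples per trace.
#' @slot c0 assumed sound speed, m/s.
#' @slot bandLo,bandHi detector passband edges, Hz.
#'
#' @export
setClass("ScanGeometry",
  representation(
    extentX = "numeric", extentY = "numeric", step = "numeric",
    nBeams = "integer", prf = "numeric", fs = "numeric",
    nSamples = "integer", c0 = "numeric",
    bandLo = "numeric", bandHi = "numeric"
  )
)

.gridCount <- function(extent, step) {
  ratio <- extent / step
  n <- round(ratio)
  if (abs(ratio - n) > 1e-9 * max(1, abs(ratio)))
    stop("invalid geometry: extent ", extent,
         " mm is not an integer multiple of step ", step, " mm")
  as.integer(n)
}

setValidity("ScanGeometry", function(object) {
  msg <- character()
  pos <- c(extentX = object@extentX, extentY = object@extentY,
           step = object@step, nBeams = object@nBeams, prf = object@prf,
           fs = object@fs, nSamples = object@nSamples, c0 = object@c0,
           bandLo = object@bandLo, bandHi = object@bandHi)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all geometry fields must be positive and finite")
  if (!length(msg)) {
    nx <- tryCatch(.gridCount(object@extentX, object@step),
                   error = function(e) conditionMessage(e))
    ny <- tryCatch(.gridCount(object@extentY, object@step),
                   error = function(e) conditionMessage(e))
    if (is.character(nx)) msg <- c(msg, nx)
    if (is.character(ny)) msg <- c(msg, ny)
    if (is.integer(nx) && object@nBeams > nx)
      msg <- c(msg, "nBeams must not exceed the x grid dimension")
    if (!(object@bandLo < object@bandHi && object@bandHi < object@fs / 2))
      msg <- c(msg, "need bandLo < bandHi < fs/2")
  }
  if (length(msg)) msg else TRUE
})

#' RF scan: time traces on the detector grid
#'
#' The raw input of the imaging pipeline: one pressure-amplitude time trace
#' per detector, in arbitrary linear units, indexed \code{(ix, iy, it)}.
#'
#' @slot geometry a [ScanGeometry-class].
#' @slot traces numeric array of dimension \code{(nx, ny, nSamples)}.
#' @export
setClass("RFScan",
  representation(geometry = "ScanGeometry", traces = "array")
)

setValidity("RFScan", function(object) {
  g <- object@geometry
  d <- dim(object@traces)
  expect <- c(.gridCount(g@extentX, g@step), .gridCount(g@extentY, g@step),
              g@nSamples)
  if (length(d) != 3 || any(d != expect))
    return(sprintf("trace array must have dimension (%d, %d, %d)",
                   expect[1], expect[2], expect[3]))
  if (!all(is.finite(object@traces)))
    return("traces must be finite")
  TRUE
})

#' Reconstructed volume
#'
#' A voxel grid anchored at the sensor plane: voxel \code{(ix, iy, iz)}
#' (one-based) has its centre at \code{origin + (i - 1) * spacing}
#' millimetres, with z increasing into the tissue.
#'
#' @slot values numeric 3-D array \code{(ix, iy, iz)}.
#' @slot spacing per-axis voxel size, mm.
#' @slot origin coordinate of voxel (1,1,1), mm.
#' @slot info free-form list (reconstruction parameters, residual log, ...).
#' @export
setClass("Volume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", info = "list"),
  prototype(origin = c(0, 0, 0), info = list())
)

setValidity("Volume", function(object) {
  if (length(dim(object@values)) != 3)
    return("values must be a 3-D array")
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    return("origin must be three finite numbers (mm)")
  if (!all(is.finite(object@values)))
    return("values must be finite")
  TRUE
})

#' Relative detector sensitivity map
#'
#' Multiplicative per-detector gains of the FPI sensor, in (0, 1], with the
#' best detector normalised to 1.
#'
#' @slot gains numeric matrix \code{(nx, ny)}.
#' @export
setClass("SensitivityMap", representation(gains = "matrix"))

setValidity("SensitivityMap", function(object) {
  g <- object@gains
  if (!is.numeric(g) || any(!is.finite(g)))
    return("gains must be finite numeric")
  if (any(g <= 0) || any(g > 1 + 1e-12))
    return("gains must lie in (0, 1]")
  if (max(g) < 1 - 1e-9)
    return("at least one gain must equal 1")
  TRUE
})

#' Acquisition schedule of a stepped multi-beam scan
#'
#' Pulse and A-line counts and timing implied by a [ScanGeometry-class]:
#' each excitation pulse records \code{nBeams} A-lines, so
#' \code{alineRate = nBeams * prf} and
#' \code{duration = ceil(nx * ny / nBeams) / prf}.
#'
#' @slot nALines total A-lines (detector positions).
#' @slot nPulses excitation pulses needed.
#' @slot alineRate A-lines per second.
#' @slot duration scan duration, s (raw).
#' @slot durationRounded duration rounded half-up to whole seconds.
#' @export
setClass("AcquisitionSchedule",
  representation(nALines = "integer", nPulses = "integer",
                 alineRate = "numeric", duration = "numeric",
                 durationRounded = "numeric")
)

#' Layered vessel phantom
#'
#' A list of absorbing primitives (spheres and cylinder segments) with a
#' layer tag per absorber, emulating the layered vasculature of a hollow
#' organ wall: a superficial web of fine vessels over progressively larger,
#' branching vessels at depth.
#'
#' @slot absorbers data.frame with columns \code{kind} ("sphere" or
#'   "cylinder"), \code{x1,y1,z1,x2,y2,z2} (mm; spheres use only the first
#'   triplet), \code{radius} (mm), \code{strength} (dimensionless),
#'   \code{layer} ("superficial", "mid", "deep") and \code{vessel}
#'   (integer id grouping segments of one vessel).
#' @export
setClass("VesselPhantom", representation(absorbers = "data.frame"))

setValidity("VesselPhantom", function(object) {
  a <- object@absorbers
  need <- c("kind", "x1", "y1", "z1", "x2", "y2", "z2",
            "radius", "strength", "layer", "vessel")
  if (!all(need %in% names(a)))
    return(paste("absorbers must have columns:", paste(need, collapse = ", ")))
  if (nrow(a)) {
    if (any(a$radius <= 0)) return("radius must be positive")
    if (any(a$strength < 0)) return("strength must be non-negative")
    if (!all(a$kind %in% c("sphere", "cylinder")))
      return("kind must be 'sphere' or 'cylinder'")
    if (!all(a$layer %in% c("superficial", "mid", "deep")))
      return("layer must be 'superficial', 'mid' or 'deep'")
  }
  TRUE
})

#' Illumination model
#'
#' Gaussian excitation-beam lateral profile with exponential fluence decay
#' in depth: \code{phi(x, y, z) = G(x, y) * exp(-muEff * z)} with G a
#' unit-peak centred Gaussian whose 1/e^2 intensity diameter is
#' \code{beamDiameter}.
#'
#' @slot beamDiameter 1/e^2 beam diameter, mm.
#' @slot muEff effective optical attenuation coefficient, mm^-1.
#' @slot pulseEnergy pulse energy, mJ (metadata only).
#' @export
setClass("IlluminationModel",
  representation(beamDiameter = "numeric", muEff = "numeric",
                 pulseEnergy = "numeric")
)

setValidity("IlluminationModel", function(object) {
  if (object@beamDiameter <= 0) return("beamDiameter must be positive")
  if (object@muEff < 0) return("muEff must be non-negative")
  TRUE
})

#' Power-law acoustic attenuation model
#'
#' Frequency-dependent amplitude loss \code{alpha0 * f_MHz^power} in
#' dB/cm over the propagation path.
#'
#' @slot alpha0 attenuation coefficient, dB cm^-1 MHz^-power.
#' @slot power frequency-power-law exponent, in \[1, 2\].
#' @export
setClass("AttenuationModel",
  representation(alpha0 = "numeric", power = "numeric")
)

setValidity("AttenuationModel", function(object) {
  if (object@alpha0 < 0) return("alpha0 must be non-negative")
  if (object@power < 1 || object@power > 2)
    return("power must lie in [1, 2]")
  TRUE
})

setClassUnion("AttenuationModelOrNULL", c("AttenuationModel", "NULL"))

#' Reconstruction parameters
#'
#' @slot c sound speed, m/s (warn outside \[1300, 1700\]).
#' @slot atten an [AttenuationModel-class] to compensate, or NULL.
#' @slot nIter time-reversal iterations.
#' @slot tol relative-residual stopping tolerance.
#' @slot nonneg apply a non-negativity projection each iteration.
#' @export
setClass("ReconParams",
  representation(c = "numeric", atten = "AttenuationModelOrNULL",
                 nIter = "integer", tol = "numeric", nonneg = "logical")
)

setValidity("ReconParams", function(object) {
  if (object@c <= 0) return("sound speed must be positive")
  if (object@nIter < 1) return("nIter must be >= 1")
  if (object@tol <= 0) return("tol must be positive")
  TRUE
})

#' Enhancement parameters
#'
#' @slot muEff effective optical attenuation used for depth compensation,
#'   mm^-1.
#' @slot compCap maximum fluence-correction amplification (>= 1).
#' @slot sigK sigmoid slope (NULL: 4 / IQR of the volume).
#' @slot sigX0 sigmoid midpoint (NULL: volume median).
#' @slot dynRangeDb log-compression dynamic range, dB.
#' @export
setClass("EnhanceParams",
  representation(muEff = "numeric", compCap = "numeric",
                 sigK = "numericOrNULL", sigX0 = "numericOrNULL",
                 dynRangeDb = "numeric")
)

setValidity("EnhanceParams", function(object) {
  if (object@muEff < 0) return("muEff must be non-negative")
  if (object@compCap < 1) return("compCap must be >= 1")
  if (!is.null(object@sigK) && object@sigK <= 0)
    return("sigK must be positive")
  if (object@dynRangeDb <= 0) return("dynRangeDb must be positive")
  TRUE
})
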