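#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a scan geometry
#'
#' Defaults describe the integrated FPI scanner: a 19 x 16 mm sensor area
#' scanned at 100 um pitch by 32 parallel interrogation beams at a 100 Hz
#' pulse repetition frequency, traces sampled at 60 MHz over the 2-15 MHz
#' detection band. The default sound speed (1540 m/s, soft-tissue
#' convention) is a placeholder that reconstruction normally replaces by
#' autofocus selection.
#'
#' @param extentX,extentY sensor scan area, mm.
#' @param step detector pitch, mm.
#' @param nBeams parallel interrogation beams.
#' @param prf pulse repetition frequency, Hz.
#' @param fs sampling frequency, Hz.
#' @param nSamples samples per trace.
#' @param c0 assumed sound speed, m/s.
#' @param bandLo,bandHi detection passband edges, Hz.
#' @return a [ScanGeometry-class].
#' @examples
#' g <- ScanGeometry()
#' gridDims(g)          # 190 x 160 detectors
#' scanSchedule(g)      # 3200 A-lines/s, ~10 s
#' @export
ScanGeometry <- function(extentX = 19, extentY = 16, step = 0.1,
                         nBeams = 32L, prf = 100, fs = 60e6,
                         nSamples = 1024L, c0 = 1540,
                         bandLo = 2e6, bandHi = 15e6) {
  new("ScanGeometry", extentX = extentX, extentY = extentY, step = step,
      nBeams = as.integer(nBeams), prf = prf, fs = fs,
      nSamples = as.integer(nSamples), c0 = c0,
      bandLo = bandLo, bandHi = bandHi)
}

#' Detector grid dimensions
#'
#' @param geometry a [ScanGeometry-class].
#' @return integer vector \code{c(nx, ny)}.
#' @export
gridDims <- function(geometry) {
  c(nx = .gridCount(geometry@extentX, geometry@step),
    ny = .gridCount(geometry@extentY, geometry@step))
}

#' Detector coordinates
#'
#' Lateral positions (mm) of every detector in x-fastest raster order.
#'
#' @param geometry a [ScanGeometry-class].
#' @return matrix with columns \code{x, y}, one row per detector.
#' @export
detectorPositions <- function(geometry) {
  n <- gridDims(geometry)
  cbind(x = rep((seq_len(n[1]) - 1) * geometry@step, times = n[2]),
        y = rep((seq_len(n[2]) - 1) * geometry@step, each = n[1]))
}

#' Construct an RF scan
#'
#' @param geometry a [ScanGeometry-class].
#' @param traces numeric array \code{(nx, ny, nSamples)}.
#' @return an [RFScan-class].
#' @export
RFScan <- function(geometry, traces) {
  if (!is.null(names(dim(traces)))) names(dim(traces)) <- NULL
  new("RFScan", geometry = geometry, traces = traces)
}

#' Construct a volume
#'
#' @param values 3-D numeric array.
#' @param spacing per-axis voxel size, mm (scalar recycled).
#' @param origin coordinate of the first voxel centre, mm.
#' @param info free-form list.
#' @return a [Volume-class].
#' @export
Volume <- function(values, spacing, origin = c(0, 0, 0), info = list()) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (!is.null(names(dim(values)))) names(dim(values)) <- NULL
  new("Volume", values = values, spacing = unname(as.numeric(spacing)),
      origin = unname(as.numeric(origin)), info = info)
}

#' Construct a sensitivity map
#'
#' @param gains matrix of per-detector gains in (0, 1], max normalised to 1.
#' @return a [SensitivityMap-class].
#' @export
SensitivityMap <- function(gains) new("SensitivityMap", gains = gains)

#' Construct an illumination model
#'
#' Defaults: 30 mm 1/e^2 beam diameter filling the sensor, 18 mJ per pulse.
#'
#' @param beamDiameter 1/e^2 beam diameter, mm.
#' @param muEff effective optical attenuation, mm^-1.
#' @param pulseEnergy pulse energy, mJ (metadata).
#' @return an [IlluminationModel-class].
#' @export
IlluminationModel <- function(beamDiameter = 30, muEff = 0.5,
                              pulseEnergy = 18) {
  new("IlluminationModel", beamDiameter = beamDiameter, muEff = muEff,
      pulseEnergy = pulseEnergy)
}

#' Construct an acoustic attenuation model
#'
#' Defaults to the soft-tissue convention 0.5 dB cm^-1 MHz^-1.1.
#'
#' @param alpha0 dB cm^-1 MHz^-power.
#' @param power frequency exponent in \[1, 2\].
#' @return an [AttenuationModel-class].
#' @export
AttenuationModel <- function(alpha0 = 0.5, power = 1.1) {
  new("AttenuationModel", alpha0 = alpha0, power = power)
}

#' Construct reconstruction parameters
#'
#' @param c sound speed, m/s.
#' @param atten [AttenuationModel-class] or NULL.
#' @param nIter time-reversal iterations.
#' @param tol relative-residual stopping tolerance.
#' @param nonneg non-negativity projection per iteration.
#' @return a [ReconParams-class].
#' @export
ReconParams <- function(c = 1540, atten = NULL, nIter = 5L, tol = 1e-3,
                        nonneg = TRUE) {
  if (c < 1300 || c > 1700)
    warning("sound speed ", c, " m/s outside the usual 1300-1700 m/s range")
  new("ReconParams", c = c, atten = atten, nIter = as.integer(nIter),
      tol = tol, nonneg = nonneg)
}

#' Construct enhancement parameters
#'
#' @param muEff effective optical attenuation, mm^-1.
#' @param compCap maximum fluence-correction amplification.
#' @param sigK sigmoid slope (NULL: 4 / IQR).
#' @param sigX0 sigmoid midpoint (NULL: median).
#' @param dynRangeDb log-compression dynamic range, dB.
#' @return an [EnhanceParams-class].
#' @export
EnhanceParams <- function(muEff = 0.5, compCap = 10, sigK = NULL,
                          sigX0 = NULL, dynRangeDb = 40) {
  new("EnhanceParams", muEff = muEff, compCap = compCap, sigK = sigK,
      sigX0 = sigX0, dynRangeDb = dynRangeDb)
}

## ---- accessors ------------------------------------------------------------

#' @rdname RFScan-class
#' @export
setMethod("geometry", "RFScan", function(x) x@geometry)

#' @rdname RFScan-class
#' @export
setMethod("traces", "RFScan", function(x) x@traces)

#' @rdname Volume-class
#' @param x a Volume.
#' @export
setMethod("voxels", "Volume", function(x) x@values)

#' @rdname Volume-class
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname Volume-class
#' @export
setMethod("origin", "Volume", function(x) x@origin)

#' @rdname Volume-class
#' @export
setMethod("volInfo", "Volume", function(x) x@info)

#' @rdname SensitivityMap-class
#' @param x a SensitivityMap.
#' @export
setMethod("gains", "SensitivityMap", function(x) x@gains)

#' @rdname VesselPhantom-class
#' @param x a VesselPhantom.
#' @export
setMethod("absorbers", "VesselPhantom", function(x) x@absorbers)

## ---- show methods ---------------------------------------------------------

setMethod("show", "ScanGeometry", function(object) {
  n <- gridDims(object)
  cat(sprintf("ScanGeometry: %g x %g mm @ %g um pitch (%d x %d detectors)\n",
              object@extentX, object@extentY, object@step * 1000,
              n[1], n[2]))
  cat(sprintf("  %d beams, PRF %g Hz, fs %g MHz, %d samples, band %g-%g MHz, c0 %g m/s\n",
              object@nBeams, object@prf, object@fs / 1e6, object@nSamples,
              object@bandLo / 1e6, object@bandHi / 1e6, object@c0))
})

setMethod("show", "RFScan", function(object) {
  d <- dim(object@traces)
  cat(sprintf("RFScan: %d x %d traces x %d samples (max |p| = %.3g)\n",
              d[1], d[2], d[3], max(abs(object@traces))))
  show(object@geometry)
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume: %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "AcquisitionSchedule", function(object) {
  cat(sprintf("AcquisitionSchedule: %d A-lines in %d pulses @ %g A-lines/s\n",
              object@nALines, object@nPulses, object@alineRate))
  cat(sprintf("  duration %.3g s (~%g s)\n",
              object@duration, object@durationRounded))
})

setMethod("show", "VesselPhantom", function(object) {
  a <- object@absorbers
  cat(sprintf("VesselPhantom: %d absorbers, %d vessels (%s)\n",
              nrow(a), length(unique(a$vessel)),
              paste(sprintf("%s: %d", names(table(a$layer)), table(a$layer)),
                    collapse = ", ")))
})

## ---- acquisition schedule -------------------------------------------------

#' Acquisition schedule of a stepped scan
#'
#' Derives A-line and pulse counts and the scan duration from the geometry:
#' each excitation pulse records \code{nBeams} A-lines in parallel, so the
#' A-line rate is \code{nBeams * prf} and the whole grid takes
#' \code{ceil(nx * ny / nBeams)} pulses. With the default geometry this is
#' 3200 A-lines/s and 9.5 s (~10 s) for the 190 x 160 grid.
#'
#' @param geometry a [ScanGeometry-class].
#' @return an [AcquisitionSchedule-class]; the raw duration is kept in
#'   \code{duration} and its half-up whole-second rounding in
#'   \code{durationRounded}.
#' @export
scanSchedule <- function(geometry) {
  stopifnot(is(geometry, "ScanGeometry"))
  validObject(geometry)
  n <- gridDims(geometry)
  nALines <- as.integer(n[1]) * as.integer(n[2])
  nPulses <- as.integer(ceiling(nALines / geometry@nBeams))
  duration <- nPulses / geometry@prf
  new("AcquisitionSchedule",
      nALines = as.integer(nALines), nPulses = nPulses,
      alineRate = geometry@nBeams * geometry@prf,
      duration = duration,
      durationRounded = floor(duration + 0.5))
}

#' @rdname scanSchedule
#' @param x an AcquisitionSchedule.
#' @export
nALines <- function(x) x@nALines

#' @rdname scanSchedule
#' @export
nPulses <- function(x) x@nPulses

#' @rdname scanSchedule
#' @export
alineRate <- function(x) x@alineRate

#' @rdname scanSchedule
#' @param rounded report the half-up whole-second rounding.
#' @export
scanDuration <- function(x, rounded = FALSE)
  if (rounded) x@durationRounded else x@duration

## ---- stepped-scan assembly ------------------------------------------------

#' Split a scan into per-pulse beam blocks
#'
#' Models the stepped multi-beam acquisition: the detector grid is covered
#' in x-fastest raster order, \code{nBeams} contiguous positions per
#' excitation pulse (the linearly arranged interrogation beams), the block
#' advancing one beam-width per pulse. Each block carries its pulse number
#' and the linear grid indices it covers, so blocks can be re-assembled in
#' any delivery order.
#'
#' @param scan an [RFScan-class].
#' @return list of blocks, each \code{list(pulse, index, traces)} with
#'   \code{traces} a \code{(length(index), nSamples)} matrix.
#' @export
disassembleScan <- function(scan) {
  g <- scan@geometry
  n <- gridDims(g)
  nA <- n[1] * n[2]
  tr <- matrix(scan@traces, nrow = nA)   # linear detector index x samples
  starts <- seq(1L, nA, by = g@nBeams)
  lapply(seq_along(starts), function(p) {
    idx <- starts[p]:min(starts[p] + g@nBeams - 1L, nA)
    list(pulse = p, index = idx, traces = tr[idx, , drop = FALSE])
  })
}

#' Assemble per-pulse beam blocks into an RF scan
#'
#' Inverse of [disassembleScan()]: validates that the delivered blocks
#' cover every grid position exactly once (in any order) and rebuilds the
#' full trace array.
#'
#' @param blocks list of \code{list(pulse, index, traces)} blocks.
#' @param geometry a [ScanGeometry-class].
#' @return an [RFScan-class].
#' @export
assembleScan <- function(blocks, geometry) {
  n <- gridDims(geometry)
  nA <- n[1] * n[2]
  tr <- matrix(NA_real_, nrow = nA, ncol = geometry@nSamples)
  seen <- logical(nA)
  for (b in blocks) {
    idx <- as.integer(b$index)
    if (any(idx < 1L | idx > nA))
      stop("coverage error: grid index ", idx[idx < 1L | idx > nA][1],
           " outside the ", nA, "-position grid")
    dup <- idx[seen[idx]]
    if (length(dup))
      stop("coverage error: grid index ", dup[1], " covered more than once")
    if (nrow(b$traces) != length(idx) || ncol(b$traces) != geometry@nSamples)
      stop("coverage error: block trace matrix does not match its index set")
    tr[idx, ] <- b$traces
    seen[idx] <- TRUE
  }
  if (!all(seen))
    stop("coverage error: grid index ", which(!seen)[1], " not covered")
  RFScan(geometry, array(tr, dim = c(n[1], n[2], geometry@nSamples)))
}
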