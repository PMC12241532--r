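#' @include AllClasses.R geometry.R
NULL

## Scan/volume containers: NIfTI-1 (float64) for the array plus a JSON
## sidecar ("<path>.json") carrying the geometry / spacing metadata at full
## double precision, so read(write(x)) is bit-exact.

.geomToList <- function(g) {
  list(extent_x_mm = g@extentX, extent_y_mm = g@extentY, step_mm = g@step,
       n_beams = g@nBeams, prf_hz = g@prf, fs_hz = g@fs,
       n_samples = g@nSamples, c0_mps = g@c0,
       band_lo_hz = g@bandLo, band_hi_hz = g@bandHi)
}

.geomFromList <- function(meta) {
  need <- c("extent_x_mm", "extent_y_mm", "step_mm", "n_beams", "prf_hz",
            "fs_hz", "n_samples", "c0_mps", "band_lo_hz", "band_hi_hz")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("format error: missing geometry field '", miss[1], "'")
  ScanGeometry(extentX = meta$extent_x_mm, extentY = meta$extent_y_mm,
               step = meta$step_mm, nBeams = meta$n_beams, prf = meta$prf_hz,
               fs = meta$fs_hz, nSamples = meta$n_samples, c0 = meta$c0_mps,
               bandLo = meta$band_lo_hz, bandHi = meta$band_hi_hz)
}

.sidecar <- function(path) paste0(path, ".json")

.writeContainer <- function(arr, path, meta) {
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

.readContainer <- function(path, kind) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (!file.exists(.sidecar(path)))
    stop("format error: missing sidecar '", .sidecar(path), "'")
  meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  if (is.null(meta$container) || meta$container != kind)
    stop("format error: expected container '", kind, "', found '",
         meta$container, "'")
  arr <- array(as.numeric(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  list(meta = meta, arr = arr)
}

#' Scan and volume container I/O
#'
#' Writes an [RFScan-class] or [Volume-class] to a NIfTI-1 file (float64,
#' bit-exact) with a JSON sidecar (\code{<path>.json}) holding the full
#' geometry or spacing metadata; \code{read*} restores the object exactly.
#'
#' @param scan an [RFScan-class].
#' @param volume a [Volume-class].
#' @param path file path (conventionally \code{.nii}; uncompressed output
#'   is byte-reproducible).
#' @return the written path (write) or the restored object (read).
#' @name containerIO
NULL

#' @rdname containerIO
#' @export
writeScan <- function(scan, path) {
  stopifnot(is(scan, "RFScan"))
  validObject(scan)
  .writeContainer(scan@traces, path,
                  c(list(container = "rfscan", format_version = 1L),
                    list(geometry = .geomToList(scan@geometry))))
}

#' @rdname containerIO
#' @export
readScan <- function(path) {
  x <- .readContainer(path, "rfscan")
  if (is.null(x$meta$geometry))
    stop("format error: missing geometry field 'geometry'")
  g <- .geomFromList(x$meta$geometry)
  n <- gridDims(g)
  if (length(dim(x$arr)) != 3 ||
      !all(dim(x$arr) == c(n[1], n[2], g@nSamples)))
    stop("format error: trace array dimension (",
         paste(dim(x$arr), collapse = " x "),
         ") does not match geometry grid (", n[1], " x ", n[2], " x ",
         g@nSamples, ")")
  RFScan(g, x$arr)
}

#' @rdname containerIO
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "Volume"))
  validObject(volume)
  .writeContainer(volume@values, path,
                  list(container = "volume", format_version = 1L,
                       spacing_mm = volume@spacing, origin_mm = volume@origin,
                       info = volume@info))
}

#' @rdname containerIO
#' @export
readVolume <- function(path) {
  x <- .readContainer(path, "volume")
  for (f in c("spacing_mm", "origin_mm"))
    if (is.null(x$meta[[f]]))
      stop("format error: missing field '", f, "'")
  info <- x$meta$info
  if (is.null(info)) info <- list() else info <- as.list(info)
  Volume(x$arr, spacing = x$meta$spacing_mm, origin = x$meta$origin_mm,
         info = info)
}

#' Export a volume as a multi-page TIFF stack
#'
#' One 32-bit float page per z slice, intensities rescaled to \[0, 1\]
#' (enhanced volumes already are). Voxel spacing is recorded in a JSON
#' sidecar.
#'
#' @param volume a [Volume-class].
#' @param path output \code{.tif} path.
#' @return the written path, invisibly.
#' @export
exportTiffStack <- function(volume, path) {
  v <- volume@values
  vmax <- max(v)
  if (vmax > 1 || min(v) < 0) {
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  }
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) t(v[, , k])[, , drop = FALSE])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(spacing_mm = volume@spacing,
                            origin_mm = volume@origin),
                       .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export an image as PNG with scale metadata
#'
#' @param image numeric matrix in \[0, 1\] (grey) or \code{h x w x 3} RGB
#'   array.
#' @param path output \code{.png} path.
#' @param mmPerPx pixel pitch, mm (stored in a tEXt chunk and a JSON
#'   sidecar).
#' @return the written path, invisibly.
#' @export
exportPng <- function(image, path, mmPerPx = NA_real_) {
  img <- pmin(pmax(image, 0), 1)
  if (is.matrix(img)) img <- t(img)[rev(seq_len(ncol(img))), , drop = FALSE]
  ok <- try(png::writePNG(img, path,
                          text = c(mm_per_px = format(mmPerPx))),
            silent = TRUE)
  if (inherits(ok, "try-error")) png::writePNG(img, path)
  jsonlite::write_json(list(mm_per_px = mmPerPx), .sidecar(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
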