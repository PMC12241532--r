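#' @include AllClasses.R geometry.R
NULL

.axisIndex <- function(axis) {
  if (is.character(axis)) match(axis, c("x", "y", "z"))
  else as.integer(axis)
}

#' Slab maximum intensity projection
#'
#' Per-pixel maximum of the volume over a restricted coordinate range along
#' the projection axis, together with the position of that maximum (the
#' depth-of-max map for z projections). Slab bounds are half-open
#' \code{[lo, hi)}. [defaultSlabs()] returns the standard z presets
#' (0.05-0.5, 0.5-1.5 and 1.5-5 mm) that separate the superficial, mid and
#' deep vascular layers.
#'
#' @param volume a [Volume-class].
#' @param axis projection axis: "x", "y", "z" or 1:3.
#' @param range \code{c(lo, hi)} in mm along the axis (NULL: full extent).
#' @return \code{list(image, posOfMax, axis, range, pixelSpacing)};
#'   \code{image} and \code{posOfMax} are matrices over the two remaining
#'   axes (in axis order), \code{posOfMax} in mm.
#' @export
slabMip <- function(volume, axis = "z", range = NULL) {
  ax <- .axisIndex(axis)
  if (is.na(ax)) stop("axis must be one of x, y, z")
  v <- volume@values
  d <- dim(v)
  coord <- volume@origin[ax] + (seq_len(d[ax]) - 1) * volume@spacing[ax]
  if (is.null(range)) range <- c(coord[1], coord[d[ax]] + 1e-9)
  keep <- which(coord >= range[1] & coord < range[2])
  if (!length(keep))
    stop("empty slab: no voxels with ", c("x", "y", "z")[ax], " in [",
         range[1], ", ", range[2], ")")
  perm <- c(setdiff(1:3, ax), ax)
  vp <- aperm(v, perm)[, , keep, drop = FALSE]
  dp <- dim(vp)
  m <- matrix(vp, nrow = dp[1] * dp[2])
  imax <- max.col(m, ties.method = "first")
  img <- matrix(m[cbind(seq_len(nrow(m)), imax)], dp[1], dp[2])
  pos <- matrix(coord[keep][imax], dp[1], dp[2])
  list(image = img, posOfMax = pos, axis = c("x", "y", "z")[ax],
       range = range,
       pixelSpacing = volume@spacing[setdiff(1:3, ax)])
}

#' @rdname slabMip
#' @export
defaultSlabs <- function() {
  list(superficial = c(0.05, 0.5), mid = c(0.5, 1.5), deep = c(1.5, 5))
}

#' Depth-encoded maximum intensity projection
#'
#' Full-depth z MIP coloured by the depth of the maximum: hue from depth
#' through a 256-bin colormap, brightness from the MIP intensity
#' (normalised to \[0, 1\]). Invertible to (intensity, depth) up to
#' colormap quantisation via [decodeDepthMip()].
#'
#' @param volume a [Volume-class].
#' @param colormap a palette name accepted by
#'   [grDevices::hcl.colors()] (default "viridis").
#' @param nBins colormap bins.
#' @return \code{list(rgb, colormap, nBins, depthRange, pixelSpacing)} with
#'   \code{rgb} an \code{nx x ny x 3} array in \[0, 1\].
#' @export
depthEncodedMip <- function(volume, colormap = "viridis", nBins = 256L) {
  hit <- match(tolower(colormap), tolower(grDevices::hcl.pals()))
  if (is.na(hit))
    stop("unknown colormap '", colormap, "'")
  colormap <- grDevices::hcl.pals()[hit]
  mip <- slabMip(volume, axis = "z")
  img <- mip$image
  vmax <- max(img)
  inten <- if (vmax > 0) img / vmax else img
  zr <- base::range(mip$posOfMax)
  if (diff(zr) == 0) zr[2] <- zr[1] + 1e-9
  bin <- pmin(nBins, 1L + floor((mip$posOfMax - zr[1]) / diff(zr) *
                                  (nBins - 1L) + 0.5))
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(nBins, colormap)) / 255)
  rgb <- array(0, dim = c(dim(img), 3))
  for (ch in 1:3)
    rgb[, , ch] <- matrix(pal[bin, ch], nrow(img), ncol(img)) * inten
  list(rgb = rgb, colormap = colormap, nBins = as.integer(nBins),
       depthRange = zr, pixelSpacing = mip$pixelSpacing)
}

#' Decode a depth-encoded MIP
#'
#' Recovers the intensity and depth maps from [depthEncodedMip()] output by
#' matching each pixel's chromatic direction against the colormap; exact up
#' to colormap quantisation (zero-intensity pixels have undefined depth,
#' returned as NA).
#'
#' @param encoded the list returned by [depthEncodedMip()].
#' @return \code{list(intensity, depth)} matrices (depth in mm).
#' @export
decodeDepthMip <- function(encoded) {
  pal <- t(grDevices::col2rgb(
    grDevices::hcl.colors(encoded$nBins, encoded$colormap)) / 255)
  paln <- pal / sqrt(rowSums(pal^2))
  d <- dim(encoded$rgb)
  px <- matrix(encoded$rgb, nrow = d[1] * d[2])
  nrm <- sqrt(rowSums(px^2))
  depth <- matrix(NA_real_, d[1], d[2])
  inten <- matrix(0, d[1], d[2])
  nz <- nrm > 0
  if (any(nz)) {
    sim <- (px[nz, , drop = FALSE] / nrm[nz]) %*% t(paln)
    bin <- max.col(sim, ties.method = "first")
    zr <- encoded$depthRange
    depth[nz] <- zr[1] + (bin - 1) / (encoded$nBins - 1) * diff(zr)
    inten[nz] <- nrm[nz] / sqrt(rowSums(pal^2))[bin]
  }
  list(intensity = inten, depth = depth)
}

#' Crop surface layers of a volume
#'
#' Zeroes the first \code{nLayers} z slices (extent preserved so
#' coordinates stay valid); used to suppress the contact-surface artifacts
#' and bubbles that dominate the first layers of a rendering.
#'
#' @param volume a [Volume-class].
#' @param nLayers number of z slices to zero (must be < nz).
#' @return a [Volume-class].
#' @export
cropSurface <- function(volume, nLayers) {
  nz <- dim(volume@values)[3]
  if (nLayers < 0 || nLayers >= nz)
    stop("nLayers must lie in [0, nz)")
  v <- volume@values
  if (nLayers > 0) v[, , seq_len(nLayers)] <- 0
  Volume(v, spacing = volume@spacing, origin = volume@origin,
         info = volume@info)
}

#' Count bright connected components in a MIP image
#'
#' Thresholds the image at a fraction of its maximum and counts 8-connected
#' components (via \code{EBImage::bwlabel}); the vessel count of a
#' projection for well-separated vasculature.
#'
#' @param image numeric matrix (e.g. \code{slabMip(...)$image}).
#' @param threshold fraction of the image maximum (default half-max).
#' @return integer component count.
#' @export
componentCount <- function(image, threshold = 0.5) {
  mx <- max(image)
  if (mx <= 0) return(0L)
  bw <- image >= threshold * mx
  as.integer(max(EBImage::bwlabel(bw)))
}
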