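#' @include AllClasses.R geometry.R containers-io.R phantom.R forward.R preprocess.R recon.R enhance.R render.R
NULL

#' Pipeline configuration schema
#'
#' The published set of allowed configuration keys, as a nested named list
#' mirroring the YAML layout; [readPipelineConfig()] rejects any key not
#' present here (reporting its field path).
#'
#' @return nested named list; leaves describe the expected type.
#' @export
configSchema <- function() {
  layer <- list(depth = "numeric(2)", radius = "numeric(2)", n = "count",
                length = "numeric(2)", branch_prob = "fraction",
                motif_prob = "fraction")
  list(
    seed = "integer",
    geometry = list(extent_x = "mm", extent_y = "mm", step = "mm",
                    n_beams = "count", prf = "Hz", fs = "Hz",
                    n_samples = "count", c0 = "m/s", band_lo = "Hz",
                    band_hi = "Hz"),
    phantom = list(layer_spec = list(superficial = layer, mid = layer,
                                     deep = layer),
                   min_separation = "mm"),
    simulate = list(spacing = "mm", snr_db = "dB",
                    sensitivity = "logical", depth_max = "mm"),
    illumination = list(beam_diameter = "mm", mu_eff = "1/mm",
                        pulse_energy = "mJ"),
    attenuation = list(alpha0 = "dB/cm/MHz^y", power = "exponent"),
    preprocess = list(cutoff_hz = "Hz", wavelet_family = "name",
                      wavelet_levels = "count",
                      sensitivity_floor = "fraction"),
    recon = list(method = "kspace|time_reversal", c = "m/s",
                 autofocus = list(enabled = "logical", c_min = "m/s",
                                  c_max = "m/s", c_step = "m/s"),
                 n_iter = "count", tol = "fraction", nonneg = "logical",
                 pad_factor = "count", lateral_upsample = "count"),
    enhance = list(mu_eff = "1/mm", comp_cap = "factor", sig_k = "slope",
                   sig_x0 = "midpoint", dyn_range_db = "dB",
                   crop_layers = "count"),
    render = list(slabs = "named list of numeric(2)", colormap = "name")
  )
}

.checkKeys <- function(cfg, schema, path = "") {
  if (!is.list(cfg)) return(invisible())
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema))
      stop("schema violation at '", here, "': unknown key")
    if (is.list(schema[[nm]]) && !nm %in% c("slabs"))
      .checkKeys(cfg[[nm]], schema[[nm]], here)
  }
  invisible()
}

#' Default pipeline configuration
#'
#' A small, fast demonstration configuration (a few vessels over a reduced
#' detector patch); the full-sensor study geometry is obtained by raising
#' \code{geometry} to the [ScanGeometry()] defaults.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    geometry = list(extent_x = 3.2, extent_y = 3.2, step = 0.1,
                    n_beams = 32L, prf = 100, fs = 60e6,
                    n_samples = 512L, c0 = 1540, band_lo = 2e6,
                    band_hi = 15e6),
    phantom = list(
      layer_spec = list(
        superficial = list(depth = c(0.3, 0.7), radius = c(0.06, 0.1),
                           n = 2L, length = c(1.5, 2.5), branch_prob = 0,
                           motif_prob = 0),
        mid = list(depth = c(0.9, 1.6), radius = c(0.1, 0.16), n = 1L,
                   length = c(2, 3), branch_prob = 0, motif_prob = 0)),
      min_separation = 1.0),
    simulate = list(spacing = 0.05, snr_db = 30, sensitivity = TRUE,
                    depth_max = 2.5),
    illumination = list(beam_diameter = 30, mu_eff = 0.5,
                        pulse_energy = 18),
    attenuation = NULL,
    preprocess = list(cutoff_hz = 0.5e6, wavelet_family = "d4",
                      wavelet_levels = 4L, sensitivity_floor = 0.2),
    recon = list(method = "kspace", c = NULL,
                 autofocus = list(enabled = TRUE, c_min = 1490,
                                  c_max = 1590, c_step = 10),
                 n_iter = 5L, tol = 1e-3, nonneg = TRUE,
                 pad_factor = 2L, lateral_upsample = 1L),
    enhance = list(mu_eff = 0.5, comp_cap = 10, sig_k = NULL,
                   sig_x0 = NULL, dyn_range_db = 40, crop_layers = 4L),
    render = list(slabs = list(superficial = c(0.05, 0.5),
                               mid = c(0.5, 1.5), deep = c(1.5, 5)),
                  colormap = "viridis")
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys against
#' [configSchema()], and merges the result over [defaultPipelineConfig()].
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("missing input: config file '", path, "'")
  cfg <- yaml::read_yaml(path)
  .checkKeys(cfg, configSchema())
  .mergeConfig(defaultPipelineConfig(), cfg)
}

.configGeometry <- function(config) {
  g <- config$geometry
  ScanGeometry(extentX = g$extent_x, extentY = g$extent_y, step = g$step,
               nBeams = g$n_beams, prf = g$prf, fs = g$fs,
               nSamples = g$n_samples, c0 = g$c0, bandLo = g$band_lo,
               bandHi = g$band_hi)
}

.configLayerSpec <- function(ls) {
  lapply(ls, function(l)
    list(depth = as.numeric(l$depth), radius = as.numeric(l$radius),
         n = as.integer(l$n), length = as.numeric(l$length),
         branchProb = l$branch_prob %||% 0,
         motifProb = l$motif_prob %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stages
#'
#' Each stage reads and writes the standard containers so stages compose
#' exactly as [runPipeline()] chains them: simulate a scan from the
#' configured phantom, preprocess it, reconstruct a volume, enhance it,
#' render MIP images.
#'
#' @param config configuration list (see [readPipelineConfig()]).
#' @param input path of the stage input container.
#' @param out output path (a directory for \code{stageRender}).
#' @param seed optional seed overriding \code{config$seed}.
#' @return the output path(s), invisibly.
#' @name pipelineStages
NULL

#' @rdname pipelineStages
#' @export
stageSimulate <- function(config, out, seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  geom <- .configGeometry(config)
  ph <- makeVesselTree(seed,
                       layerSpec = .configLayerSpec(config$phantom$layer_spec),
                       box = list(x = c(0, geom@extentX),
                                  y = c(0, geom@extentY)),
                       minSeparation = config$phantom$min_separation %||% 0)
  mu <- rasterize(ph, spacing = config$simulate$spacing,
                  box = list(x = c(0, geom@extentX),
                             y = c(0, geom@extentY),
                             z = c(0, config$simulate$depth_max)))
  illum <- IlluminationModel(beamDiameter = config$illumination$beam_diameter,
                             muEff = config$illumination$mu_eff,
                             pulseEnergy = config$illumination$pulse_energy)
  p0 <- applyFluence(mu, illum)
  atten <- if (!is.null(config$attenuation))
    AttenuationModel(config$attenuation$alpha0, config$attenuation$power)
  scan <- forwardProject(p0, geom, atten = atten)
  if (isTRUE(config$simulate$sensitivity))
    scan <- applySensorInhomogeneity(scan, defaultSensitivityMap(geom))
  if (!is.null(config$simulate$snr_db) && is.finite(config$simulate$snr_db))
    scan <- addNoise(scan, config$simulate$snr_db, seed + 1L)
  writeScan(scan, out)
}

#' @rdname pipelineStages
#' @export
stagePreprocess <- function(input, config, out) {
  if (!file.exists(input)) stop("missing input: '", input, "'")
  scan <- readScan(input)
  scan <- highpass(scan, config$preprocess$cutoff_hz)
  scan <- waveletDenoise(scan, config$preprocess$wavelet_family,
                         config$preprocess$wavelet_levels)
  if (isTRUE(config$simulate$sensitivity))
    scan <- sensitivityCorrect(scan, defaultSensitivityMap(scan@geometry),
                               config$preprocess$sensitivity_floor)
  writeScan(scan, out)
}

#' @rdname pipelineStages
#' @export
stageReconstruct <- function(input, config, out) {
  if (!file.exists(input)) stop("missing input: '", input, "'")
  scan <- readScan(input)
  rc <- config$recon
  cUse <- rc$c %||% scan@geometry@c0
  if (isTRUE(rc$autofocus$enabled)) {
    af <- autofocusSoS(scan, seq(rc$autofocus$c_min, rc$autofocus$c_max,
                                 by = rc$autofocus$c_step),
                       padFactor = rc$pad_factor)
    cUse <- af$cBest
    utils::write.csv(af$scores, paste0(out, ".scores.csv"),
                     row.names = FALSE)
  }
  vol <- if (identical(rc$method, "time_reversal")) {
    atten <- if (!is.null(config$attenuation))
      AttenuationModel(config$attenuation$alpha0, config$attenuation$power)
    timeReversal(scan, ReconParams(c = cUse, atten = atten,
                                   nIter = rc$n_iter, tol = rc$tol,
                                   nonneg = rc$nonneg),
                 padFactor = rc$pad_factor)
  } else {
    kspaceReconstruct(scan, c = cUse, padFactor = rc$pad_factor,
                      lateralUpsample = rc$lateral_upsample)
  }
  writeVolume(vol, out)
}

#' @rdname pipelineStages
#' @export
stageEnhance <- function(input, config, out) {
  if (!file.exists(input)) stop("missing input: '", input, "'")
  vol <- readVolume(input)
  en <- config$enhance
  params <- EnhanceParams(muEff = en$mu_eff, compCap = en$comp_cap,
                          sigK = en$sig_k, sigX0 = en$sig_x0,
                          dynRangeDb = en$dyn_range_db)
  vol <- enhanceVolume(vol, params,
                       beamDiameter = config$illumination$beam_diameter)
  vol <- cropSurface(vol, min(en$crop_layers, dim(vol@values)[3] - 1L))
  writeVolume(vol, out)
}

#' @rdname pipelineStages
#' @export
stageRender <- function(input, config, out) {
  if (!file.exists(input)) stop("missing input: '", input, "'")
  vol <- readVolume(input)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  zmax <- vol@origin[3] + (dim(vol@values)[3] - 1) * vol@spacing[3]
  for (nm in names(config$render$slabs)) {
    rng <- as.numeric(config$render$slabs[[nm]])
    if (rng[1] >= zmax) next
    mip <- slabMip(vol, axis = "z", range = rng)
    p <- file.path(out, paste0("mip_", nm, ".png"))
    mx <- max(mip$image)
    exportPng(if (mx > 0) mip$image / mx else mip$image, p,
              mmPerPx = mip$pixelSpacing[1])
    written <- c(written, p)
  }
  enc <- depthEncodedMip(vol, config$render$colormap)
  p <- file.path(out, "mip_depth_encoded.png")
  png::writePNG(aperm(enc$rgb, c(2, 1, 3))[rev(seq_len(dim(enc$rgb)[2])), , ,
                                           drop = FALSE], p)
  written <- c(written, p)
  p <- file.path(out, "volume.tif")
  exportTiffStack(vol, p)
  invisible(c(written, p))
}

#' Run the full pipeline
#'
#' Chains simulate, preprocess, reconstruct, enhance and render, writing
#' every intermediate container plus a JSON run manifest (config hash,
#' seed, versions, per-stage timings, output list) to \code{outdir}.
#' Identical config and seed reproduce bit-identical containers and
#' images.
#'
#' @param config a configuration list or a YAML path.
#' @param outdir output directory.
#' @param seed optional seed overriding \code{config$seed}.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else .checkKeys(config, configSchema())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed)
  config$seed <- seed
  cfgFile <- file.path(outdir, "config.json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- list(scan = file.path(outdir, "scan.nii"),
                preprocessed = file.path(outdir, "scan_preprocessed.nii"),
                volume = file.path(outdir, "volume.nii"),
                enhanced = file.path(outdir, "volume_enhanced.nii"),
                render = file.path(outdir, "render"))
  timings <- list()
  tstage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    fun()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  tstage("simulate", function() stageSimulate(config, paths$scan, seed))
  tstage("preprocess",
         function() stagePreprocess(paths$scan, config, paths$preprocessed))
  tstage("reconstruct",
         function() stageReconstruct(paths$preprocessed, config,
                                     paths$volume))
  tstage("enhance",
         function() stageEnhance(paths$volume, config, paths$enhanced))
  tstage("render",
         function() stageRender(paths$enhanced, config, paths$render))
  manifest <- list(
    config_file = basename(cfgFile),
    config_md5 = unname(tools::md5sum(cfgFile)),
    seed = seed,
    package_version = as.character(utils::packageVersion("fptomo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timings_s = timings,
    outputs = lapply(paths, basename))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
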