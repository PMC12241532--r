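Package: fptomo
Title: Planar Fabry-Perot Photoacoustic Tomography: Simulation,
    Reconstruction and Rendering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation and image formation for photoacoustic
    tomography with a planar Fabry-Perot interferometer (FPI) ultrasound
    sensor. Provides the acquisition model of a stepped multi-beam
    interrogation scan, a layered vascular phantom generator with Gaussian
    illumination and exponential fluence decay, band-limited spherical-wave
    forward projection with optional power-law acoustic attenuation and
    FPI sensitivity banding, trace preprocessing (zero-phase high-pass,
    wavelet soft-threshold denoising, sensitivity correction), planar
    k-space (FFT) reconstruction, iterative time reversal with attenuation
    compensation, autofocus sound-speed selection by a global image
    gradient metric, fluence compensation, sigmoid normalization and
    logarithmic compression, and maximum-intensity-projection rendering
    with depth colour encoding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'containers-io.R'
    'dwt.R'
    'phantom.R'
    'enhance.R'
    'forward.R'
    'fptomo-package.R'
    'render.R'
    'recon.R'
    'preprocess.R'
    'pipeline.R'
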