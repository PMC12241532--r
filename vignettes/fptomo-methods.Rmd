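---
title: "Image formation for planar Fabry-Perot photoacoustic tomography"
author: "fptomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image formation for planar Fabry-Perot photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`fptomo` models the full image-formation chain of a photoacoustic
tomograph built around a planar Fabry-Perot interferometer (FPI)
ultrasound sensor, and provides a synthetic-data generator so that every
stage can be verified without instrument data. The physical picture: a
nanosecond laser pulse with a Gaussian lateral profile illuminates tissue
through the optically transparent sensor; optical absorption by
hemoglobin launches broadband ultrasound; focused interrogation beams
sample the FPI film on a regular grid, each grid point acting as one
point-like broadband detector on the plane $z = 0$.

## Acquisition model

A `ScanGeometry` fixes the detector grid and timing. The defaults are the
integrated system's settings: a $19 \times 16$ mm sensor area scanned at
100 µm pitch (grid $190 \times 160$, half-open, detector $(i_x, i_y)$ at
$(i_x \Delta, i_y \Delta)$), 32 linearly arranged interrogation beams
stepped by one position per excitation pulse at a 100 Hz pulse repetition
frequency, traces sampled at 60 MHz over a 2–15 MHz detection band.
`scanSchedule()` derives the acquisition arithmetic: $32 \times 100 =
3200$ A-lines/s, $\lceil 190 \cdot 160 / 32 \rceil = 950$ pulses, a 9.5 s
scan reported as both the raw value and its half-up rounding (10 s).
`disassembleScan()` / `assembleScan()` model the per-pulse beam blocks:
blocks carry explicit grid indices, so assembly is order-invariant and
validates exact single coverage.

The sound speed is *not* treated as a known constant anywhere: the
geometry's `c0 = 1540` m/s is only the soft-tissue convention used as a
starting value, and reconstruction normally replaces it by autofocus
selection (below).

## Synthetic phantoms and the forward model

`makeVesselTree()` draws layered vessel phantoms: a superficial web of
fine vessels (defaults: 0.05–0.5 mm depth, radii 20–50 µm, i.e. diameters
under 100 µm), a mid layer (0.5–1.5 mm, 60–200 µm radii) and a deep layer
of large branching vessels (1.5–5 mm, 0.25–0.75 mm radii). Radii grow and
counts shrink with depth; deeper layers branch more and may emit
parallel-vessel pairs/triplets (one trunk plus one or two offset thinner
companions — the artery-with-veins motif). Every draw is a pure function
of the seed. An optional `minSeparation` rejection-samples trunk
placements until their lateral centreline clearance exceeds the request —
used by the well-separated test fixtures. `rasterize()` voxelises the
absorber list with $3^3$ partial-volume subsampling.

`applyFluence()` converts absorption $\mu_a$ into initial pressure
$p_0 = \mu_a \, G(x, y) \, e^{-\mu_{\mathrm{eff}} z}$, with $G$ a
unit-peak Gaussian of 1/e² diameter 30 mm (the beam fills the sensor) and
$\mu_{\mathrm{eff}}$ the effective optical attenuation (default
0.5 mm⁻¹, a mid-range soft-tissue value; in the instrument this knob is
adjusted manually). The Grüneisen factor is absorbed into the arbitrary
units.

`forwardProject()` computes the traces as a superposition of spherical
waves: each source voxel contributes amplitude $\propto 1/r$ at delay
$r/c_0$. The pressure response of an impulsive point absorber is the
*time derivative* of the delayed delta (the N-wave of the acoustic
initial-value problem); this derivative is folded into the detection
kernel together with the band-pass. Without it, the exact planar
inversion — which assumes wave-equation data — mislocalises sources
axially and the forward/backward operator pair is inconsistent.
`bandpass = FALSE` yields raw delayed deltas for arrival-time
diagnostics. The detector band is a raised-cosine-edged passband, flat
between the −6 dB edges at 2 and 15 MHz (the FPI's stated range; the true
impulse response is unpublished, so a smooth, in-band-invertible shape
was chosen). Detectors are ideal points: the interrogation-spot size is
unpublished and spatial averaging is deliberately not modelled.

Optional power-law acoustic attenuation applies
$\alpha_0 f^y$ dB/cm over each exact source–detector path (defaults
$\alpha_0 = 0.5$ dB cm⁻¹ MHz⁻¹·¹, $y = 1.1$, the soft-tissue convention;
the instrument's values are unpublished). `applySensorInhomogeneity()`
imposes the FPI's characteristic sensitivity pattern — by default three
vertical bands of relative gain 1.0/0.7/0.85 with a smooth low-frequency
ripple along $y$ — and `addNoise()` adds white Gaussian noise scaled to
an exact realised SNR, deterministically per seed.

## Preprocessing

Traces are conditioned before inversion:

* `highpass()` — 4th-order Butterworth applied forward and backward
  (zero phase), default cutoff 0.5 MHz. Odd-reflection padding long
  enough for the filter transient ($3 f_s / f_c$ samples) keeps edge
  artifacts out of the trace. DC rejection is below −60 dB and in-band
  amplitude change under 1 %.
* `waveletDenoise()` — per-trace periodized orthonormal Daubechies 4-tap
  decomposition (4 levels), soft thresholding of all detail coefficients
  at the universal threshold $\hat\sigma \sqrt{2 \ln n}$ with
  $\hat\sigma$ the MAD of the finest-scale details / 0.6745. The
  transform is orthonormal, so energy never increases. The filter pair is
  computed in closed form from $\sqrt 3$; no wavelet library is used.
* `sensitivityCorrect()` — division by the detector gain floored at 0.2,
  the exact inverse of the applied inhomogeneity wherever the gain is
  above the floor; the floor bounds noise amplification in dead zones.

## Reconstruction

`kspaceReconstruct()` is the standard one-step FFT inversion for planar
detection: 3-D FFT of the (time-zero-padded) traces, remapping of
temporal frequency onto the axial wavenumber through the dispersion
relation $\omega = c\sqrt{k_x^2 + k_y^2 + k_z^2}$ with the Jacobian
weight $k_z / |k|$, evanescent components zeroed, inverse FFT. The
spectral remapping uses 4-point Lagrange interpolation: the spectra
oscillate at a rate set by the arrival delay, and linear interpolation
leaves several-percent inconsistencies between the forward and backward
propagators that dominate the time-reversal residual. The native grid is
the detector grid laterally and $c / f_s$ per sample axially
(≈ 25.7 µm at 1540 m/s); `lateralUpsample` performs exact band-limited
(spectral zero-padding) lateral refinement and `resampleVolume()`
trilinear resampling, e.g. to the 50 µm display grid. Time is
zero-padded twofold to suppress wrap-around.

`timeReversal()` refines iteratively: back-propagate the (optionally
attenuation-compensated) traces, re-project the estimate with the exact
k-space forward propagator, back-propagate the trace residual, add the
correction, and project onto non-negative values (default on; off it is
a purely linear scheme). It stops after `nIter` (default 5) iterations or
when the relative trace residual falls below `tol` (default $10^{-3}$),
warns and returns the best iterate if the residual grows twice in a row,
and logs the residual path in `volInfo()`. Attenuation compensation
amplifies each of 12 frequency bands by the power-law loss over the
time-equivalent path $c t$, capped at +20 dB so the amplifying filter
cannot blow up noise. These counts and tolerances are the package's own
choices; the instrument's are unpublished.

### Autofocus sound-speed selection

`autofocusSoS()` reconstructs at each candidate speed and maximises a
global image-gradient focus functional, ties broken toward the smallest
candidate, returning the full score table for audit. One design point
deserves emphasis. The obvious functional — the raw sum of gradient
magnitudes of the signed image, which `sharpness()` computes — turns out
to be *minimised* near the true speed on band-passed photoacoustic
images: a zero-DC, sign-oscillating image concentrates into fewer, larger
lobes as it focuses, which lowers its total variation, and the overall
reconstruction amplitude varies systematically with the assumed speed.
`focusScore()` therefore evaluates the squared gradient of the *modulus*
image normalised by the image energy, which is scale-invariant and peaks
at focus; on seeded vessel fixtures it recovers the simulated speed
within one 10 m/s grid step. `sharpness()` is retained as the documented
raw metric.

## Enhancement and rendering

Enhancement is applied in the fixed order fluence compensation → sigmoid
normalization → logarithmic compression (`enhanceVolume()`):

* `fluenceCompensate()` divides by $G(x,y) e^{-\mu_{\mathrm{eff}} z}$,
  the exact inverse of the illumination model, with the correction capped
  (default 10×) to bound noise amplification at depth.
* `sigmoidNormalize()` is the logistic stretch
  $1/(1 + e^{-k (v - x_0)})$. Defaults $x_0 = \mathrm{median}$,
  $k = 4/\mathrm{IQR}$ suit dense vascular volumes; for sparse volumes
  (mostly background) the median sits in the background and should be
  overridden, as the test fixtures do.
* `logCompress()` maps to decibels over a dynamic range (default 40 dB),
  maximum at 1, floor at 0.

`slabMip()` produces per-pixel maxima with the position of the maximum
over half-open coordinate slabs; the `defaultSlabs()` presets
(0.05–0.5, 0.5–1.5, 1.5–5 mm) separate the superficial, mid and deep
vascular layers. `depthEncodedMip()` colours the full-depth MIP by depth
of maximum through a 256-bin perceptually uniform colormap (viridis), and
`decodeDepthMip()` inverts it up to colormap quantisation.
`cropSurface()` zeroes the first z slices, which in practice contain only
contact artifacts and bubbles, preserving the coordinate frame.
`componentCount()` (8-connected labelling above half-maximum) turns a MIP
into a vessel count for well-separated fixtures.

# Containers, configuration, pipeline

Scans and volumes are written as NIfTI-1 files (float64, bit-exact) with
a JSON sidecar holding the complete geometry/spacing metadata at 17
significant digits, so `read(write(x))` reproduces `x` exactly; volumes
additionally export as 32-bit float TIFF stacks and rendered images as
PNG with mm/px metadata. The YAML pipeline configuration validates
against the published `configSchema()` — unknown keys are rejected with
their field path. `runPipeline()` chains simulate → preprocess →
reconstruct → enhance → render, writes every intermediate container and a
JSON manifest (config hash, seed, versions, per-stage timings), and is
bit-reproducible for a fixed config and seed. The same stages are exposed
individually and through the `inst/cli/fptomo.R` command-line entry
point.

# Numerical choices and degenerate inputs

* FFT remapping: 4-point Lagrange along the frequency axis; bins whose
  stencil would cross the Nyquist boundary contribute zero.
* The forward k-space propagator caps the obliquity weight $|k|/k_z$ at
  100 (grazing waves).
* All-zero inputs: reconstruction of an all-zero scan is an all-zero
  volume; `logCompress()` refuses an all-zero volume; `addNoise()`
  refuses a finite SNR on an all-zero scan; autofocus on an all-zero scan
  returns the smallest candidate by the tie-break rule.
* Geometry validation rejects extents that are not integer multiples of
  the pitch (tolerance $10^{-9}$ on the ratio), beams exceeding the x
  grid, and bands reaching Nyquist.
* Rasterization warns (and proceeds) when the voxel size does not resolve
  the smallest radius with two voxels, or when absorbers are clipped by
  the box.

# What the simulations do and do not show

The generator reproduces the features that drive the image-formation
chain: band-limited N-wave traces from layered vasculature, Gaussian
illumination with exponential depth decay, banded sensor sensitivity,
power-law acoustic attenuation and white noise. It deliberately omits
acoustic heterogeneity and refraction, shear waves, nonlinearity,
speckle-like sub-resolution absorber textures, finite detector size and
motion. Passing tests therefore demonstrate the correctness and internal
consistency of the implementation under the stated physics, not imaging
performance on real tissue.

Problem sizes used by the tests and the acceptance analysis were chosen
to exercise the full chain at desk scale: $64 \times 64$ detector patches
with 1024-sample traces for the point-spread analysis, $32 \times 32$
patches with 256 samples for the iterative and end-to-end studies, ten
seeds per stochastic claim.

One acceptance-level observation is worth recording here. With a 100 µm
detector pitch, any linearly reconstructed image has its lateral spectrum
truncated at the Nyquist wavenumber $\pi / 0.1$ mm⁻¹; the corresponding
sinc main-lobe bound on the amplitude-profile FWHM is
$3.791 / k_{\mathrm{Nyq}} \approx 121$ µm, and the dispersion-shell
weighting of the exact inversion widens the measured value to ≈ 131 µm.
A sub-100 µm *vessel visibility* (detectability of sub-pitch absorbers,
which land on individual detector columns with high contrast) is
entirely consistent with this; a sub-100 µm amplitude-PSF width is not
achievable at this pitch, and the package reports the honest figure.

# Worked example

```{r, eval = FALSE}
library(fptomo)

geom <- ScanGeometry()          # the integrated system's geometry
scanSchedule(geom)              # 3200 A-lines/s, 9.5 s (~10 s)

## simulate a small patch end to end
cfg <- defaultPipelineConfig()
runPipeline(cfg, "run1")        # scan.nii ... render/mip_*.png + manifest
```
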