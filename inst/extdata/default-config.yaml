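# Demonstration pipeline configuration: a reduced detector patch with a
# few simulated vessels, preprocessed, reconstructed with autofocus
# sound-speed selection and rendered as depth-encoded MIPs.
# All keys are validated against fptomo::configSchema(); units are noted
# in the schema (mm, Hz, m/s, dB).
seed: 1
geometry:
  extent_x: 3.2
  extent_y: 3.2
  step: 0.1
  n_beams: 32
  prf: 100
  fs: 60.0e+6
  n_samples: 512
  c0: 1540
  band_lo: 2.0e+6
  band_hi: 15.0e+6
phantom:
  layer_spec:
    superficial:
      depth: [0.3, 0.7]
      radius: [0.06, 0.1]
      n: 2
      length: [1.5, 2.5]
      branch_prob: 0
      motif_prob: 0
    mid:
      depth: [0.9, 1.6]
      radius: [0.1, 0.16]
      n: 1
      length: [2, 3]
      branch_prob: 0
      motif_prob: 0
  min_separation: 1.0
simulate:
  spacing: 0.05
  snr_db: 30
  sensitivity: true
  depth_max: 2.5
illumination:
  beam_diameter: 30
  mu_eff: 0.5
  pulse_energy: 18
preprocess:
  cutoff_hz: 0.5e+6
  wavelet_family: d4
  wavelet_levels: 4
  sensitivity_floor: 0.2
recon:
  method: kspace
  autofocus:
    enabled: true
    c_min: 1490
    c_max: 1590
    c_step: 10
  pad_factor: 2
  lateral_upsample: 1
enhance:
  mu_eff: 0.5
  comp_cap: 10
  dyn_range_db: 40
  crop_layers: 4
render:
  slabs:
    superficial: [0.05, 0.5]
    mid: [0.5, 1.5]
    deep: [1.5, 5]
  colormap: viridis
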