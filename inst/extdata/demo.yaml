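# Demo pipeline: 2-sphere anechoic phantom, 36-frame rotational sweep at
# 48^2, quick INR fit, sampling and hull volumetry. Runs in about a minute
# on one CPU.
seed: 5
geometry:
  sweep_deg: 180
  step_deg: 5
  axial_extent_mm: 40
  lateral_extent_mm: 40
  rows: 48
  cols: 48
phantom:
  n_spheres: 2
  radius_range_mm: [6, 10]
  anechoic: true
  speckle_scale: 0
inr:
  pe_bands: 4
  n_layers: 4
  width: 16
loss:
  w_image: 1
  w_seg: 1
train:
  epochs: 40
  lr_init: 3.0e-4
sample:
  spacing_mm: 1
  threshold: 0.5
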