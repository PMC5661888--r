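# Desk-scale smoke experiment: a small phantom cohort, the tiny network
# preset and a short schedule. Completes on one CPU well inside a coffee
# break; see the methods vignette for how these sizes were chosen.
seed: 2024
phantoms:
  n_phantoms: 20
  radius_vox: 4
  shape: [20, 44, 44]
  spacing: [2.0, 0.7, 0.7]
  noise_sd: 30
  kind_mix: {isolated: 0.4, juxtapleural: 0.2, cavitary: 0.2, ggo: 0.1, calcific: 0.1}
split:
  train: 12
  val: 2
sampling:
  fraction: 0.40
  margin: 8
patches:
  size_2d: 35
  size_2d_large: 65
  normalize_2d: true
model:
  tiny: true
  pooling: central
train:
  base_lr: 5.0e-3   # desk-scale rate; the published full-scale value is 6.0e-5
  gamma: 1.0e-4
  power: 0.75
  momentum: 0.9
  batch_size: 64
  max_epochs: 3
  patience: 3
segmentation:
  threshold: 0.5
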