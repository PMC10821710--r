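# 3D anisotropic instance segmentation: few Z slices, so Z is never
# down-sampled; exclusion masks ignore border-touching cells.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: center_normalize
    deterministic: true
  - name: random_flip
    deterministic: false
  - name: random_rot90
    deterministic: false
sampling:
  patch_size: [8, 32, 32]
  patches_per_image: 1
  weighting: foreground_weighted
framework:
  kind: embedseg
  embed:
    seed_threshold: 0.7
    min_size: 25
    fg_seed_weight: 30
network:
  name: unet_aniso_3d
  dim: 3
  in_channels: 1
  depth: 2
  base_filters: 8
  z_factors: [1]
trainer:
  learning_rate: 0.003
  max_epochs: 2
  steps_per_epoch: 25
  batch_size: 1
inference:
  window_size: [8, 32, 32]
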