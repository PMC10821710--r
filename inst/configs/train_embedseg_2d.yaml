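# 2D instance segmentation via spatial embeddings (offsets + sigma +
# seediness), decoded by iterative clustering.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: percentile_normalize
    deterministic: true
  - name: random_flip
    deterministic: false
  - name: random_rot90
    deterministic: false
sampling:
  patch_size: [64, 64]
  patches_per_image: 2
  weighting: foreground_weighted
  fg_ratio: 0.5
framework:
  kind: embedseg
  embed:
    center_mode: medoid
    fg_threshold: 0.5
    seed_threshold: 0.7
    min_size: 25
    fg_seed_weight: 30
network:
  name: unet_2d
  in_channels: 1
  depth: 2
  base_filters: 8
trainer:
  learning_rate: 0.003
  max_epochs: 4
  steps_per_epoch: 75
  batch_size: 2
inference:
  window_size: [64, 64]
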