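# Unsupervised mask <-> image translation with cycle consistency.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: percentile_normalize
    deterministic: true
sampling:
  patch_size: [32, 32]
  patches_per_image: 2
framework:
  kind: cyclegan
  cycle_weight: 10
  identity_weight: 5
  adv_weight: 1
network:
  name: unet_2d
  in_channels: 1
  out_channels: 1
  depth: 2
  base_filters: 8
  final_activation: tanh
trainer:
  max_epochs: 2
  steps_per_epoch: 25
  batch_size: 2
  learning_rate: 0.0002
inference:
  window_size: [32, 32]
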