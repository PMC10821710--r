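# H&E-like semantic segmentation with Reinhard stain normalization.
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
  patch_size: [32, 32]
  patches_per_image: 4
  weighting: foreground_weighted
framework:
  kind: fcn
  recon_loss: mse
network:
  name: unet_2d
  in_channels: 3
  out_channels: 1
  depth: 2
  base_filters: 8
  final_activation: sigmoid
trainer:
  max_epochs: 3
  steps_per_epoch: 50
  batch_size: 4
inference:
  window_size: [32, 32]
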