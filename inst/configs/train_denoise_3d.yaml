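# Paired low-SNR -> high-SNR restoration.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: percentile_normalize
    deterministic: true
sampling:
  patch_size: [8, 32, 32]
  patches_per_image: 2
framework:
  kind: fcn
  recon_loss: mse
network:
  name: unet_aniso_3d
  dim: 3
  in_channels: 1
  out_channels: 1
  depth: 2
  base_filters: 8
  z_factors: [1]
trainer:
  max_epochs: 2
  steps_per_epoch: 25
  batch_size: 2
inference:
  window_size: [8, 32, 32]
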