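# pix2pix: FCN objective plus a conditional patch discriminator.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: percentile_normalize
    deterministic: true
sampling:
  patch_size: [32, 32]
  patches_per_image: 4
framework:
  kind: pix2pix
  recon_loss: mae
  recon_weight: 100
  adv_weight: 1
  gan_objective: lsgan
network:
  name: unet_2d
  in_channels: 1
  out_channels: 1
  depth: 2
  base_filters: 8
  final_activation: tanh
trainer:
  max_epochs: 4
  steps_per_epoch: 50
  batch_size: 4
  learning_rate: 0.0002
inference:
  window_size: [32, 32]
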