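# 2D label-free: predict fluorescence-like intensity from a
# brightfield-like source with a plain FCN U-Net.
data:
  mode: csv_manifest
  val_fraction: 0.2
preprocess:
  - name: percentile_normalize
    lo: 0.5
    hi: 99.5
    out_lo: -1
    out_hi: 1
    deterministic: true
sampling:
  patch_size: [32, 32]
  patches_per_image: 4
framework:
  kind: fcn
  recon_loss: mse
network:
  name: unet_2d
  dim: 2
  in_channels: 1
  out_channels: 1
  depth: 2
  base_filters: 8
trainer:
  max_epochs: 4
  steps_per_epoch: 50
  batch_size: 4
  learning_rate: 0.002
inference:
  window_size: [32, 32]
  overlap: 0.25
  blend: gaussian
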