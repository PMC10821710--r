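# Inference-only: load a checkpoint and run tiled prediction on a folder.
data:
  mode: paired_folders
preprocess:
  - name: percentile_normalize
    deterministic: true
framework:
  kind: fcn
network:
  name: unet_2d
  depth: 2
  base_filters: 8
inference:
  window_size: [64, 64]
  overlap: 0.25
  blend: gaussian
  un_normalize: true
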