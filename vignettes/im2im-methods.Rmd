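---
title: "Models and methods behind im2im"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind im2im}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models the package implements, the assumptions
behind them, the parameters a user may want to change, and the numerical
and design choices taken where several reasonable options existed. It
states no result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The data model

Every image is an `nd_image`: a numeric array whose axes are a subsequence
of **T, C, Z, Y, X** (time, channel, axial, two lateral axes), stored in
that canonical order, with optional physical voxel sizes in microns. Y and
X are always present; all other axes are optional, so the same code path
handles a 64×64 tile and a five-dimensional time-lapse multichannel stack.
On disk an image is a multi-page TIFF (pages ordered T-slowest, Z-fastest)
with a JSON sidecar recording axes, shape, dtype and voxel size. Integer
images round-trip losslessly through 16-bit samples; float images are
affinely encoded into [0, 1] 32-bit-float samples with the affine stored
in the sidecar, so values round-trip to float32 precision. Files without a
sidecar are interpreted by rank: 2 → YX, 3 → ZYX, 4 → CZYX, 5 → TCZYX.

## Intensity normalization

Microscopy intensities are camera-offset- and exposure-dependent, so every
training pipeline starts with a per-image, per-channel normalization:

* **percentile** — clip to the [`lo`, `hi`] percentile range (defaults
  0.5 and 99.5, linear interpolation between order statistics) and map
  affinely onto `out_range`, default [−1, 1]. Robust to hot pixels.
* **standard** — subtract the mean, divide by the *population* standard
  deviation of all voxels.
* **center** — the same z-scoring, but with statistics computed only on a
  chunk of `ceiling(center_fraction · Z)` planes centred on the middle of
  the Z axis (`center_fraction` defaults to 0.5 and is exposed because the
  appropriate chunk depends on how much of the stack is out of focus).
  Useful for 3D stacks whose blurred top and bottom planes would otherwise
  dominate the statistics. At `center_fraction = 1` it *is* standard
  normalization, which the test suite asserts to 1e−6.

Population (not sample) standard deviations are used throughout so that
this limit holds exactly. Each normalization attaches its statistics to
the result, which lets inference invert the transform exactly
(`un_normalize`) when predictions should come back in input units.
Intensity (float) targets are normalized with the same transform list as
sources; integer label targets are never touched.

For H&E histology tiles, stain normalization is a Reinhard-style
statistics transfer: the tile is mapped into the Ruderman lαβ opponent
colour space, each channel is re-centred and re-scaled to a reference
tile's location/scale, and the result is mapped back and clipped. The
colour space and transfer rule are declared in the config
(`stain_norm: reinhard`) so alternative schemes can be added without
changing the interface. Clipping at the gamut boundary means the transfer
is exact only for tiles that do not saturate; the tests quantify this.

## Patch sampling and exclusion masks

Training crops `patch_size` windows from each record. Origins are uniform
over the valid set (patches never cross image borders), or
foreground-weighted: with probability `fg_ratio` (default 0.5) the window
is centred on a positive voxel of the weight map (or of the target when no
weight map is given). The default 0.5 balances two failure modes: pure
instance-centred sampling under-represents background, pure uniform
sampling under-represents rare objects. Identical crop windows are applied
to source, target and masks.

An **exclusion mask** marks regions to ignore — typically unannotated
areas or cells touching the image border. Every loss in the package is a
masked mean over non-excluded voxels, and the gradient at excluded voxels
is identically zero (asserted by finite differences). A patch falling
entirely inside an excluded region is re-drawn, up to 10 attempts.

## Backbones

Built-ins are a 2D/3D U-Net, an anisotropic 3D U-Net and a PatchGAN-style
discriminator. `depth` counts resolution levels (`depth = 1` is plain
convolution blocks, no pooling); channels start at `base_filters` and
double per level. For 3D data each down-sampling step has a per-axis
factor, and the anisotropic variant keeps the Z factor at 1 on early (or
all) levels, so a stack with 4–8 Z slices fits through a network that
halves Y and X several times — the common geometry of high-NA microscopy
where axial resolution is several times coarser than lateral. The
discriminator is three stride-2 convolutions plus a scoring convolution,
so its output is a grid of patch logits rather than a single scalar.

Any other architecture can be supplied by a dotted import path
(`pkg::factory`) with keyword arguments; the resolved network is probed
with a zero tensor and channel mismatches are reported as shape-contract
errors before training starts.

The layer engine itself (im2col convolutions over BLAS, instance/batch
normalization, nearest-neighbour upsampling, Adam) is written in base R
with hand-derived reverse-mode gradients. Correctness rests on
finite-difference gradient checks over random parameter slices of full 2D
and 3D U-Nets, which the test suite runs on every execution.

## Frameworks

* **FCN**: masked mean reconstruction loss (`mae`, `mse` or `smooth_mae`),
  single Adam optimizer (default lr 1e−3).
* **pix2pix**: generator loss `λ_rec·recon + λ_adv·adv`, discriminator
  loss `½[adv(real) + adv(fake, detached)]`, alternating updates with Adam
  (lr 2e−4, β₁ = 0.5 convention for GANs). Defaults `λ_rec = 100`,
  `λ_adv = 1`, least-squares objective; all YAML-overridable. At
  `λ_adv = 0` the generator gradient equals `λ_rec` times the FCN
  gradient exactly — an invariant the acceptance suite checks to 1e−6.
  The generator can be initialized from an FCN checkpoint
  (`framework.generator_init`), reproducing the FCN's outputs bitwise
  before the first update.
* **CycleGAN**: adversarial terms on both directions plus cycle
  (`λ_cyc = 10`) and identity (`λ_id = 5`) L1 terms on unpaired batches.
  Identity generators make the cycle and identity terms exactly zero.
* **EmbedSeg-type**: the network emits d offset channels, a sigma channel
  (positivity via `exp`) and a seed channel (`sigmoid`). For instance k
  with centre `C_k` (medoid by default — guaranteed to lie inside
  non-convex instances; centroid available), the Gaussian affinity
  `φ_k(e_i) = exp(−‖e_i − C_k‖²/(2σ_k²))` with `σ_k` the mean predicted
  sigma over the instance is scored against membership over the instance
  plus nearby background (its bounding box dilated by `margin`, default
  5 px) with the **Lovász hinge** on `2φ − 1` — the convex Jaccard
  surrogate whose minimum puts the `φ = 0.5` decoding contour on the
  instance boundary, which a plain per-pixel squared loss does not do
  under the strong foreground/background imbalance of microscopy patches.
  A smoothness term penalizes the within-instance variance of sigma; the
  seed map regresses toward `φ` (detached) on foreground and 0 elsewhere,
  with foreground pixels carrying an extra weight (`fg_seed_weight`) so
  the sparse foreground signal converges within short schedules while the
  dense background keeps firm pressure toward 0. Centres are computed on
  the fly per patch after cropping, so augmented/cropped geometry is
  always consistent — no precalculated centre images, no precropping.
  Pixel coordinates are normalized per axis to (0, 1).

Decoding clusters candidates (seed > `fg_threshold`, 0.5): repeatedly take
the highest-seed unassigned candidate as a centre, assign every candidate
with affinity > 0.5, stop when no candidate's seed exceeds
`seed_threshold`, and drop instances below `min_size` voxels. One
embedding centre can own several connected components, so holed and
fragmented instances are representable. The example configs set
`min_size` to 25 px, in line with the minimum object sizes used by
embedding- and flow-based nuclear segmentation tools: under-trained seed
maps leave small halo fragments around true objects, and a realistic
minimum object size removes them without touching genuine nuclei (the
generator's smallest ellipses are ~28 px).

Two initialization details matter in practice and are set by
`embedseg_head_init`: the final convolution starts at zero (embeddings
start at the pixel coordinates) and the sigma bias starts at
`log(0.2)` — roughly an object radius in normalized units. With a random
head, every embedding starts far from its centre, `φ` is numerically zero
and the instance term provides no gradient. The generic `seed_threshold`
default follows the published convention (0.9); the shipped desk-scale
example configs set 0.7, because after a few hundred optimization steps
the seed map — which regresses toward `φ` — is still biased low relative
to its asymptote, and the decoder would otherwise find no centres. Both
values are plain YAML fields.

## Sliding-window inference

Full images (up to 5D) are predicted by tiling the spatial axes into
windows of `window_size` with stride `window · (1 − overlap)` (default
overlap 0.25), predicting each window, and accumulating predictions with a
separable Gaussian weight (σ = `gaussian_sigma_scale` · window, default
0.125, max-normalized, floored at 1e−6 so coverage is strictly positive).
The output is the voxelwise weighted average; reflect-padding up to the
network's down-sampling multiple is inverted afterwards. Timepoints are
processed independently — including their normalization — so a T-stack
prediction equals the concatenation of single-frame predictions exactly.
For an identity model this machinery is a partition of unity: the output
equals the normalized input to 1e−5 for every overlap and blend mode
tested, including prime-sized images. Gaussian blending exists because
real networks disagree at window borders; a fixture whose model corrupts a
two-pixel border shows strictly smaller stitching error under Gaussian
than uniform blending.

EmbedSeg inference decodes each window independently and merges window
instances by IoU ≥ 0.5 against the growing canvas, giving fresh labels to
unmatched instances.

## Data modes, caching, portions

Four pairing modes cover the layouts seen in practice: a CSV manifest
(columns `source_path,target_path[,exclusion_path][,weight_path]`), two
folders matched by identical file names, one folder with `stem_IM` /
`stem_GT` suffixes, and pre-split `train/`/`val/` subtrees. Everything
else splits by `val_fraction` under the run seed. Deterministic transforms
(normalization, padding) are cached on first touch, keyed by file path,
modification time and the serialized transform spec — changing any
parameter invalidates the key, and cached results are voxelwise identical
to a fresh pipeline. For collections larger than memory, the portion
loader walks a seeded permutation in chunks of
`ceiling(portion_fraction · N)` records per reload period, so all records
are visited before any repeats.

## Determinism

Every stochastic component (split, sampler, weight init, augmentation,
portions, synthetic data) draws from a private RNG stream derived from the
run seed by a named child-seed hash; streams never touch the global RNG or
each other. Two runs with equal seed and config produce identical loss
trajectories in full precision; the acceptance script measures the
difference (zero).

## The synthetic-data generator

`make_blob_world` places non-overlapping random ellipses/ellipsoids
(rejection sampling) on a canvas and renders a clean intensity image:
per-object random amplitude × a smooth quadratic-plus-sinusoid interior
texture, Gaussian PSF blur, constant background 0.1, Gaussian (optionally
Poisson) noise. Task renderers derive paired fixtures: *labelfree*
(source = inverted, edge-enhanced, heavily blurred rendering — enough
nonlinearity that an identity model fails), *semantic*, *instance* (with
border-touching instances as the exclusion mask, the uncurated-cell
situation), *denoise* (low/high-SNR pair), *modality* (heavy/light blur)
and *stain* (two-stain optical-density RGB rendering with per-image colour
jitter). Defaults are 64² (2D) or 8×32×32 (3D) canvases, 2–5 objects,
noise sd 0.05, PSF σ 1 px — small enough that the full test suite trains
every framework on CPU in minutes. Because each source has an exactly
known target, metric ceilings are exact (predicting the stored target
scores Pearson 1).

What the generator does *not* emulate: optical aberrations, structured
noise, intensity drift, crowded/touching objects, annotation errors.
Passing tests therefore demonstrate that the machinery — losses,
gradients, sampling, stitching, decoding — is correct, not that any model
generalizes to real microscopy data; on real data the same configs need
larger backbones and schedules.

## Problem sizes and schedules

The shipped tests and the acceptance script use deliberately small
problems chosen as the smallest sizes at which each property is
informative: 6-image fixtures, depth-2 U-Nets with 8 base filters, 200
optimization steps for label-free regression (reaching holdout Pearson
≥ 0.8), 300 steps per seed for EmbedSeg (median AP@50 over three seeds
≥ 0.8 on a held-out fixture set). Two short-schedule choices in the
example configs follow from measured convergence rather than taste: the
2D label-free config uses `mse` at lr 2e−3 because the MAE sign gradient
converges too slowly for schedules this short, and the EmbedSeg configs
use lr 3e−3 with flip/rotation augmentation for the same reason. All of
these are config fields, not constants.

## Known limitations

* CPU only; no GPU path, no mixed precision (the `precision` field is a
  contract-level hook), no multi-node training.
* Batch normalization uses current-batch statistics in all modes (no
  running averages); generators default to instance normalization.
* No stain deconvolution into optical-density components; stain transfer
  is statistics-based.
* The cache stores fully materialized arrays; images are read eagerly
  (deferred per-record loading happens at the dataset level, not inside a
  single TIFF).
* No test-time augmentation, model ensembling or replay buffers
  (config hooks reserve the options).
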