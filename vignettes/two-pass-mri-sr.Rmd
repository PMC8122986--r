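---
title: "Two-pass tri-planar super-resolution of 3D brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pass tri-planar super-resolution of 3D brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrisr)
```

## The reconstruction problem

A T1-weighted brain volume is a 3D voxel grid — in the sizes this package is
organised around, 256 × 256 × 150 voxels, stored as NIfTI. Acquiring only
half the resolution (128 × 128 × 75) is cheaper, and the task is to restore
the full grid. 3D super-resolution CNNs solve this directly but carry large
parameter counts. The approach implemented here replaces the 3D network with
two 2D reconstructions that exploit the grid's tri-planar structure:

1. slice the half-resolution volume on the sagittal, coronal and axial
   planes and super-resolve each 2D slice ×2 (`extract_slices()`,
   generator kind `"rfb_esrgan"`);
2. rebuild a double-size volume by writing each slice at its (alternating)
   target index (`rebuild()`) — two slices of different planes that cross at
   a voxel both write it, and their values are averaged;
3. restore the rebuilt volume — which has exactly one eighth of its voxels
   written by no plane, plus seam artifacts — with a second, same-size
   generator run slice-wise on all three planes (kind `"nesrgan"`,
   `second_pass_plane_policy()`).

The missing-voxel structure is exact, not approximate: after interval-1
decimation the kept slices sit at odd 1-based indices, so a voxel is missed
iff all three of its coordinates are even — a fraction of 1/8 on
even-dimension grids, and the exhaustively enumerated count otherwise. The
suite property-tests this against a brute-force oracle.

## Networks

**Stage 1 (×2).** A shallow 3×3 convolution lifts the 1-channel slice to
`base_channels` (default 64) features; the trunk is 16 residual-in-residual
dense blocks (RRDB: 3 dense blocks of five 3×3 convolutions, growth
`base_channels/2`, residual scale 0.2) followed by 8 residual
receptive-field dense blocks (RRFDB), then a trunk convolution with a long
skip, one upsampling stage, and a 3×3 output head. The receptive-field unit
aggregates four branches — 1×1; 1×1→3×3; 1×1→3×3 dilation 3;
1×1→1×3→3×1→3×3 dilation 5 — fused by a 1×1 convolution; this is the
canonical receptive-field-block layout, adopted because the source figure
shows the branch idea ("numerous small kernels") without exact widths.
The cited alternating NNI/sub-pixel upsampling scheme is defined per ×2
stage; at the package's ×2 scale there is a single stage and the sub-pixel
(final) stage is the default, with NNI selectable. At ×4 the stages
alternate NNI then SPC.

**Stage 2 (same size).** nESRGAN keeps the RRDB trunk (16 blocks) and makes
three changes: (a) a per-channel, zero-initialised, learned-strength
Gaussian noise map is added to each dense block's fused output before its
residual add — one noise image per spatial position, shared across channels,
as in style-based generators; (b) all upsampling is interpolation followed
by convolution — a structural test asserts that no transposed convolution
exists in the graph, since zero-insertion upsampling is what produces
checkerboard artifacts (a `"deconv"` mode is retained solely to demonstrate
them); (c) a linear-interpolation downsampling block at the head halves the
feature maps so the ×2 tail restores the original size (odd extents round up
and are cropped back, so any H×W maps to H×W).

**Global residual skip.** Both generators add their head output to an
interpolation of the input (bicubic ×2 for stage 1, identity for stage 2)
and the head convolution is zero-initialised. A freshly built generator is
therefore *exactly* its interpolation baseline, which gives the package a
well-defined untrained reference point, makes the "identity reduction" test
sharp (≤ 1e-6), and means training learns only the residual detail.

**Discriminator.** VGG-style: feature widths 64→128→256→512, kernel 3,
strides alternating (1, 2), batch normalization and LReLU (slope 0.2), two
fully connected layers to a single pre-sigmoid logit `C(x)`.

## Losses

The generator objective is `L_percep + λ·L_adv + η·L1`. The printed source
equations mislabel two terms (the formula labelled as the adversarial loss
is a pixel L1, and the one labelled pixel loss is the relativistic
adversarial loss); the package follows the prose and the standard
ESRGAN/relativistic-average assignment:

* `L1` — mean absolute error;
* `L_percep` — L1 in a feature space. The reference extractor is
  pre-activation VGG-19; pretrained weights are a *pluggable* dependency,
  never shipped. An identity extractor (making `L_percep = L1`) ships for
  fully offline work, and any object with `forward`/`backward` can be
  plugged in;
* `L_adv` — relativistic-average loss on logit differences,
  `−E log(1−σ(C_r − E C_f)) − E log σ(C_f − E C_r)` for the generator and
  the swapped form for the discriminator. Both equal `2 log 2` on equal
  logits; only logit differences matter, which the suite tests as an
  offset-invariance property; log arguments are clamped to `[1e-8, 1]`.

λ and η are printed nowhere in the source; the ESRGAN-lineage defaults
λ = 5e-3, η = 1e-2 are declared as this package's defaults and are
config-overridable. Stage-1 pretraining is L1-only (for both networks);
stage 2 adds the perceptual and adversarial terms. The optimiser is Adam
(lr 1e-4 stage 1, 1e-5 stage 2, β = 0.9/0.999) — likewise a declared
default, since the source names none.

## Intensity convention and metrics

Intensities are min–max normalized per volume to [0, 1] at read time (the
raw range is kept for write-back). The source states no normalization; a
single declared convention makes PSNR's dynamic range well-defined
(MAX = 1), so absolute dB values computed here are comparable *within* this
convention but not directly against tables computed under an unknown one.
SSIM uses the universal stabilizers c1 = (0.01 L)², c2 = (0.03 L)² and a
7×7 uniform window by default (11×11 Gaussian σ = 1.5 selectable); the
window is unstated in the source. `evaluate_volume()` scores every slice of
every requested plane and reports mean ± sd per plane; slices with zero MSE
are flagged and excluded from PSNR means. Whether published per-plane
spreads are across slices or volumes is unstated; this report computes
across slices of one volume and labels `n_slices` explicitly.

## The phantom generator

`generate_phantom()` emulates what the networks need from brain MRI:
smooth anatomical structure (a seeded sum of 3D Gaussian ellipsoids inside
a head-like envelope), high-frequency content (band-limited texture from a
coarse Gaussian grid upsampled cubically — the detail SR must restore), and
acquisition noise (additive Gaussian, σ = 0.01 by default), clipped to
[0, 1]. The small-test shape 64 × 64 × 38 mirrors the even/even/even parity
of the full 256 × 256 × 150 size, whose axial extent halves to an odd 75 —
so decimation edge cases are exercised. Phantoms do **not** model MRI
physics (bias fields, Rician noise, k-space sampling, anatomy): passing
tests demonstrate the pipeline's geometry, optimisation and invariants, not
clinical image quality.

## Numerical choices

* All resampling (slice degradation, volume downscaling, the generators'
  skip and sampling layers) uses one kernel family: separable Keys cubic
  convolution (a = −0.5), antialiased (kernel stretched by the scale factor)
  when downscaling, plain when upscaling; rows renormalised so constants are
  resized exactly. Volume downscaling applies the same 1D operator along
  each axis — one convention everywhere rather than a second spline-based
  resampler for volumes.
* Decimation keeps index 0 (1-based 1) first: the printed 128/128/75 counts
  are consistent only with keep-one-skip-one, and the starting parity is
  fixed for determinism. Training data is decimated before degradation (the
  process order of the pipeline figure); the patch builder degrades each HR
  patch directly so LR/HR pairs align exactly at patch borders.
* Patch tiling stride defaults to the HR patch side (non-overlapping);
  the source is silent, and non-overlap gives reproducible counts.
* Overlap merge on rebuild is the arithmetic mean (order-independent,
  property-tested under stack permutations); a fixed plane-priority merge is
  available. The missing sentinel is 0 *plus* an explicit mask — zeros are
  legal intensities and are never used for detection.
* The interpolation-repair baseline iterates neighbor-mean filling
  (6-connected volumetric by default; a 4-connected slice-wise mode matches
  the earlier 2D formulation) until no voxel is missing; known voxels are
  never altered, and termination needs only one known voxel.
* The engine's backward passes are exact analytic gradients; the suite
  checks convolution against a naive sliding-window oracle, linear layers
  by adjointness (⟨Lx, y⟩ = ⟨x, Lᵀy⟩), and losses/batch-norm against central
  finite differences at 1e-4 relative.
* Dataset splitting is a seeded shuffle (the source gives counts, not a
  rule). Training threads one seed through weight init, shuffling and noise.

## Problem sizes used by the tests and the acceptance script

The suite and `scripts/acceptance.R` run the full architecture at reduced
width/depth where learning is involved: stage-1 training uses 1 RRDB at 8
channels, batch 16, 200 Adam steps on patches from 48 × 48 × 24 phantoms,
judged by 3-seed majority on (a) a decreasing running L1 and (b) held-out
slice PSNR at or above the bicubic baseline. Architecture contracts are
additionally exercised once at the full 16 RRDB + 8 RRFDB, 64-channel
configuration. These sizes are the package's scaled-down study design; the
full-size training protocol (581 volumes, 431/150 split, batch 16) is
expressed in the same functions and configs.

## Known limitations

* No pretrained weights are distributed; the GAN stage with a true
  perceptual extractor requires the user to plug one in.
* Phantoms are not anatomically or physically realistic (see above).
* The brightness differences reported between adjacent rebuilt slices in
  the source have no stated quantitative correction; none is implemented —
  the second pass is the mechanism that addresses them.
* Whether published comparisons normalise intensities as done here is
  unknown; absolute dB values should be compared only within this package's
  convention.
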