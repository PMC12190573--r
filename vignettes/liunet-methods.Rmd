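---
title: "LIU-Net: model, objectives and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LIU-Net: model, objectives and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gliomas are delineated on multimodal MRI as three nested regions: the
*whole tumor* (WT — everything abnormal, including peritumoral edema), the
*tumor core* (TC — the tumor excluding edema) and the *enhancing tumor*
(ET — the contrast-enhancing rim visible on T1ce). The BraTS data layout
provides four co-registered, skull-stripped modalities per patient (T1,
T1ce, T2, FLAIR), each 240×240×155 voxels, plus an expert mask with raw
labels 0 (background), 1 (necrotic/non-enhancing core), 2 (edema) and 4
(enhancing tumor); label 4 is remapped to 3 so the class alphabet is
contiguous. The evaluated regions are unions of labels: ET = {3},
TC = {1, 3}, WT = {1, 2, 3}.

This package implements LIU-Net, a *lightweight Inception U-Net*: a
five-level 3D encoder–decoder whose per-level feature extractor is an
Inception-style block of three parallel convolution towers (kernel sizes
1³, 3³, 5³) concatenated along channels. The motivation is multi-scale
context at a small parameter budget — the default instantiation has about
3.45 M trainable parameters, an order of magnitude below the ~19 M of a
conventional 3D U-Net of comparable depth.

## Architecture

Each Inception block maps its input to `c1 + c3 + c5` channels:

* a 1³ convolution to `c1` channels (fine detail),
* a 1³ bottleneck to `reduce3` channels followed by a 3³ convolution to
  `c3` channels (medium structure),
* a 1³ bottleneck to `reduce5` channels followed by a 5³ convolution to
  `c5` channels (large structure).

Every convolution is "same"-padded, bias-free, and followed by batch
normalization and ReLU. The bottlenecks are standard Inception practice
and are what keeps the 5³ tower affordable; without them the 5³
convolutions alone would dominate the parameter count.

The encoder stacks five such blocks with 2×2×2 max-pooling between levels;
the default block widths are (32, 64, 128, 256, 320), split ¼/½/¼ across
the towers with ¼-width bottlenecks. The decoder mirrors levels 4→1:
nearest-neighbour ×2 upsampling followed by a 1³ channel-adjust
convolution (a stride-2 transposed convolution is available as
`upsample = "transposed"`), concatenation with the same-level encoder
output (the skip connection), then another Inception block. The head is a
1³ convolution to 4 classes with a per-voxel softmax. The network is fully
convolutional: any spatial shape divisible by `2^(depth-1)` = 16 works,
and the output spatial shape always equals the input's.

The published description fixes the depth, the tower kernel sizes, the
pooling and the skip-connection topology but not the per-level widths,
so the width schedule above is this package's own calibration, chosen to
land in the low millions of parameters; all widths are configurable via
`liunet_arch()` and `inception_block_config()`. One block per level is
used. `estimate_flops()` reports the usual 2×(multiply–accumulate) count
over convolution layers at a stated input shape; FLOP figures are
convention-dependent (whether BN/activations count, fused vs unfused
accounting) and are meant for order-of-magnitude comparison only.

## Objectives

Training minimizes a weighted sum of two terms computed on the softmax
probabilities \(p\) against the one-hot truth \(g\):

* **Soft Dice loss**, squared-denominator form, per channel
  \(D_c = (2\sum_i p_i g_i + \epsilon) / (\sum_i p_i^2 + \sum_i g_i^2 +
  \epsilon)\), averaged over the three foreground channels (background is
  excluded by default, configurable), loss \(= 1 - \bar D\). The smoothing
  constant \(\epsilon = 10^{-6}\) keeps empty-region gradients finite.
* **Focal loss** \(-\alpha_t (1-p_t)^\gamma \ln p_t\) averaged over
  voxels, where \(p_t\) is the probability of the voxel's true class,
  clipped at \(10^{-7}\). Defaults \(\alpha = 0.25\), \(\gamma = 2\); a
  per-class \(\alpha_t\) vector is supported, as is the expanded binary
  form. At \(\gamma = 0, \alpha = 1\) the focal term reduces exactly to
  cross-entropy — one of the test suite's oracle identities.

The combined objective is `lambda1 * focal + lambda2 * dice` with both
weights defaulting to 1. Dice sums run over the whole batch
(batch-global Dice) rather than per sample. Natural logarithms are used
throughout.

Evaluation uses the *hard* Dice `2|X∩Y|/(|X|+|Y|)` on argmaxed
predictions per region. When both masks are empty the score is defined as
1 (the community convention: nothing to find and nothing found); when
exactly one is empty, 0. Cohort scores are unweighted subject-wise means.

## Preprocessing

The pipeline order is **resample, then normalize, then stack**: each
modality is resampled to the network shape (default 128³; tests use 32³)
with separable trilinear interpolation, normalized per modality and per
subject, and stacked in the fixed channel order (t1, t1ce, t2, flair).
Normalizing after resampling guarantees the advertised output range even
if interpolation overshoots. Two normalization modes exist because the
published account is ambiguous between them: min–max rescaling to [0, 1]
(the default — it is the only formula printed) and z-scoring with the
population standard deviation. A constant volume degenerates to all zeros
(with a warning in min–max mode) instead of dividing by zero. Labels are
resampled nearest-neighbour (never interpolated), remapped 4→3, and
one-hot encoded.

## Training engine

Optimization is Adam (learning rate 1e-4, batch size 2, 100 epochs by
default — the published recipe). Everything is seeded: weight
initialisation (He-normal), the per-epoch data order, and any
augmentation draws (optional axis flips, off by default because no
specific augmentation scheme is published). The per-epoch log records
training loss, validation loss and per-region soft Dice; the kept weights
are those of the best validation epoch by mean foreground soft Dice (the
final weights when no validation partition exists — a selection rule this
package chooses, since none is published). Checkpoints are RDS files; a
save/load round trip reproduces predictions bit-identically. CPU
determinism is contractual and tested.

Internally the network runs on (voxels × channels) matrices. The 3³/5³
convolutions are computed slab-by-slab as implicit GEMM in single
precision (about 1e-7 relative rounding, far below the training noise
floor); the option `liunet.conv.double = TRUE` switches the convolution
engine to full double precision, which the finite-difference gradient
oracle in the test suite uses. Batch normalization uses population
statistics over the batch with running-average momentum 0.1 and
\(\epsilon = 10^{-5}\); prediction always uses the running statistics.

## The phantom generator

`generate_phantom()` builds BraTS-like subjects from nested ellipsoids: a
brain ellipsoid containing a whole-tumor ellipsoid whose outer shell is
edema (label 2), inside it an enhancing rim (label 3) wrapping a
necrotic/non-enhancing core (label 1) — so the ET ⊆ TC ⊆ WT nesting holds
by construction. The four channels are tissue means plus Gaussian noise,
with the clinically motivated contrast pattern: FLAIR brightest in edema,
T1ce brightest in the enhancing rim, T2 bright across the tumor, T1
near-uniform. Defaults: 64³ volumes (32³ in most tests, 240×240×155
available to exercise the exact BraTS resampling path), noise SD 10
intensity units — 10–20 % of the tissue contrasts, enough to be
non-trivial while keeping tissue classes statistically separable, which
is what a voxel-wise learnability check needs. Each subject's randomness
derives from `(seed, subject_index)`, so cohorts are order-independent
and bit-reproducible.

Phantoms deliberately trade realism for controllable geometry: no bias
fields, no texture, no multi-focal disease, single-voxel-scale noise
only. Passing phantom tests therefore demonstrates that the pipeline,
optimizer and objectives are wired correctly — not that the default
configuration reaches any particular accuracy on real BraTS images,
which requires the challenge download and long GPU training and is out of
scope here.

## Problem sizes and numerical choices in the test suite

The suite runs entirely on synthetic phantoms at 16³–32³ so a single CPU
suffices. The learnability check trains the default architecture on 4
phantoms at 32³ for 150 steps (75 epochs × 2 steps at batch 2) with the
combined loss and asserts mean foreground soft Dice ≥ 0.80 plus a strict
WT improvement over the untrained network. That run uses a step size of
1e-3 — ten times the production default — because 150 steps is a
smoke-test regime: 1e-4 is tuned for 100 epochs over hundreds of
subjects, not for rapid memorization of four (with it, the same run
plateaus around 0.75 soft Dice; at 1e-3 it reaches ≈ 0.99). The split
arithmetic check reproduces the published cohort sizes (1,250 →
875/125/250 at 70/10/20 under the floor rule). The parameter count of
every instantiated network is checked against an independent analytic
layer-walk; gradients are checked against central finite differences
(relative tolerance 1e-3, convolution engine in double precision).

## Known limitations

* CPU-only; full-scale inputs (128³, hundreds of subjects, 100 epochs)
  are expressible in the configuration but impractical without a GPU
  framework.
* Single-precision convolutions make training runs reproducible on a
  given BLAS but not bit-portable across BLAS implementations.
* The exact published tower widths are not recoverable from the source
  description, so the 3.45 M default is near, not equal to, the reported
  3.124 M; the enforced acceptance bound is the ~19 M baseline.
* No bias-field correction, histogram matching, patch extraction, or
  Hausdorff/surface metrics.
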