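---
title: "Segmenting and staging rectal cancer on 3D MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and staging rectal cancer on 3D MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Preoperative T staging of rectal cancer on T2-weighted MRI decides whether a
patient goes straight to total mesorectal excision or receives neoadjuvant
treatment first.  The decisive boundary is the outer edge of the muscularis
propria: a tumor confined within it is staged T2 or below, a tumor invading
through it into the mesorectal fat is T3 or above.  `rectseg` implements a
semi-automated pipeline for this decision: the user supplies one click — an
approximate tumor center — and the software segments tumor, rectum and
mesorectum in 3D and derives the binary T stage from the segmentation
geometry.

## Segmentation model

The segmentation network is a 3D U-Net-style encoder-decoder built from
convolution + batch-normalization + ReLU blocks.  Downsampling uses stride-2
3x3x3 convolutions, upsampling uses transposed convolutions with a 4x4x4
kernel (stride 2), and each skip connection passes through a 1x1x1
convolution + batch normalization + ReLU before being summed into the
decoder stream.  The head is a 1x1x1 convolution to three channels with a
per-channel sigmoid.  The output is *multi-label*, not a partition: a voxel
can be both tumor and rectum, which is anatomically required because mural
tumor tissue lies inside the rectum contour.  Channel order is fixed:
tumor, rectum, mesorectum.

Several architectural details are configurable because they are not uniquely
determined by the block structure alone:

* `levels` (default 4) and `base_channels` (default 16, doubled per level).
  Tests and desk-scale experiments use `levels = 3`, `base_channels = 8`.
* per-level convolution kernels, either 3x3x3 or 3x3x1.  The default places
  the through-plane-thin 3x3x1 kernel at the finest level — where the raw
  acquisition is most anisotropic — and 3x3x3 elsewhere; the decoder mirrors
  the encoder's per-level choice.
* Downsampling is by strided convolution rather than pooling, matching the
  symmetric strided transposed-convolution upsampling.
* Skip fusion is by summation (after the 1x1x1 projection) rather than
  concatenation; with the projection in place the two are equally
  expressive per parameter and the sum halves the width of the decoder
  convolutions.

The engine behind the network is written in the package's own C++ backend
(im2col/col2im lowering onto BLAS GEMM, fused batch-norm/ReLU kernels,
analytic backward passes, Adam); it runs in single precision internally,
which is standard practice for convolutional network training.

## The combined loss

Training minimizes `Loss_SEG + lambda * Loss_STG`.

**Segmentation term.** `Loss_SEG` is the soft Dice loss per channel,
`1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, averaged without
weights over the three channels, and evaluated only for cases that carry
voxelwise ground-truth labels.  The smoothing constant `eps = 1` defines the
empty-mask case and stabilizes gradients; `eps = 0` recovers the textbook
formula.

**Staging term.** The package's staging surrogate is
`p_staging = max_i p_tumor,i * (1 - p_rectum,i)`, the most "incriminating"
voxel in the volume — high only when some voxel is confidently tumor and
confidently not rectum, i.e. when the prediction implies extramural tumor.
With the stage encoded as `g = +1` (>= T3) or `g = -1` (<= T2), the loss is

```
Loss_STG = -[(1 - g)/2 + g * p_staging]
```

which is linear in `p_staging` with slope exactly `-g`: it pushes the
predicted breach up for true T3 cases and down for true T2 cases, and its
range is [-1, 0].  It is evaluated for *all* cases, including those with
only a pathology-confirmed stage and no segmentation masks — this is the
weak-supervision mechanism that lets stage-only cases shape the
segmentation.  The maximum is implemented as a hard max with the subgradient
routed through the argmax voxel; a temperature-smoothed variant was
considered and rejected as an unneeded extra hyperparameter, since the hard
max is the stated form and trains stably at our scales.

`lambda` defaults to 0.02; `lambda = 0` is the Dice-only ablation baseline.

## Staging rule

After binarizing the three probability channels at 0.5 (strictly greater
than), the case is classified `GE_T3` exactly when at least one tumor voxel
lies outside the rectum mask, i.e. beyond the muscularis propria; otherwise
`LE_T2`.  Contour voxels belong to the rectum mask, so "completely included
in the rectum" and "no tumor voxel outside the rectum" coincide; an optional
stricter mode (`contour_strict`) additionally calls T3 when the tumor
touches the outer rectum boundary from inside, via face-connectivity
boundary extraction.  It is off by default because the inside/outside
dichotomy is the primary reading of the rule.  An empty predicted tumor mask
classifies as `LE_T2` with a `tumor_empty` quality flag instead of raising,
so cross-validation over imperfect checkpoints stays total.

## Preprocessing

Volumes are resampled to isotropic voxels (trilinear; default 0.5 mm),
cropped to a fixed block centered on the user-supplied tumor center
(default 256 x 256 x 128 voxels), and z-score normalized.  Masks follow the
identical geometry with nearest-neighbor interpolation, zero padding, and no
normalization.  Conventions chosen where the protocol leaves them open:
physical millimeter coordinates, 0-based voxel indices, voxel-center
convention; image padding uses the input minimum (avoids bright borders on
T2-like contrast), mask padding uses 0.  Whether and how the original
protocol normalized intensities is unstated; z-scoring is the conventional
choice and the network is trained and evaluated under the same convention,
so nothing downstream depends on absolute signal units.

## Training and model selection

Adam with base learning rate 0.003, beta1 0.9, beta2 0.999, epsilon 1e-8.
Each batch holds 5 cases: 3 with segmentation labels and 2 staging-only
(configurable; cohorts lacking one group fall back to single-group batches
with a warning).  Every 100th iteration the network is scored on the
validation fold by the sum of the mean binarized Dice score, staging
sensitivity and staging specificity, and the best-scoring checkpoint is
kept.  The mean Dice score averages the three structures — whether the
original selection used per-structure or averaged Dice is not recoverable,
so the averaged form is used and recorded.  If a validation fold lacks one
stage class the undefined sensitivity or specificity enters the selection
sum as 0 (a deliberately conservative choice that demotes such checkpoints).

Augmentation (optional, off by default at desk scale where the phantom
cohort can simply be made larger): uniform scaling in [0.9, 1.1], in-plane
rotation in [-10, 10] degrees about the tumor center, and slice-thickness
conversion to a random thickness in [2, 4] mm before isotropic resampling.
The magnitudes are not specified by the protocol; these ranges cover the
plausible acquisition variation without breaking stage geometry.

**Cross-validation.** Ten folds by seeded random partition (an optional
stage-stratified mode exists but is off by default, matching the plain
"randomly divided" protocol).  Rotation `r` evaluates on fold `r`,
validates on fold `r+1 (mod k)`, and trains on the remaining eight; over
the ten rotations every case is evaluated exactly once.  "The remaining two
datasets were used for validation and evaluation" does not pin which of the
two held-out folds plays which role; the `eval = r, val = r+1` rotation is
one concrete reading and is recorded in the report.  Segmentation metrics
are computed only over label-bearing cases; staging metrics over all cases.

All randomness flows from one master seed split into named substreams
(cohort, folds, batches, augmentation, weights), so every run is exactly
reproducible.

## The synthetic phantom generator

Patient images for the original study are not publicly deposited, so the
package ships a phantom generator that emulates the relevant anatomy and
lets every stage of the pipeline run end to end:

* nested tubular anatomy along one axis — fluid lumen, rectal wall
  (muscularis propria), surrounding bright mesorectal fat — with optional
  sinusoidal curvature of the tube axis;
* a tumor as an angular sector of the wall with a smooth super-ellipsoidal
  cap, protruding up to 2.5 mm into the lumen (as mural tumors do) and
  extending radially `invasion_depth_mm` beyond the outer wall: a
  non-positive depth gives T2 geometry (tumor inside the rectum), a positive
  depth a T3 breach into the mesorectum;
* the stage label is always *derived* from the generated masks (any tumor
  voxel outside the rectum), never stored separately, so geometry and label
  cannot drift apart;
* T2-like intensities (fat bright, muscle dark, tumor intermediate;
  mucinous tumors bright, close to fat — which is exactly why they are hard
  to segment on real T2 images) with Rician noise, i.e. the magnitude of
  complex Gaussian noise, the standard MR magnitude statistic;
* an anisotropic synthesis grid (0.5 x 0.5 mm in-plane, 3.5 mm effective
  slice pitch emulating 3 mm slices + 0.5 mm gaps) so isotropic resampling
  is genuinely exercised.

Cohorts mirror the two-group study design: a configurable fraction of cases
carries full masks, the rest only the stage; defaults reproduce the study
composition (201 cases, 135 labeled, 119 at >= T3, ~3% mucinous).
Phantom intensity means are free parameters — the study reports no intensity
statistics for its images — and were fixed once at plausible T2-weighted
contrast (background 20, lumen 30, wall 60, tumor 110, mesorectal fat 200,
mucinous 220, noise sigma 8).

**What the phantom does not emulate**: organ deformation and peristalsis,
heterogeneous tumor texture, partial-volume and bias-field artifacts,
neighboring organs, lymph nodes, or the mesorectal fascia's irregular
shape.  Tests passing on phantoms therefore demonstrate that the algorithms
are implemented correctly and that the training signal behaves as designed;
they do not certify clinical performance on patient images, whose published
accuracy cannot be reproduced without the original data.

## Numerical choices and degenerate inputs

* Binarization is strictly greater-than; a probability of exactly 0.5 maps
  to background.
* Both-masks-empty Dice similarity is defined as 1 (perfect agreement on
  absence); sensitivity/specificity with empty denominators return `NA`
  sentinels rather than raising.
* Tumor diameter is the maximal axis-aligned bounding-box extent in mm — a
  deterministic approximation of the maximal diameter, chosen over Feret
  diameters for speed; the original measurement plane is unspecified.
* Dice smoothing `eps = 1`; batch-norm epsilon 1e-5, momentum 0.1; He
  weight initialization.
* Checkpoint-selection ties keep the earlier iteration.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run at desk scale, chosen so the
full pipeline (cohort synthesis, training, cross-validation, evaluation)
completes on a single CPU core: phantoms synthesized at 96 x 96 x 20 voxels
(0.5 x 0.5 x 3.5 mm), preprocessed to 1 mm isotropic 48^3 crops (a crop that exactly covers the phantom's in-plane extent, so the network sees anatomy rather than padding) for the
end-to-end training gate (levels = 3, base_channels = 8), and coarser 2.5 mm
/ 16^3 crops for the multi-seed loss-ablation comparison.  The acceptance
gates on these synthetic cohorts (held-out median DSC at least 0.7 for
tumor and 0.85 for rectum/mesorectum, staging accuracy at least 0.8, and
the combined loss beating or matching the Dice-only baseline on staging
accuracy) are artifact-level checks of correct behavior under the package's
own study conditions, not claims about patient data.

## Known limitations

* The exact channel widths, depth and kernel placement of the original
  network are not recoverable from its description; the implementation keeps
  the stated block structure fully configurable instead.
* The staging term is named a cross-entropy loss in the original
  description, but the printed formula is linear in `p_staging`; the linear
  reading — consistent with the stated behavior for both stages — is
  implemented, and the logarithmic variant is deliberately not assumed.
* The hard-max staging gradient touches one voxel per case per step; for
  very large volumes this is a sparse signal, which is precisely why it is
  paired with the dense Dice term.
* Phantom realism limits are listed above; transfer to clinical data would
  require retraining on annotated patient images.
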