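# rectseg

Semi-automated segmentation and T staging of rectal cancer on 3D
T2-weighted MRI.

## What this package does, and for whom

Preoperative MRI staging of rectal cancer hinges on one geometric question:
does the tumor stay inside the muscularis propria (stage ≤ T2) or invade
through it into the mesorectal fat (stage ≥ T3)?  The answer directs
neoadjuvant treatment and surgical planning, and reading it reliably off MR
images requires specialist experience that is not available at every
institution.

`rectseg` implements a deep-learning pipeline for this task, aimed at
methods researchers in medical image analysis: the user marks one
approximate tumor center, and the software segments **tumor**, **rectum**
(everything within the outer muscularis propria) and **mesorectum** in 3D,
then derives the binary T stage from the segmentation geometry.  Because
the patient images of the motivating study are not publicly available, the
package also ships a synthetic rectal-anatomy phantom generator, so every
component — preprocessing, network, losses, staging rule, metrics,
cross-validation — is fully exercisable and testable end to end.

## The method

**Segmentation network.**  A 3D U-Net-style encoder-decoder: convolution
(3×3×3 or 3×3×1) + batch-norm + ReLU blocks, stride-2 convolutions down,
4×4×4 transposed convolutions up, skip connections through 1×1×1
convolution + batch-norm + ReLU, and a 3-channel sigmoid head (channels:
tumor, rectum, mesorectum).  The output is multi-label — tumor and rectum
legitimately overlap.  The network engine (im2col/GEMM convolutions,
analytic backprop, Adam) is implemented in the package's own C++ backend.

**Combined loss.**  Training minimizes

    Loss_SEG + λ · Loss_STG,        λ = 0.02

where `Loss_SEG` is the per-channel soft Dice loss
`1 − 2Σpᵢgᵢ / (Σpᵢ + Σgᵢ)` (mean over the three channels, evaluated only on
cases with voxelwise labels), and the staging term supervises the *stage*
of cases that carry no masks at all:

    p_staging = maxᵢ p_cancer,i · (1 − p_rectaltube,i)
    Loss_STG  = −[(1 − g)/2 + g · p_staging],   g = +1 (≥T3) / −1 (≤T2)

`p_staging` is a differentiable surrogate for "tumor tissue exists outside
the rectum"; the loss pushes it up for true T3 cases and down for true T2
cases (∂Loss_STG/∂p_staging = −g exactly).  With λ = 0 the objective
reduces to the plain Dice loss — the ablation baseline.

**Staging rule.**  After binarizing at 0.5, a case is ≥ T3 exactly when at
least one tumor voxel lies outside the rectum mask, otherwise ≤ T2.

**Protocol.**  Adam (lr 0.003, β₁ 0.9, β₂ 0.999, ε 1e−8); batches of 5 = 3
labeled + 2 staging-only cases; validation every 100 iterations with
checkpoint selection by the sum of mean Dice score, staging sensitivity and
staging specificity; rotating 10-fold cross-validation (per rotation: 8
folds train, 1 validates, 1 evaluates).  Volumes are resampled isotropic,
cropped around the tumor center, and z-scored.

See `vignettes/rectseg-methods.Rmd` for assumptions, parameter rationale,
and the phantom generator's scope and limits.

## Worked example

Staging metrics from a 2×2 contingency of predicted vs pathological stage
(the counts of the motivating study's 201-case cohort):

```r
library(rectseg)
tab <- confusion_2x2(tp = 92, fp = 19, fn = 27, tn = 63)
print(tab)
#>          truth
#> predicted LE_T2 GE_T3
#>     LE_T2    63    27
#>     GE_T3    19    92
#> sensitivity 0.773  specificity 0.768  accuracy 0.771
```

A miniature end-to-end run on synthetic phantoms:

```r
set.seed(1)
train <- generate_cohort(12, seg_labeled_fraction = 0.75, seed = 1)
val   <- generate_cohort(4, seg_labeled_fraction = 1, seed = 2)
cfg <- train_config(network = network_config(levels = 3, base_channels = 8),
                    max_iterations = 200, validate_every = 100,
                    target_mm = 1.0, out_shape = c(48, 48, 48), seed = 1)
fit <- train_network(train, val, cfg)

case <- generate_phantom(phantom_spec(invasion_depth_mm = 3, seed = 99))
pred <- predict_case(fit$network, case, target_mm = 1.0,
                     out_shape = c(48, 48, 48))
print(pred$stage)
#> <predicted GE_T3, breach voxels 3>
dsc(pred$masks$rectum, pred$truth_labels$rectum)
#> [1] 0.9627366
```

(The printed numbers come from this exact script; a short 200-iteration run
already stages the obvious T3 phantom correctly and segments the rectum
well, while tumor-boundary precision keeps improving with longer training —
the shipped acceptance run trains for 500 iterations.)

The command-line front end (`inst/cli/rectseg`) wraps the same functions:

```sh
Rscript inst/cli/rectseg simulate --n 20 --seed 7 --out cohort/
Rscript inst/cli/rectseg stage --labels cohort/case001_labels.nii.gz --json
```

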