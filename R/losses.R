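#' Soft Dice loss
#'
#' The differentiable segmentation objective for one channel,
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, where `p` are
#' predicted probabilities and `g` the binary ground truth.  The smoothing
#' term `eps` (default 1) defines the empty-mask case as 0 and stabilizes
#' gradients; `eps = 0` gives the exact Dice-loss formula (with the 0/0 case
#' defined as 0).
#'
#' @param p numeric vector/array of probabilities in \[0, 1\].
#' @param g binary vector/array of the same length.
#' @param eps smoothing added to numerator and denominator.
#' @return Scalar loss in \[0, 1\].
#' @export
dice_loss <- function(p, g, eps = 1) {
  if (length(p) != length(g)) stop("p and g must have equal length")
  p <- as.numeric(p); g <- as.numeric(g)
  if (any(p < -1e-9 | p > 1 + 1e-9)) stop("p must lie in [0, 1]")
  den <- sum(p) + sum(g) + eps
  if (den == 0) return(0)
  1 - (2 * sum(p * g) + eps) / den
}

# Gradient of dice_loss with respect to p.
dice_loss_grad <- function(p, g, eps = 1) {
  den <- sum(p) + sum(g) + eps
  if (den == 0) return(rep(0, length(p)))
  num <- 2 * sum(p * g) + eps
  -(2 * g * den - num) / den^2
}

#' Differentiable staging probability
#'
#' The scalar surrogate for "tumor exists outside the rectum":
#' `max_i p_tumor_i * (1 - p_rectum_i)` over all voxels.  High values mean
#' some voxel is confidently tumor while confidently not rectum.
#'
#' @param p_maps a [prob_maps] object (the mesorectum channel is not used).
#' @return Scalar in \[0, 1\].
#' @export
staging_probability <- function(p_maps) {
  stopifnot(inherits(p_maps, "prob_maps"))
  if (length(p_maps$tumor) == 0) stop("empty probability volume")
  max(p_maps$tumor * (1 - p_maps$rectum))
}

#' Staging loss
#'
#' The stage-supervision term `-[(1 - g)/2 + g * p_staging]` with
#' `g = +1` for true stage >= T3 and `g = -1` otherwise.  For T3 cases it
#' decreases as `p_staging` grows (rewarding predicted tumor outside the
#' rectum); for T2 cases it increases with `p_staging` (penalizing any
#' predicted breach).  Range `[-1, 0]`; the gradient with respect to
#' `p_staging` is exactly `-g`.
#'
#' @param p_staging scalar in \[0, 1\], see [staging_probability()].
#' @param stage a [stage_label] (or +1/-1 `g_staging`).
#' @return Scalar in `[-1, 0]`.
#' @export
staging_loss <- function(p_staging, stage) {
  g <- if (inherits(stage, "stage_label")) stage$g_staging else stage
  if (!(g %in% c(-1, 1))) stop("stage must encode g_staging in {-1, +1}")
  if (!is.finite(p_staging) || p_staging < -1e-9 || p_staging > 1 + 1e-9)
    stop("p_staging must lie in [0, 1]")
  -((1 - g) / 2 + g * p_staging)
}

#' Combined training objective
#'
#' For fully-labeled cases, the unweighted mean of the three per-channel Dice
#' losses plus `lambda` times the staging loss; for staging-only cases, the
#' `lambda`-weighted staging loss alone.  With `lambda = 0` this reduces
#' exactly to the mean Dice loss (the ablation baseline).
#'
#' @param p_maps a [prob_maps].
#' @param labels a [seg_labels] on the same grid, or `NULL` for staging-only
#'   cases.
#' @param stage a [stage_label].
#' @param lambda balance between segmentation and staging terms (default
#'   0.02).
#' @param eps Dice smoothing, see [dice_loss()].
#' @return Scalar loss.
#' @export
combined_loss <- function(p_maps, labels, stage, lambda = 0.02, eps = 1) {
  stopifnot(inherits(p_maps, "prob_maps"))
  if (lambda < 0) stop("lambda must be >= 0")
  stg <- staging_loss(staging_probability(p_maps), stage)
  if (is.null(labels)) return(lambda * stg)
  stopifnot(inherits(labels, "seg_labels"))
  if (!identical(dim(labels$tumor), dim(p_maps$tumor)))
    stop("labels and probability maps must share one grid")
  seg <- mean(c(dice_loss(p_maps$tumor, labels$tumor, eps),
                dice_loss(p_maps$rectum, labels$rectum, eps),
                dice_loss(p_maps$mesorectum, labels$mesorectum, eps)))
  seg + lambda * stg
}
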