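#' Dice similarity coefficient
#'
#' `2 * |P intersect G| / (|P| + |G|)` between a predicted and a reference
#' binary mask; 1 means complete overlap.  When both masks are empty the DSC
#' is defined as 1 (perfect agreement on absence).
#'
#' @param pred_mask,truth_mask binary arrays of a common shape.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask))
    stop("masks must have equal size")
  p <- as.logical(pred_mask); g <- as.logical(truth_mask)
  np <- sum(p); ng <- sum(g)
  if (np + ng == 0) return(1)
  2 * sum(p & g) / (np + ng)
}

#' 2x2 staging confusion table
#'
#' Cross-tabulates predicted against ground-truth binary T stage, with
#' `GE_T3` as the positive class: `tp` = predicted and true >= T3, `tn` =
#' predicted and true <= T2, `fp`/`fn` the disagreements.  Predictions with
#' an empty tumor mask count as predicted `LE_T2`.
#'
#' @param preds list of `stage_prediction` objects (or category strings).
#' @param truths list of [stage_label] objects (or category strings).
#' @return An object of class `confusion_2x2` with fields `tp`, `fp`, `fn`,
#'   `tn`, `total`.
#' @export
staging_confusion <- function(preds, truths) {
  if (length(preds) != length(truths))
    stop("prediction and truth lists must have equal length")
  if (length(preds) == 0) stop("need at least one case")
  cat_of <- function(x) if (is.character(x)) x else x$category
  p <- vapply(preds, cat_of, "")
  g <- vapply(truths, cat_of, "")
  stopifnot(all(p %in% c("LE_T2", "GE_T3")), all(g %in% c("LE_T2", "GE_T3")))
  structure(list(tp = sum(p == "GE_T3" & g == "GE_T3"),
                 fp = sum(p == "GE_T3" & g == "LE_T2"),
                 fn = sum(p == "LE_T2" & g == "GE_T3"),
                 tn = sum(p == "LE_T2" & g == "LE_T2"),
                 total = length(p)),
            class = "confusion_2x2")
}

#' @rdname staging_confusion
#' @param tp,fp,fn,tn nonnegative counts.
#' @export
confusion_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, total = sum(counts)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2,
              dimnames = list(predicted = c("LE_T2", "GE_T3"),
                              truth = c("LE_T2", "GE_T3")))
  print(m)
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              sensitivity(x), specificity(x), accuracy(x)))
  invisible(x)
}

#' Staging classification metrics
#'
#' Sensitivity `tp / (tp + fn)` (fraction of true >= T3 cases called T3),
#' specificity `tn / (tn + fp)` (fraction of true <= T2 cases called T2) and
#' overall accuracy `(tp + tn) / total`.  A zero denominator yields `NA`
#' rather than an error.
#'
#' @param t a `confusion_2x2`.
#' @return Scalar in \[0, 1\], or `NA` for an empty denominator.
#' @export
sensitivity <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  if (t$tp + t$fn == 0) return(NA_real_)
  t$tp / (t$tp + t$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  if (t$tn + t$fp == 0) return(NA_real_)
  t$tn / (t$tn + t$fp)
}

#' @rdname sensitivity
#' @export
accuracy <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  if (t$total == 0) return(NA_real_)
  (t$tp + t$tn) / t$total
}

#' Tumor diameter from a mask
#'
#' The maximum axis-aligned bounding-box extent of the mask in physical
#' millimeters (a deterministic approximation of the maximal tumor
#' diameter).
#'
#' @param mask nonempty binary 3D array.
#' @param spacing_mm per-axis voxel size in mm.
#' @return Diameter in mm.
#' @export
tumor_diameter <- function(mask, spacing_mm) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!is.matrix(idx) || nrow(idx) == 0) stop("tumor mask is empty")
  extents <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * spacing_mm
  max(extents)
}

#' Summarize a set of DSC values
#'
#' @param values nonempty numeric vector of DSC values in \[0, 1\].
#' @return An object of class `dsc_summary` with `values`, `median` and the
#'   interquartile range `iqr = c(q25, q75)`.
#' @export
summarize_dsc <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("need at least one DSC value")
  if (any(values < 0 | values > 1)) stop("DSC values must lie in [0, 1]")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(values = values, median = q[2], iqr = c(q25 = q[1],
                                                         q75 = q[3])),
            class = "dsc_summary")
}

#' @export
print.dsc_summary <- function(x, ...) {
  cat(sprintf("<DSC n=%d median %.3f [IQR %.3f-%.3f]>\n", length(x$values),
              x$median, x$iqr[1], x$iqr[2]))
  invisible(x)
}

#' Evaluate predictions against ground truth for a cohort
#'
#' Computes per-case DSC for the three structures (labeled cases only),
#' tumor diameter from the ground-truth mask, and the pooled staging
#' confusion with sensitivity/specificity/accuracy.
#'
#' Subgroup reporting (conveniences, computed with standard routines): when
#' mucinous flags are supplied and both groups are present, a Wilcoxon
#' rank-sum comparison of tumor DSC between mucinous and non-mucinous cases;
#' when diameters are available, the Pearson correlation between tumor DSC
#' and tumor diameter (excluding mucinous cases).
#'
#' @param pred_list list of lists with `masks` ([seg_labels] or `NULL`) and
#'   `stage` (`stage_prediction`), one per case.
#' @param truth_list list of lists with `labels` ([seg_labels] or `NULL`),
#'   `stage` ([stage_label]) and optionally `spacing_mm`, `case_id`,
#'   `mucinous`.
#' @return A list with `per_case` (data.frame), `dsc_summaries`,
#'   `confusion` plus the three staging metrics, and `subgroups` (or `NULL`).
#' @export
evaluate_predictions <- function(pred_list, truth_list) {
  stopifnot(length(pred_list) == length(truth_list))
  n <- length(pred_list)
  rows <- lapply(seq_len(n), function(i) {
    pr <- pred_list[[i]]; tr <- truth_list[[i]]
    labeled <- !is.null(tr$labels) && !is.null(pr$masks)
    sp <- if (is.null(tr$spacing_mm)) c(1, 1, 1) else tr$spacing_mm
    data.frame(
      case_id = if (is.null(tr$case_id)) sprintf("case%03d", i) else tr$case_id,
      dsc_tumor = if (labeled) dsc(pr$masks$tumor, tr$labels$tumor) else NA,
      dsc_rectum = if (labeled) dsc(pr$masks$rectum, tr$labels$rectum) else NA,
      dsc_mesorectum = if (labeled)
        dsc(pr$masks$mesorectum, tr$labels$mesorectum) else NA,
      diameter_mm = if (!is.null(tr$labels) && sum(tr$labels$tumor) > 0)
        tumor_diameter(tr$labels$tumor, sp) else NA,
      stage_true = tr$stage$category,
      stage_pred = pr$stage$category,
      tumor_empty = pr$stage$tumor_empty,
      mucinous = if (is.null(tr$mucinous)) NA else tr$mucinous)
  })
  per_case <- do.call(rbind, rows)
  conf <- staging_confusion(as.list(per_case$stage_pred),
                            as.list(per_case$stage_true))
  lab <- !is.na(per_case$dsc_tumor)
  summaries <- if (any(lab)) list(
    tumor = summarize_dsc(per_case$dsc_tumor[lab]),
    rectum = summarize_dsc(per_case$dsc_rectum[lab]),
    mesorectum = summarize_dsc(per_case$dsc_mesorectum[lab])) else NULL
  subgroups <- NULL
  ok <- lab & !is.na(per_case$mucinous)
  if (any(ok)) {
    muc <- per_case$mucinous[ok]
    dt <- per_case$dsc_tumor[ok]
    if (any(muc) && any(!muc)) {
      w <- stats::wilcox.test(dt[muc], dt[!muc], exact = FALSE)
      subgroups$mucinous <- list(
        n_mucinous = sum(muc), n_other = sum(!muc),
        median_mucinous = median(dt[muc]), median_other = median(dt[!muc]),
        p_value = w$p.value)
    }
    dia <- per_case$diameter_mm[ok]
    keep <- !muc & !is.na(dia)
    if (sum(keep) >= 3 && sd(dt[keep]) > 0 && sd(dia[keep]) > 0) {
      ct <- stats::cor.test(dt[keep], dia[keep], method = "pearson")
      subgroups$diameter <- list(n = sum(keep),
                                 pearson_r = unname(ct$estimate),
                                 p_value = ct$p.value)
    }
  }
  list(per_case = per_case, dsc_summaries = summaries, confusion = conf,
       sensitivity = sensitivity(conf), specificity = specificity(conf),
       accuracy = accuracy(conf), subgroups = subgroups)
}
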