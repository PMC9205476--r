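#' Rotating k-fold cross-validation
#'
#' The cases are randomly partitioned into `k` folds.  In rotation `r`, fold
#' `r` is the evaluation set, fold `r + 1` (mod `k`) the validation set used
#' for checkpoint selection, and the remaining `k - 2` folds form the
#' training set; over all rotations every fold is the evaluation fold
#' exactly once.  Segmentation metrics (DSC) are computed only on cases
#' carrying ground-truth segmentation labels; staging metrics on all cases.
#' Evaluation-fold predictions are pooled into the final confusion table and
#' DSC summaries.
#'
#' @param cases list of [rs_case] objects (`length(cases) >= k`).
#' @param cfg a [train_config].
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment (default: `cfg$seed`).
#' @param trainer function `(train_cases, val_cases, cfg) -> model`; defaults
#'   to [train_network()] (returning its selected checkpoint).  Supplying a
#'   stub trainer allows protocol-level testing without network training.
#' @param predictor function `(model, case, cfg) -> list(masks, stage,
#'   truth_labels)`; defaults to [predict_case()] on the model's network.
#' @param stratify if `TRUE`, folds are stratified by stage; off by default
#'   (plain seeded random partition).
#' @return An object of class `cv_report`: per-rotation results, the pooled
#'   confusion table with sensitivity/specificity/accuracy, pooled DSC
#'   summaries, the fold assignment, and the seeds/config used.
#' @export
cross_validate <- function(cases, cfg = train_config(), k = 10L, seed = NULL,
                           trainer = NULL, predictor = NULL,
                           stratify = FALSE) {
  n <- length(cases)
  k <- as.integer(k)
  if (n < k) stop("need at least k cases for k folds")
  if (k < 3L) stop("rotating train/validation/evaluation roles need k >= 3")
  if (is.null(seed)) seed <- cfg$seed
  if (is.null(trainer))
    trainer <- function(train_cases, val_cases, cfg)
      train_network(train_cases, val_cases, cfg)
  if (is.null(predictor))
    predictor <- function(model, case, cfg) {
      net <- if (inherits(model, "rs_network")) model else model$network
      pr <- predict_case(net, case, cfg$target_mm, cfg$out_shape,
                         cfg$threshold)
      list(masks = pr$masks, stage = pr$stage,
           truth_labels = pr$truth_labels)
    }

  fold_of <- with_seed(substream_seed(seed, "folds"), {
    if (stratify) {
      f <- integer(n)
      for (cat in c("LE_T2", "GE_T3")) {
        idx <- which(vapply(cases, function(c) c$stage$category, "") == cat)
        f[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
      f
    } else {
      rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  if (any(tabulate(fold_of, k) == 0))
    stop("a fold received zero cases; reduce k or add cases")

  rotations <- vector("list", k)
  all_rows <- list()
  for (r in seq_len(k)) {
    eval_idx <- which(fold_of == r)
    val_idx <- which(fold_of == (r %% k) + 1L)
    train_idx <- setdiff(seq_len(n), c(eval_idx, val_idx))
    model <- trainer(cases[train_idx], cases[val_idx], cfg)

    rows <- lapply(eval_idx, function(i) {
      pr <- predictor(model, cases[[i]], cfg)
      labeled <- has_labels(cases[[i]]) && !is.null(pr$truth_labels)
      data.frame(
        case_id = cases[[i]]$case_id, rotation = r,
        stage_true = cases[[i]]$stage$category,
        stage_pred = pr$stage$category,
        tumor_empty = pr$stage$tumor_empty,
        dsc_tumor = if (labeled) dsc(pr$masks$tumor, pr$truth_labels$tumor)
          else NA_real_,
        dsc_rectum = if (labeled) dsc(pr$masks$rectum, pr$truth_labels$rectum)
          else NA_real_,
        dsc_mesorectum = if (labeled)
          dsc(pr$masks$mesorectum, pr$truth_labels$mesorectum) else NA_real_)
    })
    per_case <- do.call(rbind, rows)
    all_rows[[r]] <- per_case
    conf <- staging_confusion(as.list(per_case$stage_pred),
                              as.list(per_case$stage_true))
    lab <- !is.na(per_case$dsc_tumor)
    rotations[[r]] <- list(
      rotation = r, eval_idx = eval_idx, val_idx = val_idx,
      train_idx = train_idx, confusion = conf,
      dsc_summaries = if (any(lab)) list(
        tumor = summarize_dsc(per_case$dsc_tumor[lab]),
        rectum = summarize_dsc(per_case$dsc_rectum[lab]),
        mesorectum = summarize_dsc(per_case$dsc_mesorectum[lab])) else NULL,
      selected_iteration = if (is.list(model) &&
                               !is.null(model$selected_iteration))
        model$selected_iteration else NA_integer_)
  }
  per_case <- do.call(rbind, all_rows)
  pooled <- confusion_2x2(
    tp = sum(vapply(rotations, function(x) x$confusion$tp, 0)),
    fp = sum(vapply(rotations, function(x) x$confusion$fp, 0)),
    fn = sum(vapply(rotations, function(x) x$confusion$fn, 0)),
    tn = sum(vapply(rotations, function(x) x$confusion$tn, 0)))
  lab <- !is.na(per_case$dsc_tumor)
  structure(list(
    k = k, seed = seed, fold_of = fold_of, rotations = rotations,
    per_case = per_case, pooled_confusion = pooled,
    sensitivity = sensitivity(pooled), specificity = specificity(pooled),
    accuracy = accuracy(pooled),
    dsc_summaries = if (any(lab)) list(
      tumor = summarize_dsc(per_case$dsc_tumor[lab]),
      rectum = summarize_dsc(per_case$dsc_rectum[lab]),
      mesorectum = summarize_dsc(per_case$dsc_mesorectum[lab])) else NULL,
    selected_iterations = vapply(rotations,
                                 function(x) x$selected_iteration, 1L),
    config = cfg), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report k=%d, n=%d cases>\n", x$k, x$pooled_confusion$total))
  print(x$pooled_confusion)
  if (!is.null(x$dsc_summaries)) {
    for (nm in names(x$dsc_summaries)) {
      cat(nm, ": "); print(x$dsc_summaries[[nm]])
    }
  }
  invisible(x)
}
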