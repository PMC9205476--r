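test_that("dsc matches hand counts, symmetry and the empty convention", {
  p <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)) > 0
  g <- array(c(0, 0, 1, 1, 1, 1, 0, 0), c(2, 2, 2)) > 0
  expect_equal(dsc(p, g), 0.5)            # |P|=4, |G|=4, |P&G|=2
  expect_equal(dsc(p, p), 1)
  expect_equal(dsc(p, !p), 0)
  expect_equal(dsc(p, g), dsc(g, p))
  expect_equal(dsc(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))), 1)
})

test_that("dsc complements dice_loss on binary inputs", {
  set.seed(7)
  for (i in 1:30) {
    p <- runif(60) > 0.5
    g <- runif(60) > 0.5
    expect_equal(dsc(p, g), 1 - dice_loss(as.numeric(p), as.numeric(g),
                                          eps = 0))
    # the eps=1 smoothing perturbs by at most 1/(|P|+|G|)
    if (sum(p) + sum(g) > 0)
      expect_lt(abs(dsc(p, g) - (1 - dice_loss(as.numeric(p), as.numeric(g),
                                               eps = 1))),
                1 / (sum(p) + sum(g)))
    expect_equal(dsc(p, g), brute_dsc(p, g))
  }
})

test_that("the study contingency table reproduces the printed metrics", {
  t <- confusion_2x2(tp = 92, fp = 19, fn = 27, tn = 63)
  expect_equal(t$total, 201)
  expect_equal(round(sensitivity(t), 3), 0.773)
  expect_equal(round(specificity(t), 3), 0.768)
  expect_equal(round(accuracy(t), 3), 0.771)
  # same table assembled from case-level predictions
  preds <- c(rep("GE_T3", 92), rep("LE_T2", 27), rep("GE_T3", 19),
             rep("LE_T2", 63))
  truths <- c(rep("GE_T3", 119), rep("LE_T2", 82))
  t2 <- staging_confusion(as.list(preds), as.list(truths))
  expect_equal(t2$tp, 92); expect_equal(t2$fn, 27)
  expect_equal(t2$fp, 19); expect_equal(t2$tn, 63)
  expect_equal(t2$tp + t2$fp, 111)        # predicted >= T3 row total
  expect_equal(t2$fn + t2$tn, 90)         # predicted <= T2 row total
})

test_that("degenerate confusion tables give NA sentinels, not errors", {
  t <- confusion_2x2(tp = 0, fp = 3, fn = 0, tn = 7)
  expect_true(is.na(sensitivity(t)))
  expect_equal(specificity(t), 0.7)
  perfect <- confusion_2x2(tp = 5, fp = 0, fn = 0, tn = 5)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(accuracy(perfect), 1)
  expect_error(staging_confusion(list(), list()), "at least one")
  expect_error(staging_confusion(list("GE_T3"), list()), "equal length")
})

test_that("metrics reproduce a brute-force recount over cases", {
  set.seed(8)
  p <- sample(c("LE_T2", "GE_T3"), 50, replace = TRUE)
  g <- sample(c("LE_T2", "GE_T3"), 50, replace = TRUE)
  t <- staging_confusion(as.list(p), as.list(g))
  n_correct <- 0L
  for (i in 1:50) if (p[i] == g[i]) n_correct <- n_correct + 1L
  expect_equal(accuracy(t), n_correct / 50)
  expect_equal(sensitivity(t), sum(p == "GE_T3" & g == "GE_T3") /
                 sum(g == "GE_T3"))
})

test_that("tumor diameter is the largest bounding-box extent in mm", {
  d <- c(50L, 10L, 10L)
  single <- array(FALSE, d); single[3, 3, 3] <- TRUE
  expect_equal(tumor_diameter(single, 0.5), 0.5)
  rod <- array(FALSE, d); rod[1:40, 5, 5] <- TRUE
  expect_equal(tumor_diameter(rod, 0.5), 20)   # the small-tumor cutoff scale
  # sphere of radius r: diameter within one voxel of 2r
  r <- 5
  sph <- array(FALSE, c(16L, 16L, 16L))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    if ((i - 8)^2 + (j - 8)^2 + (k - 8)^2 <= r^2) sph[i, j, k] <- TRUE
  expect_lt(abs(tumor_diameter(sph, 1) - 2 * r), 1.5)
  expect_error(tumor_diameter(array(FALSE, c(2, 2, 2)), 1), "empty")
})

test_that("dsc summaries report median and interquartile range", {
  s <- summarize_dsc(c(0.2, 0.5, 0.8))
  expect_equal(s$median, 0.5)
  cs <- summarize_dsc(rep(0.7, 10))
  expect_equal(unname(diff(cs$iqr)), 0)
  set.seed(9)
  u <- summarize_dsc(runif(300))
  expect_lt(abs(u$median - 0.5), 0.1)
  expect_true(u$iqr[1] <= u$median && u$median <= u$iqr[2])
  expect_error(summarize_dsc(numeric(0)), "at least one")
  expect_error(summarize_dsc(c(0.2, 1.4)), "0, 1")
})

test_that("cohort evaluation reports subgroup statistics when available", {
  set.seed(10)
  d <- c(6L, 6L, 4L)
  mk_truth <- function(mucinous, stage, size = 3L) {
    tum <- array(FALSE, d); tum[2:(1 + size), 2:4, 2:3] <- TRUE
    list(labels = seg_labels(tum, array(TRUE, d), array(FALSE, d)),
         stage = stage_label(stage), spacing_mm = c(1, 1, 1),
         mucinous = mucinous)
  }
  mk_pred <- function(truth, jitter) {
    m <- truth$labels
    flip <- sample(length(m$tumor), jitter)
    m$tumor[flip] <- !m$tumor[flip]
    list(masks = m, stage = classify_stage(m))
  }
  truths <- c(lapply(1:6, function(i)
                mk_truth(FALSE, "LE_T2", size = 1L + (i %% 4))),
              lapply(1:2, function(i) mk_truth(TRUE, "LE_T2")))
  preds <- lapply(seq_along(truths), function(i)
    mk_pred(truths[[i]], jitter = if (i > 6) 20 else i))
  ev <- evaluate_predictions(preds, truths)
  expect_false(is.null(ev$subgroups$mucinous))
  expect_equal(ev$subgroups$mucinous$n_mucinous, 2)
  expect_lte(ev$subgroups$mucinous$median_mucinous,
             ev$subgroups$mucinous$median_other)
  expect_true(ev$subgroups$mucinous$p_value >= 0 &&
                ev$subgroups$mucinous$p_value <= 1)
  expect_false(is.null(ev$subgroups$diameter))
  expect_equal(ev$subgroups$diameter$n, 6)
  expect_true(abs(ev$subgroups$diameter$pearson_r) <= 1)
})
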