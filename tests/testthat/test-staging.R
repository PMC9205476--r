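test_that("binarization is strict at the threshold", {
  d <- c(3L, 3L, 1L)
  tum <- array(0.5, d); tum[1, 1, 1] <- 0.5 + 1e-9; tum[2, 1, 1] <- 0.49
  pm <- prob_maps(tum, array(1, d), array(0, d))
  m <- binarize(pm)
  expect_true(m$tumor[1, 1, 1])       # strictly above
  expect_false(m$tumor[2, 1, 1])
  expect_false(m$tumor[3, 1, 1])      # exactly at threshold -> background
  expect_true(all(m$rectum))
  expect_false(any(m$mesorectum))
  expect_error(binarize(pm, threshold = 0), "threshold")
})

test_that("a perfectly fit phantom binarizes back to its labels", {
  case <- generate_phantom(tiny_spec())
  labs <- case$labels
  pm <- prob_maps(labs$tumor * 0.99, labs$rectum * 0.99,
                  labs$mesorectum * 0.99)
  m <- binarize(pm)
  expect_equal(m$tumor, labs$tumor)
  expect_equal(m$rectum, labs$rectum)
  expect_equal(m$mesorectum, labs$mesorectum)
})

test_that("the staging rule follows the tumor-outside-rectum dichotomy", {
  t2 <- generate_phantom(tiny_spec(invasion_depth_mm = -1))
  pr <- classify_stage(t2$labels)
  expect_equal(pr$category, "LE_T2")
  expect_equal(pr$breach_voxel_count, 0L)
  expect_false(pr$tumor_empty)

  # moving a single tumor voxel outside the rectum flips the class
  labs <- t2$labels
  outside <- which(!labs$rectum & !labs$tumor)[1]
  labs$tumor[outside] <- TRUE
  pr2 <- classify_stage(labs)
  expect_equal(pr2$category, "GE_T3")
  expect_equal(pr2$breach_voxel_count, 1L)
})

test_that("an empty tumor mask yields LE_T2 with the quality flag", {
  d <- c(4L, 4L, 2L)
  m <- seg_labels(array(FALSE, d), array(TRUE, d), array(FALSE, d))
  pr <- classify_stage(m)
  expect_equal(pr$category, "LE_T2")
  expect_true(pr$tumor_empty)
})

test_that("classification agrees with a brute-force voxel scan", {
  set.seed(4)
  for (i in 1:60) {
    m <- random_masks(c(4L, 4L, 2L), p = runif(1, 0.1, 0.9))
    got <- classify_stage(m)
    want <- brute_classify_stage(m)
    expect_equal(got$category, want$category)
    expect_equal(got$breach_voxel_count, want$breach_voxel_count)
    expect_equal(got$tumor_empty, want$tumor_empty)
  }
})

test_that("stage monotonicity under mask growth", {
  set.seed(5)
  for (i in 1:20) {
    m <- random_masks(c(5L, 4L, 2L), p = 0.3)
    base <- classify_stage(m)$category
    # adding tumor voxels can only move LE_T2 -> GE_T3
    m2 <- m
    add <- which(!m2$tumor)[seq_len(3)]
    m2$tumor[add] <- TRUE
    grown <- classify_stage(m2)$category
    if (base == "GE_T3") expect_equal(grown, "GE_T3")
    # adding rectum voxels can only move GE_T3 -> LE_T2
    m3 <- m
    addr <- which(!m3$rectum)[seq_len(3)]
    m3$rectum[addr] <- TRUE
    covered <- classify_stage(m3)$category
    if (base == "LE_T2") expect_equal(covered, "LE_T2")
  }
})

test_that("breach presence matches the binarized staging signal", {
  set.seed(6)
  for (i in 1:20) {
    m <- random_masks(c(4L, 4L, 3L))
    pm <- prob_maps(m$tumor + 0, m$rectum + 0, m$mesorectum + 0)
    p_stg <- staging_probability(pm)
    if (classify_stage(m)$breach_voxel_count > 0) {
      expect_equal(p_stg, 1)
    } else {
      expect_lt(p_stg, 1)
    }
  }
})

test_that("contour-strict mode flags tumors touching the rectum boundary", {
  d <- c(7L, 7L, 3L)
  rectum <- array(FALSE, d); rectum[2:6, 2:6, 1:3] <- TRUE
  tumor <- array(FALSE, d); tumor[4, 4, 2] <- TRUE      # deep interior
  m <- seg_labels(tumor, rectum, array(FALSE, d))
  expect_equal(classify_stage(m)$category, "LE_T2")
  expect_equal(classify_stage(m, contour_strict = TRUE)$category, "LE_T2")
  tumor[2, 4, 2] <- TRUE                                 # on the contour
  m2 <- seg_labels(tumor, rectum, array(FALSE, d))
  expect_equal(classify_stage(m2)$category, "LE_T2")
  expect_equal(classify_stage(m2, contour_strict = TRUE)$category, "GE_T3")
})
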