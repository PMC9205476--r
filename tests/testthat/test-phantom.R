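test_that("phantom spec validation rejects impossible anatomy", {
  expect_error(phantom_spec(lumen_radius_mm = 6, wall_thickness_mm = 4,
                            mesorectum_radius_mm = 9), "mesorectum_radius")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_spec(tumor_angular_extent_deg = 0), "angular")
  expect_error(phantom_spec(tumor_angular_extent_deg = 400), "angular")
})

test_that("T2 geometry confines the tumor to the rectum", {
  case <- generate_phantom(tiny_spec(invasion_depth_mm = -1))
  expect_equal(case$stage$category, "LE_T2")
  expect_true(sum(case$labels$tumor) > 0)
  expect_true(all(case$labels$rectum[case$labels$tumor]))
})

test_that("T3 geometry breaches into the mesorectum", {
  case <- generate_phantom(tiny_spec(invasion_depth_mm = 3))
  expect_equal(case$stage$category, "GE_T3")
  expect_gt(sum(case$labels$tumor & !case$labels$rectum), 0)
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(tiny_spec(seed = 42L))
  b <- generate_phantom(tiny_spec(seed = 42L))
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$labels, b$labels)
  c <- generate_phantom(tiny_spec(seed = 43L))
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("masks satisfy the anatomy invariants", {
  for (inv in c(-1.5, -0.5, 2, 3.5)) {
    case <- generate_phantom(tiny_spec(invasion_depth_mm = inv))
    labs <- case$labels
    expect_false(any(labs$rectum & labs$mesorectum))
    expect_true(all(labs$rectum[labs$tumor] | labs$mesorectum[labs$tumor]))
    # staging rule self-consistency: breach <=> tumor touches mesorectum
    breach <- any(labs$tumor & !labs$rectum)
    expect_equal(any(labs$tumor & labs$mesorectum), breach)
    expect_equal(case$stage$category, if (breach) "GE_T3" else "LE_T2")
  }
})

test_that("deeper invasion never shrinks the extramural tumor volume", {
  breaches <- vapply(c(-1, 0.5, 1.5, 2.5, 3.5), function(inv) {
    labs <- generate_phantom(tiny_spec(invasion_depth_mm = inv))$labels
    sum(labs$tumor & !labs$rectum)
  }, 0)
  expect_true(all(diff(breaches) >= 0))
})

test_that("zero noise yields exact tissue means", {
  means <- list(background = 10, lumen = 25, wall = 50, mesorectum = 180,
                tumor = 100, mucinous = 210)
  case <- generate_phantom(tiny_spec(noise_sigma = 0,
                                     intensity_means = means))
  labs <- case$labels
  v <- case$volume$values
  expect_true(all(v[labs$tumor] == means$tumor))
  expect_true(all(v[labs$mesorectum & !labs$tumor] == means$mesorectum))
  muc <- generate_phantom(tiny_spec(noise_sigma = 0, mucinous = TRUE,
                                    intensity_means = means))
  expect_true(all(muc$volume$values[muc$labels$tumor] == means$mucinous))
})

test_that("cohort composition follows the requested fractions", {
  cases <- tiny_cohort(10, t3_fraction = 0.5, seg_labeled_fraction = 0.6,
                       mucinous_fraction = 0, seed = 5)
  m <- cohort_manifest(cases)
  expect_equal(sum(m$has_labels), 6)
  expect_equal(sum(!m$has_labels), 4)
  expect_equal(sum(m$stage == "GE_T3"), 5)
  expect_false(any(m$mucinous))
  # staging-only cases still carry a stage
  expect_true(all(m$stage %in% c("LE_T2", "GE_T3")))
})

test_that("a cohort mirroring the study composition has the right counts", {
  cases <- tiny_cohort(201, t3_fraction = 119 / 201,
                       seg_labeled_fraction = 135 / 201, seed = 9)
  m <- cohort_manifest(cases)
  expect_equal(length(cases), 201)
  expect_equal(sum(m$has_labels), 135)
  expect_equal(sum(m$stage == "GE_T3"), 119)
  expect_equal(sum(m$stage == "LE_T2"), 82)
})

test_that("cohort generation rejects invalid ranges", {
  expect_error(tiny_cohort(5, spec_ranges = c(tiny_ranges()[-1],
    list(lumen_radius_mm = c(5, 2)))), "range")
  expect_error(generate_cohort(0), "n must be")
  expect_error(tiny_cohort(5, t3_fraction = 1.2), "fractions")
})

test_that("the tumor center lies inside the tumor's bounding region", {
  case <- generate_phantom(tiny_spec())
  idx <- which(case$labels$tumor, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * case$volume$spacing_mm
  hi <- (apply(idx, 2, max) - 1) * case$volume$spacing_mm
  expect_true(all(case$center_mm >= lo - 1e-9 & case$center_mm <= hi + 1e-9))
})
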