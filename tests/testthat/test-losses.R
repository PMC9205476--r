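test_that("dice loss matches the exact formula on hand-computed cases", {
  # hand evaluation: 1 - 2*1/(2+2) = 0.5
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 1, 1, 0), eps = 0), 0.5)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 1, 0, 0), eps = 0), 0)
  expect_equal(dice_loss(c(0, 0, 0, 0), c(0, 1, 1, 0), eps = 0), 1)
  # smoothed variant: exact at perfect overlap, within eps-bound otherwise
  g <- c(rep(1, 20), rep(0, 20))
  expect_equal(dice_loss(g, g, eps = 1), 0)
  expect_equal(dice_loss(rep(0, 40), g, eps = 1), 1 - 1 / 21)
  expect_equal(dice_loss(numeric(0), numeric(0), eps = 0), 0)
})

test_that("dice loss is permutation-invariant and differentiable", {
  set.seed(1)
  p <- runif(50)
  g <- as.numeric(runif(50) > 0.5)
  perm <- sample(50)
  expect_equal(dice_loss(p, g), dice_loss(p[perm], g[perm]))
  # analytic gradient against central differences
  gr <- rectseg:::dice_loss_grad(p, g, eps = 1)
  for (i in c(1, 17, 42)) {
    pp <- p; pp[i] <- pp[i] + 1e-6
    pm <- p; pm[i] <- pm[i] - 1e-6
    expect_equal(gr[i], (dice_loss(pp, g) - dice_loss(pm, g)) / 2e-6,
                 tolerance = 1e-5)
  }
})

test_that("staging probability picks the most incriminating voxel", {
  d <- c(4L, 3L, 2L)
  tum <- array(0, d); rec <- array(0, d)
  tum[2, 2, 1] <- 0.9; rec[2, 2, 1] <- 0.2
  pm <- prob_maps(tum, rec, array(0, d))
  expect_equal(staging_probability(pm), 0.9 * 0.8)
  # tumor fully inside a confident rectum contributes nothing
  pm2 <- prob_maps(array(1, d), array(1, d), array(0, d))
  expect_equal(staging_probability(pm2), 0)
  pm3 <- prob_maps(array(0, d), array(runif(prod(d)), d), array(0, d))
  expect_equal(staging_probability(pm3), 0)
})

test_that("staging loss has the prescribed range, values and gradient", {
  t3 <- stage_label("GE_T3"); t2 <- stage_label("LE_T2")
  expect_equal(staging_loss(1, t3), -1)
  expect_equal(staging_loss(0, t2), -1)
  expect_equal(staging_loss(1, t2), 0)
  expect_equal(staging_loss(0, t3), 0)
  # linear in p_staging with slope exactly -g_staging
  for (stg in list(t3, t2)) {
    slope <- (staging_loss(0.8, stg) - staging_loss(0.3, stg)) / 0.5
    expect_equal(slope, -stg$g_staging)
  }
  for (p in seq(0, 1, by = 0.1)) {
    expect_gte(staging_loss(p, t3), -1)
    expect_lte(staging_loss(p, t3), 0)
  }
  expect_error(staging_loss(1.4, t3), "p_staging")
})

test_that("combined loss composes its terms as specified", {
  case <- generate_phantom(tiny_spec(invasion_depth_mm = -1,
                                     noise_sigma = 0))
  labs <- case$labels
  d <- dim(labs$tumor)
  # perfect prediction of a T2 case: zero Dice loss, staging term at optimum
  pm <- prob_maps(labs$tumor + 0, labs$rectum + 0, labs$mesorectum + 0)
  expect_equal(combined_loss(pm, labs, case$stage, lambda = 0.02),
               0.02 * -1)
  # staging-only case: lambda * staging loss alone
  expect_equal(combined_loss(pm, NULL, stage_label("GE_T3"), lambda = 0.02),
               0.02 * staging_loss(staging_probability(pm),
                                   stage_label("GE_T3")))
  # lambda = 0 reduces bit-for-bit to the mean Dice loss (ablation baseline)
  set.seed(2)
  pmr <- random_prob_maps(d)
  expect_identical(combined_loss(pmr, labs, case$stage, lambda = 0),
                   mean(c(dice_loss(pmr$tumor, labs$tumor),
                          dice_loss(pmr$rectum, labs$rectum),
                          dice_loss(pmr$mesorectum, labs$mesorectum))))
})

test_that("staging probability equals a brute-force voxel scan", {
  set.seed(3)
  for (i in 1:25) {
    pm <- random_prob_maps(c(4L, 3L, 3L))
    expect_equal(staging_probability(pm), brute_staging_probability(pm))
  }
})
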