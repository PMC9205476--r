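tiny_net_config <- function(levels = 3L, base = 4L)
  network_config(levels = levels, base_channels = base)

test_that("configuration is validated", {
  expect_error(network_config(levels = 1), "levels")
  expect_error(network_config(out_channels = 2), "out_channels")
  expect_error(network_config(conv_kernel_per_level = list(c(3, 3, 3))),
               "one conv kernel per level")
  expect_error(network_config(levels = 2,
                              conv_kernel_per_level = list(c(3, 3, 3),
                                                           c(5, 3, 3))),
               "sizes 1 and 3")
})

test_that("output shape and range honor the contract", {
  net <- build_network(tiny_net_config(), seed = 1)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), rep(1, 3))
  pm <- forward(net, g)
  expect_s3_class(pm, "prob_maps")
  expect_equal(dim(pm$tumor), c(16L, 16L, 16L))
  for (ch in c("tumor", "rectum", "mesorectum")) {
    expect_true(all(pm[[ch]] >= 0 & pm[[ch]] <= 1))
  }
})

test_that("indivisible input shapes raise an error naming the axis", {
  net <- build_network(tiny_net_config(levels = 3), seed = 1)
  g <- voxel_grid(array(0, c(16, 18, 16)), rep(1, 3))
  expect_error(forward(net, g), "axis 2")
})

test_that("parameter count strictly increases with base channels", {
  n <- vapply(c(2, 4, 8), function(b)
    n_parameters(build_network(tiny_net_config(base = b), seed = 1)), 0)
  expect_true(all(diff(n) > 0))
})

test_that("inference is deterministic for fixed weights", {
  net <- build_network(tiny_net_config(), seed = 3)
  g <- voxel_grid(array(rnorm(16^3), c(16, 16, 16)), rep(1, 3))
  p1 <- forward(net, g)
  p2 <- forward(net, g)
  expect_identical(p1, p2)
  # and initialization is deterministic per seed
  net2 <- build_network(tiny_net_config(), seed = 3)
  expect_identical(net$layers$head$W, net2$layers$head$W)
})

test_that("gradients flow to every trainable tensor", {
  net <- build_network(tiny_net_config(levels = 2, base = 2), seed = 5)
  dims <- c(8L, 8L, 8L)
  nb <- 2L
  set.seed(11)
  X <- matrix(rnorm(prod(dims) * nb), ncol = 1)
  fw <- rectseg:::net_forward(net, X, nb, dims, train = TRUE,
                              keep_cache = TRUE)
  dP <- matrix(rnorm(length(fw$P)), nrow(fw$P), 3)
  grads <- rectseg:::net_backward(net, fw$caches, dP, nb)
  for (nm in names(net$layers)) {
    for (fp in list(c("W", "dW"), c("b", "db"), c("gamma", "dgamma"),
                    c("beta", "dbeta"))) {
      if (is.null(net$layers[[nm]][[fp[1]]])) next
      gnorm <- sqrt(sum(grads[[nm]][[fp[2]]]^2))
      expect_gt(gnorm, 0)
    }
  }
})

test_that("backpropagation matches finite differences", {
  net <- build_network(tiny_net_config(levels = 2, base = 2), seed = 6)
  dims <- c(8L, 8L, 8L)
  set.seed(12)
  X <- matrix(rnorm(prod(dims)), ncol = 1)
  G <- matrix(as.numeric(runif(prod(dims) * 3) > 0.7), ncol = 3)
  stg <- list(stage_label("GE_T3"))
  tensors <- list(list(G = G))
  loss_of <- function(net) {
    fw <- rectseg:::net_forward(net, X, 1L, dims, train = TRUE)
    rectseg:::batch_loss_grad(fw$P, tensors, stg, prod(dims), 0.02, 1)$loss
  }
  fw <- rectseg:::net_forward(net, X, 1L, dims, train = TRUE,
                              keep_cache = TRUE)
  lg <- rectseg:::batch_loss_grad(fw$P, tensors, stg, prod(dims), 0.02, 1)
  grads <- rectseg:::net_backward(net, fw$caches, lg$dP, 1L)
  # spot-check a handful of weights in distinct layers; the engine runs in
  # single precision, so compare at float-scale tolerance
  set.seed(13)
  for (nm in c("enc_conv_1", "down_2", "up_1", "skip_1", "head")) {
    i <- sample(length(net$layers[[nm]]$W), 1)
    h <- 1e-3
    np <- net; np$layers[[nm]]$W[i] <- np$layers[[nm]]$W[i] + h
    nn <- net; nn$layers[[nm]]$W[i] <- nn$layers[[nm]]$W[i] - h
    num <- (loss_of(np) - loss_of(nn)) / (2 * h)
    expect_equal(grads[[nm]]$dW[i], num, tolerance = 0.05)
  }
})

test_that("thresholded inference is translation-consistent", {
  cfg <- tiny_net_config(levels = 2, base = 4)
  net <- build_network(cfg, seed = 8)
  d <- c(16L, 16L, 16L)
  vol <- array(0, d)
  vol[5:8, 5:8, 5:8] <- 3
  shift <- 2L ^ (cfg$levels - 1L)
  vol2 <- array(0, d)
  vol2[(5:8) + shift, 5:8, 5:8] <- 3
  p1 <- forward(net, voxel_grid(vol, rep(1, 3)))
  p2 <- forward(net, voxel_grid(vol2, rep(1, 3)))
  m1 <- binarize(p1)$tumor
  m2 <- binarize(p2)$tumor
  # m2 should equal m1 shifted along x, away from the volume boundary
  keep <- (shift + 1):(d[1] - shift)
  expect_gt(mean(m1[keep - shift, , ] == m2[keep, , ]), 0.98)
})

test_that("checkpoints round-trip through disk", {
  net <- build_network(tiny_net_config(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(net$layers, net2$layers)
  expect_identical(net$config, net2$config)
})
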