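#' Configuration of the 3D encoder-decoder segmentation network
#'
#' The architecture is a 3D U-Net-style encoder-decoder with skip
#' connections.  Each encoder/decoder block is a convolution + batch
#' normalization + rectified-linear unit; downsampling uses stride-2 3x3x3
#' convolutions, upsampling uses transposed convolutions with a 4x4x4 kernel,
#' and each skip connection passes through a 1x1x1 convolution + batch
#' normalization + ReLU before being summed into the decoder path.  The head
#' is a 1x1x1 convolution to 3 channels followed by a per-channel sigmoid
#' (multi-label output: tumor and rectum legitimately overlap).  Channel
#' order of the output is fixed: tumor, rectum, mesorectum.
#'
#' @param levels number of resolution levels (>= 2); the input spatial shape
#'   must be divisible by `2^(levels - 1)`.
#' @param base_channels channels at the finest level; doubled per level.
#' @param conv_kernel_per_level list of per-level kernels, each `c(3,3,3)` or
#'   `c(3,3,1)` (through-plane-thin option).  Default: `c(3,3,1)` at the
#'   first level, `c(3,3,3)` elsewhere.
#' @param out_channels fixed at 3 (tumor, rectum, mesorectum).
#' @return An object of class `network_config`.
#' @export
network_config <- function(levels = 4L, base_channels = 16L,
                           conv_kernel_per_level = NULL, out_channels = 3L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (out_channels != 3L) stop("out_channels is fixed at 3")
  if (is.null(conv_kernel_per_level))
    conv_kernel_per_level <- c(list(c(3L, 3L, 1L)),
                               rep(list(c(3L, 3L, 3L)), levels - 1L))
  if (length(conv_kernel_per_level) != levels)
    stop("need one conv kernel per level")
  for (k in conv_kernel_per_level)
    if (!(length(k) == 3L && all(k %in% c(1L, 3L))))
      stop("per-level kernels must combine sizes 1 and 3, e.g. c(3,3,3)")
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 conv_kernel_per_level = lapply(conv_kernel_per_level,
                                                as.integer),
                 deconv_kernel = c(4L, 4L, 4L), out_channels = 3L),
            class = "network_config")
}

level_channels <- function(config)
  config$base_channels * 2L^(seq_len(config$levels) - 1L)

new_conv_layer <- function(cin, cout, kernel, stride = c(1L, 1L, 1L),
                           bn = TRUE, act = "relu") {
  kprod <- prod(kernel)
  list(type = "conv", cin = cin, cout = cout, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer((kernel - 1L) %/% 2L),
       bn = bn, act = act,
       W = matrix(rnorm(cin * kprod * cout, 0, sqrt(2 / (cin * kprod))),
                  cin * kprod, cout),
       b = if (bn) NULL else rep(0, cout),
       gamma = if (bn) rep(1, cout) else NULL,
       beta = if (bn) rep(0, cout) else NULL,
       rm = if (bn) rep(0, cout) else NULL,
       rv = if (bn) rep(1, cout) else NULL)
}

new_deconv_layer <- function(cin, cout) {
  # transposed conv, kernel 4^3, stride 2, pad 1; each output voxel receives
  # 8 taps per input channel
  list(type = "deconv", cin = cin, cout = cout, bn = TRUE, act = "relu",
       W = matrix(rnorm(cin * cout * 64, 0, sqrt(2 / (cin * 8))), cin,
                  cout * 64),
       b = NULL, gamma = rep(1, cout), beta = rep(0, cout),
       rm = rep(0, cout), rv = rep(1, cout))
}

#' Build the segmentation network
#'
#' Initializes all weights (He initialization) reproducibly from `seed`.
#'
#' @param config a [network_config].
#' @param seed integer seed for weight initialization.
#' @return An object of class `rs_network`.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  ch <- level_channels(config)
  L <- config$levels
  with_seed(substream_seed(seed, "weights"), {
    layers <- list()
    layers$enc_conv_1 <- new_conv_layer(1L, ch[1],
                                        config$conv_kernel_per_level[[1]])
    for (l in 2:L) {
      layers[[paste0("down_", l)]] <-
        new_conv_layer(ch[l - 1], ch[l], c(3L, 3L, 3L), stride = c(2L, 2L, 2L))
      layers[[paste0("enc_conv_", l)]] <-
        new_conv_layer(ch[l], ch[l], config$conv_kernel_per_level[[l]])
    }
    for (l in seq(L - 1, 1)) {
      layers[[paste0("up_", l)]] <- new_deconv_layer(ch[l + 1], ch[l])
      layers[[paste0("skip_", l)]] <- new_conv_layer(ch[l], ch[l],
                                                     c(1L, 1L, 1L))
      layers[[paste0("dec_conv_", l)]] <-
        new_conv_layer(ch[l], ch[l], config$conv_kernel_per_level[[l]])
    }
    layers$head <- new_conv_layer(ch[1], config$out_channels, c(1L, 1L, 1L),
                                  bn = FALSE, act = "sigmoid")
    # start foreground probabilities low (~0.12): with Dice-type losses a
    # 0.5 everywhere start drowns small structures in the denominator
    layers$head$b <- rep(-2, config$out_channels)
    structure(list(config = config, layers = layers), class = "rs_network")
  })
}

#' @export
print.rs_network <- function(x, ...) {
  cat(sprintf("<rs_network levels=%d base=%d params=%d>\n", x$config$levels,
              x$config$base_channels, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param network an `rs_network`.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$layers, function(ly)
    length(ly$W) + length(ly$b) + length(ly$gamma) + length(ly$beta), 0))
}

check_input_dims <- function(config, dims) {
  div <- 2L^(config$levels - 1L)
  bad <- which(dims %% div != 0L)
  if (length(bad))
    stop(sprintf(paste0("input axis %d (length %d) is not divisible by ",
                        "2^(levels-1) = %d"), bad[1], dims[bad[1]], div))
  invisible(TRUE)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# One conv/deconv + BN + activation block.  Activations travel between
# blocks as single-precision C++ buffers (external pointers), so a whole
# forward/backward pass performs no R-level copies of activation matrices.
# BN and ReLU run through fused single-pass kernels; the cache keeps the
# pre-BN activations, from which the backward pass recomputes the normalized
# values and the ReLU mask.  The head (no BN, sigmoid) hands its output back
# to R as a double matrix of probabilities.
# Returns output, cache, and (in training) the layer with updated BN
# running stats.
block_fwd <- function(layer, xp, nb, dims, train = FALSE) {
  if (layer$type == "conv") {
    Yc <- cpp_conv3_fwd_f(xp, nb, dims, layer$W,
                          if (is.null(layer$b)) rep(0, layer$cout) else
                            layer$b,
                          layer$kernel, layer$stride, layer$pad)
    dims_out <- cpp_conv_out_dims(dims, layer$kernel, layer$stride, layer$pad)
  } else {
    Yc <- cpp_convt3_fwd_f(xp, nb, dims, layer$W)
    dims_out <- dims * 2L
  }
  cache <- list(X = xp, dims = dims, dims_out = dims_out)
  if (isTRUE(layer$bn)) {
    if (train) {
      st <- cpp_bn_stats_f(Yc)
      mu <- as.numeric(st$mu)
      v <- as.numeric(st$var)
      layer$rm <- (1 - BN_MOMENTUM) * layer$rm + BN_MOMENTUM * mu
      layer$rv <- (1 - BN_MOMENTUM) * layer$rv + BN_MOMENTUM * v
    } else {
      mu <- layer$rm
      v <- layer$rv
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    out <- cpp_bn_relu_fwd_f(Yc, mu, invstd, layer$gamma, layer$beta,
                             identical(layer$act, "relu"))
    cache$Yc <- Yc
    cache$mu <- mu
    cache$invstd <- invstd
    cache$batch_stats <- train
  } else if (identical(layer$act, "sigmoid")) {
    out <- 1 / (1 + exp(-cpp_fm_mat(Yc)))
    cache$out <- out
  } else {
    out <- Yc
  }
  list(out = out, cache = cache, layer = layer)
}

# Backward through one block; takes/returns activation-gradient buffers
# (the head takes a double matrix), plus parameter gradients as R numerics.
block_bwd <- function(layer, cache, dOut, nb, need_dx = TRUE) {
  g <- list()
  if (isTRUE(layer$bn)) {
    r <- cpp_bn_relu_bwd_f(cache$Yc, dOut, cache$mu, cache$invstd,
                           layer$gamma, layer$beta,
                           identical(layer$act, "relu"),
                           isTRUE(cache$batch_stats))
    g$dgamma <- as.numeric(r$dgamma)
    g$dbeta <- as.numeric(r$dbeta)
    dOut <- r$dY
  } else if (identical(layer$act, "sigmoid")) {
    dOut <- cpp_fm_new(dOut * cache$out * (1 - cache$out))
  }
  if (layer$type == "conv") {
    res <- cpp_conv3_bwd_f(cache$X, nb, cache$dims, layer$W, dOut,
                           layer$kernel, layer$stride, layer$pad, need_dx)
  } else {
    res <- cpp_convt3_bwd_f(cache$X, nb, cache$dims, layer$W, dOut)
  }
  g$dW <- res$dW
  if (!is.null(layer$b)) g$db <- as.numeric(res$db)
  list(dX = res$dX, grads = g)
}

# Full forward pass.  X: [nvox*nb, 1] matrix of normalized intensities.
# Returns the sigmoid probabilities [nvox*nb, 3] and, when keep_cache, the
# per-block caches needed by net_backward; when train, also the network with
# updated BN running statistics.
net_forward <- function(network, X, nb, dims, train = FALSE,
                        keep_cache = FALSE) {
  config <- network$config
  check_input_dims(config, dims)
  L <- config$levels
  layers <- network$layers
  caches <- list()
  run <- function(name, X, dims) {
    r <- block_fwd(layers[[name]], X, nb, dims, train = train)
    if (train) layers[[name]] <<- r$layer
    if (keep_cache) caches[[name]] <<- r$cache
    r
  }
  dims_l <- dims
  enc <- list()
  X <- cpp_fm_new(X)
  r <- run("enc_conv_1", X, dims_l)
  enc[[1]] <- r$out
  enc_dims <- list(dims_l)
  for (l in 2:L) {
    r <- run(paste0("down_", l), enc[[l - 1]], enc_dims[[l - 1]])
    dims_l <- r$cache$dims_out
    r <- run(paste0("enc_conv_", l), r$out, dims_l)
    enc[[l]] <- r$out
    enc_dims[[l]] <- dims_l
  }
  d <- enc[[L]]
  for (l in seq(L - 1, 1)) {
    ru <- run(paste0("up_", l), d, enc_dims[[l + 1]])
    rs <- run(paste0("skip_", l), enc[[l]], enc_dims[[l]])
    d <- cpp_add_f(ru$out, rs$out)
    r <- run(paste0("dec_conv_", l), d, enc_dims[[l]])
    d <- r$out
  }
  r <- run("head", d, dims)
  out <- list(P = r$out, dims = dims, nb = nb)
  if (keep_cache) out$caches <- caches
  if (train) out$network <- structure(list(config = config, layers = layers),
                                      class = "rs_network")
  out
}

# Backward pass from dP (gradient of the loss in the probability output).
# Decoder level 1 is the last block of the forward pass, so walking decoder
# levels 1..L-1 here is reverse topological order; the summed skip fusion
# splits the incoming gradient to both branches unchanged.
# Returns named per-layer gradient lists.
net_backward <- function(network, caches, dP, nb) {
  L <- network$config$levels
  layers <- network$layers
  grads <- list()
  bwd <- function(name, dOut, need_dx = TRUE) {
    r <- block_bwd(layers[[name]], caches[[name]], dOut, nb, need_dx)
    grads[[name]] <<- r$grads
    r$dX
  }
  dd <- bwd("head", dP)             # gradient wrt decoder output at level 1
  de <- vector("list", L)           # gradients wrt encoder outputs e_l
  for (l in seq_len(L - 1)) {
    df <- bwd(paste0("dec_conv_", l), dd)
    de[[l]] <- bwd(paste0("skip_", l), df)
    dd <- bwd(paste0("up_", l), df) # gradient wrt decoder state at level l+1
  }
  de[[L]] <- dd                     # bottleneck: decoder state = encoder out
  for (l in seq(L, 2)) {
    dt <- bwd(paste0("enc_conv_", l), de[[l]])
    de[[l - 1]] <- cpp_add_f(de[[l - 1]], bwd(paste0("down_", l), dt))
  }
  bwd("enc_conv_1", de[[1]], need_dx = FALSE)  # input gradient is unused
  grads
}

#' Run the network on a preprocessed volume
#'
#' Inference-mode forward pass (batch statistics frozen to running values).
#' Deterministic for fixed weights.
#'
#' @param network an `rs_network`.
#' @param grid a preprocessed [voxel_grid] (z-scored intensities) whose shape
#'   is divisible by `2^(levels - 1)`.
#' @return A [prob_maps] with channels tumor, rectum, mesorectum.
#' @export
forward <- function(network, grid) {
  stopifnot(inherits(network, "rs_network"), inherits(grid, "voxel_grid"))
  dims <- dim(grid$values)
  X <- matrix(as.numeric(grid$values), ncol = 1)
  P <- net_forward(network, X, 1L, dims)$P
  prob_maps(array(P[, 1], dims), array(P[, 2], dims), array(P[, 3], dims))
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the [network_config] together with all weights and
#' batch-normalization statistics.
#'
#' @param network an `rs_network`.
#' @param path checkpoint file path (`.rds`).
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "rs_network"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return For `load_checkpoint`, the restored `rs_network`.
#' @export
load_checkpoint <- function(path) {
  network <- readRDS(path)
  if (!inherits(network, "rs_network")) stop("not a network checkpoint: ", path)
  network
}
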