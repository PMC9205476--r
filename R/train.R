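#' Training configuration
#'
#' Bundles the optimizer settings (Adam with base learning rate 0.003,
#' beta1 0.9, beta2 0.999, epsilon 1e-8), the mixed batch composition
#' (3 fully-labeled + 2 staging-only cases per batch of 5), the combined-loss
#' balance `lambda` (0.02; 0 gives the Dice-only ablation baseline),
#' validation cadence (every 100th iteration) and the preprocessing /
#' augmentation parameters.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_seg_cases labeled cases per batch.
#' @param batch_staging_only_cases staging-only cases per batch.
#' @param max_iterations total training iterations.
#' @param validate_every validation cadence in iterations (>= 1).
#' @param lambda staging-loss weight.
#' @param eps_dice Dice smoothing term.
#' @param network a [network_config].
#' @param target_mm,out_shape preprocessing geometry (see
#'   [preprocess_case()]).
#' @param threshold binarization threshold for validation/prediction.
#' @param augment logical, apply random augmentation to training cases.
#' @param augment_ranges list with `scale`, `rotation_deg`,
#'   `slice_thickness_mm` ranges (see [augment_case()]).
#' @param seed master seed; folds, batches, augmentation and weight
#'   initialization draw from named substreams of it.
#' @param verbose print progress messages.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.003, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_seg_cases = 3L,
                         batch_staging_only_cases = 2L,
                         max_iterations = 1000L, validate_every = 100L,
                         lambda = 0.02, eps_dice = 1,
                         network = network_config(),
                         target_mm = 1.0, out_shape = c(48L, 48L, 48L),
                         threshold = 0.5, augment = FALSE,
                         augment_ranges = list(scale = c(0.9, 1.1),
                                               rotation_deg = c(-10, 10),
                                               slice_thickness_mm = c(2, 4)),
                         seed = 1L, verbose = FALSE) {
  if (validate_every < 1) stop("validate_every must be >= 1")
  if (batch_seg_cases < 1) stop("need at least one labeled case per batch")
  if (lambda < 0) stop("lambda must be >= 0")
  stopifnot(inherits(network, "network_config"))
  structure(as.list(environment()), class = "train_config")
}

#' Randomly augment a case
#'
#' Applies, in physical space, a uniform scaling and an in-plane rotation
#' about the tumor center, followed by a slice-thickness conversion
#' (resampling the through-plane axis to a random thickness).  Image
#' intensities are interpolated trilinearly, labels nearest-neighbor with
#' identical geometry, and the stage label is unchanged.  Deterministic for a
#' fixed seed.
#'
#' @param case an [rs_case].
#' @param ranges list of `c(min, max)` ranges: `scale`, `rotation_deg`,
#'   `slice_thickness_mm`.
#' @param seed integer seed.
#' @return The augmented [rs_case].
#' @export
augment_case <- function(case, ranges = list(scale = c(0.9, 1.1),
                                             rotation_deg = c(-10, 10),
                                             slice_thickness_mm = c(2, 4)),
                         seed = 1L) {
  stopifnot(inherits(case, "rs_case"))
  for (nm in c("scale", "rotation_deg", "slice_thickness_mm")) {
    rg <- ranges[[nm]]
    if (is.null(rg) || length(rg) != 2L || any(!is.finite(rg)) ||
        rg[2] < rg[1] || (nm != "rotation_deg" && rg[1] <= 0))
      stop("degenerate augmentation range for ", nm)
  }
  draws <- with_seed(seed, runif(3))
  s <- ranges$scale[1] + draws[1] * diff(ranges$scale)
  ang <- (ranges$rotation_deg[1] + draws[2] * diff(ranges$rotation_deg)) *
    pi / 180
  th <- ranges$slice_thickness_mm[1] + draws[3] *
    diff(ranges$slice_thickness_mm)

  grid <- case$volume
  d <- dim(grid$values)
  ctr <- case$center_mm
  # output voxel p maps to input coordinate A p + t (inverse of the anatomy
  # transform: scale s then rotate by ang about the through-plane axis)
  R <- matrix(c(cos(-ang), sin(-ang), 0, -sin(-ang), cos(-ang), 0, 0, 0, 1),
              3, 3)
  A <- R / s
  tvec <- ctr - A %*% ctr
  grid_sp <- grid$spacing_mm
  vol <- cpp_resample(grid$values, as.integer(d), grid_sp, grid$origin_mm,
                      as.integer(d), grid_sp, grid$origin_mm, A,
                      as.numeric(tvec), "linear", min(grid$values))
  labs <- NULL
  if (has_labels(case))
    labs <- lapply(case$labels[c("tumor", "rectum", "mesorectum")],
                   function(m)
      cpp_resample(m + 0, as.integer(d), grid_sp, grid$origin_mm,
                   as.integer(d), grid_sp, grid$origin_mm, A,
                   as.numeric(tvec), "nearest", 0) > 0.5)

  # slice-thickness conversion along the third axis
  if (abs(th - grid_sp[3]) > 1e-9) {
    sp_out <- c(grid_sp[1:2], th)
    dz <- pmax(1L, as.integer(round(d[3] * grid_sp[3] / th)))
    dims_out <- c(d[1:2], dz)
    vol <- cpp_resample(vol, as.integer(d), grid_sp, grid$origin_mm,
                        as.integer(dims_out), sp_out, grid$origin_mm, diag(3),
                        rep(0, 3), "linear", min(vol))
    if (!is.null(labs))
      labs <- lapply(labs, function(m)
        cpp_resample(m + 0, as.integer(d), grid_sp, grid$origin_mm,
                     as.integer(dims_out), sp_out, grid$origin_mm, diag(3),
                     rep(0, 3), "nearest", 0) > 0.5)
    grid_sp <- sp_out
  }

  new_grid <- voxel_grid(vol, grid_sp, grid$origin_mm)
  new_labels <- if (is.null(labs)) NULL else
    seg_labels(labs$tumor, labs$rectum, labs$mesorectum)
  rs_case(new_grid, ctr, case$stage, labels = new_labels,
          case_id = case$case_id, mucinous = case$mucinous)
}

#' Mixed-batch index stream
#'
#' Emits `n_batches` batches, each naming exactly `batch_seg_cases` labeled
#' and `batch_staging_only_cases` staging-only cases (indices into `cases`),
#' sampled reproducibly.  When no staging-only cases exist, batches fall back
#' to all-labeled composition with a logged warning (and vice versa).
#'
#' @param cases list of [rs_case] objects.
#' @param cfg a [train_config].
#' @param seed integer seed.
#' @param n_batches number of batches to emit.
#' @return List of lists with integer fields `seg` and `stg`.
#' @export
make_batches <- function(cases, cfg, seed = 1L,
                         n_batches = cfg$max_iterations) {
  labeled <- which(vapply(cases, has_labels, TRUE))
  staging_only <- which(!vapply(cases, has_labels, TRUE))
  n_seg <- cfg$batch_seg_cases
  n_stg <- cfg$batch_staging_only_cases
  if (length(labeled) == 0 && length(staging_only) == 0)
    stop("no cases to batch")
  if (length(staging_only) == 0 && n_stg > 0) {
    warning("no staging-only cases: falling back to all-labeled batches")
    n_seg <- n_seg + n_stg
    n_stg <- 0L
  }
  if (length(labeled) == 0 && n_seg > 0) {
    warning("no labeled cases: falling back to all staging-only batches")
    n_stg <- n_seg + n_stg
    n_seg <- 0L
  }
  sample_n <- function(pool, k)
    if (k == 0) integer(0) else
      pool[sample.int(length(pool), k, replace = k > length(pool))]
  with_seed(substream_seed(seed, "batches"), {
    lapply(seq_len(n_batches), function(i)
      list(seg = sample_n(labeled, n_seg), stg = sample_n(staging_only,
                                                          n_stg)))
  })
}

# --- internal training machinery -------------------------------------------

case_tensor <- function(prep) {
  X <- matrix(as.numeric(prep$volume$values), ncol = 1)
  G <- NULL
  if (!is.null(prep$labels))
    G <- cbind(as.numeric(prep$labels$tumor), as.numeric(prep$labels$rectum),
               as.numeric(prep$labels$mesorectum))
  list(X = X, G = G)
}

# Combined loss and its gradient in the probability output for one batch.
# P: [nvox*nb, 3]; tensors: list per volume with $G (or NULL); stages: list
# of stage_label.  Seg term averages over labeled volumes and channels;
# staging term averages over all volumes.
batch_loss_grad <- function(P, tensors, stages, nvox, lambda, eps) {
  nb <- length(tensors)
  dP <- matrix(0, nrow(P), 3)
  labeled <- which(!vapply(tensors, function(t) is.null(t$G), TRUE))
  loss_seg <- 0
  for (v in labeled) {
    rows <- ((v - 1) * nvox + 1):(v * nvox)
    G <- tensors[[v]]$G
    for (c in 1:3) {
      p <- P[rows, c]; g <- G[, c]
      loss_seg <- loss_seg + dice_loss(p, g, eps)
      dP[rows, c] <- dP[rows, c] +
        dice_loss_grad(p, g, eps) / (3 * length(labeled))
    }
  }
  loss_seg <- if (length(labeled)) loss_seg / (3 * length(labeled)) else 0
  loss_stg <- 0
  for (v in seq_len(nb)) {
    rows <- ((v - 1) * nvox + 1):(v * nvox)
    pt <- P[rows, 1]; pr <- P[rows, 2]
    q <- pt * (1 - pr)
    i <- which.max(q)
    g <- stages[[v]]$g_staging
    loss_stg <- loss_stg + staging_loss(q[i], stages[[v]])
    # subgradient through the argmax voxel
    dP[rows[i], 1] <- dP[rows[i], 1] - lambda * g * (1 - pr[i]) / nb
    dP[rows[i], 2] <- dP[rows[i], 2] + lambda * g * pt[i] / nb
  }
  loss_stg <- loss_stg / nb
  list(loss = loss_seg + lambda * loss_stg, loss_seg = loss_seg,
       loss_stg = loss_stg, dP = dP)
}

adam_init <- function(network) {
  lapply(network$layers, function(ly) {
    st <- list()
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(ly[[f]]))
        st[[f]] <- list(m = ly[[f]] * 0, v = ly[[f]] * 0)
    st
  })
}

adam_step <- function(network, grads, state, cfg, t) {
  fields <- c(W = "dW", b = "db", gamma = "dgamma", beta = "dbeta")
  corr1 <- 1 - cfg$beta1^t
  corr2 <- 1 - cfg$beta2^t
  for (nm in names(grads)) {
    for (f in names(fields)) {
      gr <- grads[[nm]][[fields[[f]]]]
      if (is.null(gr)) next
      st <- state[[nm]][[f]]
      st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * gr
      st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * gr^2
      state[[nm]][[f]] <- st
      upd <- cfg$learning_rate * (st$m / corr1) /
        (sqrt(st$v / corr2) + cfg$epsilon)
      network$layers[[nm]][[f]] <- network$layers[[nm]][[f]] - upd
    }
  }
  list(network = network, state = state)
}

# Validation metrics: mean over labeled cases and channels of the binarized
# DSC, plus staging sensitivity/specificity over all cases.
validate_network <- function(network, val_tensors, val_stages, dims,
                             threshold) {
  nvox <- prod(dims)
  dscs <- c()
  preds <- vector("list", length(val_tensors))
  for (v in seq_along(val_tensors)) {
    P <- net_forward(network, val_tensors[[v]]$X, 1L, dims)$P
    pm <- prob_maps(array(P[, 1], dims), array(P[, 2], dims),
                    array(P[, 3], dims))
    masks <- binarize(pm, threshold)
    preds[[v]] <- classify_stage(masks)
    G <- val_tensors[[v]]$G
    if (!is.null(G))
      dscs <- c(dscs, dsc(masks$tumor, G[, 1] > 0.5),
                dsc(masks$rectum, G[, 2] > 0.5),
                dsc(masks$mesorectum, G[, 3] > 0.5))
  }
  conf <- staging_confusion(preds, val_stages)
  sens <- sensitivity(conf); spec <- specificity(conf)
  mean_dsc <- if (length(dscs)) mean(dscs) else 0
  if (is.na(sens)) sens <- 0
  if (is.na(spec)) spec <- 0
  list(mean_dsc = mean_dsc, sensitivity = sens, specificity = spec,
       score = mean_dsc + sens + spec)
}

#' Train the segmentation network
#'
#' Minimizes the combined loss (mean per-channel Dice over labeled cases +
#' `lambda` x staging loss over all cases) with Adam on mixed batches.  At
#' every `validate_every`-th iteration the model is scored on the validation
#' cases by the sum of the mean Dice score, staging sensitivity and staging
#' specificity, and the best-scoring checkpoint is returned (ties keep the
#' earlier iteration).
#'
#' @param train_cases,val_cases lists of [rs_case] objects; validation cases
#'   should include labeled cases and both stages for the selection score to
#'   be informative.
#' @param cfg a [train_config].
#' @return A list with `network` (the selected checkpoint), `final_network`,
#'   `history` (per-iteration loss terms), `validation` (per-checkpoint
#'   metrics), `selected_iteration`, and `config`.
#' @export
train_network <- function(train_cases, val_cases, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(train_cases) == 0 || length(val_cases) == 0)
    stop("need nonempty training and validation case lists")
  dims <- as.integer(cfg$out_shape)
  nvox <- prod(dims)

  prep_tensor <- function(case)
    case_tensor(preprocess_case(case, cfg$target_mm, cfg$out_shape))
  train_tensors <- if (!cfg$augment) lapply(train_cases, prep_tensor) else NULL
  val_tensors <- lapply(val_cases, prep_tensor)
  val_stages <- lapply(val_cases, function(c) c$stage)

  network <- build_network(cfg$network, seed = cfg$seed)
  state <- adam_init(network)
  batches <- make_batches(train_cases, cfg, seed = cfg$seed)
  aug_seeds <- with_seed(substream_seed(cfg$seed, "augment"),
                         sample.int(2^30, cfg$max_iterations))

  nb <- length(batches[[1]]$seg) + length(batches[[1]]$stg)
  history <- data.frame(iteration = integer(), loss = numeric(),
                        loss_seg = numeric(), loss_stg = numeric())
  valrec <- data.frame(iteration = integer(), mean_dsc = numeric(),
                       sensitivity = numeric(), specificity = numeric(),
                       score = numeric())
  best <- list(score = -Inf, network = network, iteration = 0L)

  for (it in seq_len(cfg$max_iterations)) {
    b <- batches[[it]]
    idx <- c(b$seg, b$stg)
    tensors <- lapply(seq_along(idx), function(j) {
      case <- train_cases[[idx[j]]]
      if (cfg$augment) {
        case <- augment_case(case, cfg$augment_ranges,
                             seed = aug_seeds[it] + j)
        prep_tensor(case)
      } else train_tensors[[idx[j]]]
    })
    # staging-only tensors drop their labels' role in the seg term
    for (j in seq_along(idx))
      if (j > length(b$seg)) tensors[[j]]$G <- NULL
    stages <- lapply(train_cases[idx], function(c) c$stage)
    X <- do.call(rbind, lapply(tensors, function(t) t$X))

    fw <- net_forward(network, X, length(idx), dims, train = TRUE,
                      keep_cache = TRUE)
    network <- fw$network
    lg <- batch_loss_grad(fw$P, tensors, stages, nvox, cfg$lambda,
                          cfg$eps_dice)
    if (!is.finite(lg$loss))
      stop("training diverged: non-finite loss at iteration ", it)
    grads <- net_backward(network, fw$caches, lg$dP, length(idx))
    upd <- adam_step(network, grads, state, cfg, it)
    network <- upd$network
    state <- upd$state
    history[nrow(history) + 1L, ] <- list(it, lg$loss, lg$loss_seg,
                                          lg$loss_stg)

    if (it %% cfg$validate_every == 0 || it == cfg$max_iterations) {
      vm <- validate_network(network, val_tensors, val_stages, dims,
                             cfg$threshold)
      valrec[nrow(valrec) + 1L, ] <- list(it, vm$mean_dsc, vm$sensitivity,
                                          vm$specificity, vm$score)
      if (vm$score > best$score) {
        best <- list(score = vm$score, network = network, iteration = it)
      }
      if (cfg$verbose)
        message(sprintf(
          "iter %d: loss %.4f (seg %.4f, %.3g*stg %.4f); val dsc %.3f sens %.3f spec %.3f",
          it, lg$loss, lg$loss_seg, cfg$lambda, lg$loss_stg, vm$mean_dsc,
          vm$sensitivity, vm$specificity))
    }
  }
  list(network = best$network, final_network = network, history = history,
       validation = valrec, selected_iteration = best$iteration, config = cfg)
}

#' Segment and stage a single case
#'
#' The semi-automated inference path: preprocess around the user-supplied
#' tumor center, run the network, binarize at `threshold`, and apply the
#' rule-based T2/T3 classifier.  Masks are returned on the preprocessed grid
#' together with its geometry for mapping back.
#'
#' @param network a trained `rs_network`.
#' @param case an [rs_case] (labels, if present, are preprocessed alongside
#'   for evaluation convenience).
#' @param target_mm,out_shape preprocessing geometry.
#' @param threshold binarization threshold.
#' @return List with `masks` ([seg_labels]), `stage` (`stage_prediction`),
#'   `prob` ([prob_maps]), `truth_labels` (preprocessed [seg_labels] or
#'   `NULL`), and `geometry`.
#' @export
predict_case <- function(network, case, target_mm = 1.0,
                         out_shape = c(48L, 48L, 48L), threshold = 0.5) {
  prep <- preprocess_case(case, target_mm, out_shape)
  pm <- forward(network, prep$volume)
  masks <- binarize(pm, threshold)
  list(masks = masks, stage = classify_stage(masks), prob = pm,
       truth_labels = prep$labels,
       geometry = list(target_mm = target_mm, out_shape = out_shape,
                       origin_mm = prep$origin_mm))
}
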