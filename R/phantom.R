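#' Specification of a synthetic rectal-anatomy phantom
#'
#' The phantom is a nested tubular geometry along one grid axis: a fluid
#' lumen inside the rectal wall (muscularis propria), surrounded by
#' high-signal mesorectal fat out to the mesorectal fascia.  The tumor is an
#' angular-sector thickening of the wall with a smooth super-ellipsoidal cap;
#' a positive `invasion_depth_mm` pushes it radially beyond the outer wall
#' boundary into the mesorectum (T3 geometry), a non-positive value keeps it
#' confined within the wall (T2 geometry).  The default synthesis grid is
#' anisotropic (0.5 x 0.5 mm in-plane, 3.5 mm effective slice pitch,
#' mimicking a 3 mm slice with a 0.5 mm gap) so that isotropic resampling in
#' preprocessing is genuinely exercised.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param spacing_mm numeric length-3 voxel size (mm).
#' @param lumen_radius_mm radius of the lumen.
#' @param wall_thickness_mm thickness of the muscularis propria.
#' @param mesorectum_radius_mm outer radius of the mesorectal envelope; must
#'   exceed `lumen_radius_mm + wall_thickness_mm`.
#' @param tube_axis grid axis (1-3) the rectal tube runs along.
#' @param curvature_mm amplitude of a single sinusoidal in-plane displacement
#'   of the tube axis (0 = straight).
#' @param tumor_angular_extent_deg angular width of the tumor sector, in
#'   (0, 360].
#' @param tumor_length_mm extent of the tumor along the tube axis.
#' @param tumor_angle_deg angular position of the sector center.
#' @param invasion_depth_mm radial tumor extent beyond the outer wall
#'   boundary; <= 0 gives T2 geometry (tumor inside the rectum), > 0 a T3
#'   breach into the mesorectum.
#' @param mucinous if `TRUE`, the tumor takes a high T2 signal close to fat
#'   (mucin-rich histology) instead of the intermediate signal.
#' @param intensity_means named list of mean signals per tissue:
#'   `background`, `lumen`, `wall`, `mesorectum`, `tumor`, `mucinous`.
#' @param noise_sigma standard deviation of the complex Gaussian noise whose
#'   magnitude (Rician) corrupts the signal; 0 disables noise.
#' @param seed integer RNG seed; generation is bit-reproducible per seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 20L),
                         spacing_mm = c(0.5, 0.5, 3.5),
                         lumen_radius_mm = 4,
                         wall_thickness_mm = 3,
                         mesorectum_radius_mm = 16,
                         tube_axis = 3L,
                         curvature_mm = 2,
                         tumor_angular_extent_deg = 120,
                         tumor_length_mm = 18,
                         tumor_angle_deg = 0,
                         invasion_depth_mm = 3,
                         mucinous = FALSE,
                         intensity_means = list(background = 20, lumen = 30,
                                                wall = 60, mesorectum = 200,
                                                tumor = 110, mucinous = 220),
                         noise_sigma = 8,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 4L))
      stop("grid_shape must be 3 integers >= 4")
    if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
    if (!(lumen_radius_mm > 0 && wall_thickness_mm > 0))
      stop("lumen radius and wall thickness must be positive")
    if (lumen_radius_mm + wall_thickness_mm >= mesorectum_radius_mm)
      stop("mesorectum_radius_mm must exceed lumen_radius_mm + wall_thickness_mm")
    if (!(tube_axis %in% 1:3)) stop("tube_axis must be 1, 2 or 3")
    if (!(tumor_angular_extent_deg > 0 && tumor_angular_extent_deg <= 360))
      stop("tumor_angular_extent_deg must lie in (0, 360]")
    if (tumor_length_mm <= 0) stop("tumor_length_mm must be positive")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    need <- c("background", "lumen", "wall", "mesorectum", "tumor", "mucinous")
    if (!all(need %in% names(intensity_means)))
      stop("intensity_means must name: ", paste(need, collapse = ", "))
  })
  invisible(spec)
}

#' Generate one synthetic phantom case
#'
#' Builds the masks and the noisy MR-like volume for a [phantom_spec].  The
#' stage label is always derived from the generated geometry (any tumor voxel
#' outside the rectum mask implies `GE_T3`), never stored independently, so
#' labels and stage cannot drift apart.  The returned tumor center is the
#' centroid of the tumor mask, playing the role of the user-clicked center.
#'
#' @param spec a [phantom_spec].
#' @param case_id identifier for the generated case.
#' @param keep_labels attach the ground-truth [seg_labels] (set `FALSE` for
#'   staging-only cases).
#' @return An [rs_case].
#' @export
generate_phantom <- function(spec, case_id = "phantom", keep_labels = TRUE) {
  validate_phantom_spec(spec)
  d <- as.integer(spec$grid_shape)
  sp <- spec$spacing_mm
  perm <- switch(spec$tube_axis, `1` = c(3L, 2L, 1L), `2` = c(1L, 3L, 2L),
                 `3` = c(1L, 2L, 3L))
  dz <- d[perm]; spz <- sp[perm]          # tube along third axis of permuted grid

  x <- (seq_len(dz[1]) - 1) * spz[1]
  y <- (seq_len(dz[2]) - 1) * spz[2]
  z <- (seq_len(dz[3]) - 1) * spz[3]
  Lz <- max(z) + spz[3]
  cx0 <- mean(range(x)); cy0 <- mean(range(y))
  cx <- cx0 + spec$curvature_mm * sin(2 * pi * z / Lz)

  # radial distance and angle about the (possibly curved) tube axis
  r <- array(0, dim = dz); theta <- array(0, dim = dz)
  for (k in seq_len(dz[3])) {
    dxk <- outer(x - cx[k], rep(1, dz[2]))
    dyk <- outer(rep(1, dz[1]), y - cy0)
    r[, , k] <- sqrt(dxk^2 + dyk^2)
    theta[, , k] <- atan2(dyk, dxk)
  }

  r_out <- spec$lumen_radius_mm + spec$wall_thickness_mm
  lumen <- r < spec$lumen_radius_mm
  rectum <- r <= r_out                      # everything within the outer wall
  meso <- (r > r_out) & (r <= spec$mesorectum_radius_mm)

  # tumor: angular sector of the wall, super-ellipsoidal cap along z / theta,
  # extending radially to r_out + invasion (clamped inside the mesorectum)
  zc <- mean(range(z))
  half_len <- spec$tumor_length_mm / 2
  half_ang <- spec$tumor_angular_extent_deg / 2 * pi / 180
  ang0 <- spec$tumor_angle_deg * pi / 180
  dang <- atan2(sin(theta - ang0), cos(theta - ang0))   # wrapped difference
  uz <- array(rep((z - zc) / half_len, each = dz[1] * dz[2]), dim = dz)
  ut <- dang / half_ang
  cap <- pmax(0, (1 - pmin(1, uz^2)^2) * (1 - pmin(1, ut^2)^2))
  depth <- spec$invasion_depth_mm
  outer_r <- if (depth > 0) r_out + depth * cap else
    array(max(r_out + depth, spec$lumen_radius_mm + 0.5), dim = dz)
  outer_r <- pmin(outer_r, spec$mesorectum_radius_mm - 0.25)
  # mural tumors also protrude into the lumen; grow inward by up to 2.5 mm
  inner_r <- pmax(spec$lumen_radius_mm - 2.5 * cap, 0)
  tumor <- (abs(uz) <= 1) & (abs(ut) <= 1) & (r >= inner_r) &
    (r <= outer_r) & (cap > 0)

  tissue_mean <- spec$intensity_means
  signal <- array(tissue_mean$background, dim = dz)
  signal[lumen] <- tissue_mean$lumen
  signal[rectum & !lumen] <- tissue_mean$wall
  signal[meso] <- tissue_mean$mesorectum
  signal[tumor] <- if (spec$mucinous) tissue_mean$mucinous else tissue_mean$tumor

  if (spec$noise_sigma > 0) {
    signal <- with_seed(spec$seed, {
      n1 <- array(rnorm(length(signal), 0, spec$noise_sigma), dim = dz)
      n2 <- array(rnorm(length(signal), 0, spec$noise_sigma), dim = dz)
      sqrt((signal + n1)^2 + n2^2)        # Rician magnitude noise
    })
  }

  unperm <- order(perm)
  signal <- aperm(signal, unperm)
  tumor <- aperm(tumor, unperm)
  rectum <- aperm(rectum, unperm)
  meso <- aperm(meso, unperm)

  vol <- voxel_grid(signal, sp)
  labels <- seg_labels(tumor, rectum, meso)
  stage <- if (any(tumor & !rectum)) stage_label("GE_T3") else
    stage_label("LE_T2")

  idx <- which(tumor, arr.ind = TRUE)
  center <- vol$origin_mm + (colMeans(idx) - 1) * sp

  rs_case(vol, center, stage, labels = if (keep_labels) labels else NULL,
          case_id = case_id, mucinous = spec$mucinous)
}

#' Default per-case parameter ranges for cohort generation
#'
#' Each entry is a `c(min, max)` range sampled uniformly per case;
#' `invasion_t2` must be non-positive and `invasion_t3` positive.
#'
#' @return Named list of ranges.
#' @export
default_spec_ranges <- function() {
  list(lumen_radius_mm = c(3, 5),
       wall_thickness_mm = c(2.5, 3.5),
       mesorectum_radius_mm = c(14, 18),
       curvature_mm = c(0, 3),
       tumor_angular_extent_deg = c(90, 180),
       tumor_length_mm = c(14, 22),
       tumor_angle_deg = c(0, 360),
       invasion_t2 = c(-2, -0.5),
       invasion_t3 = c(2, 4),
       noise_sigma = c(8, 8))
}

#' Generate a cohort of phantom cases
#'
#' Emulates the two-group training cohort: a fraction of cases carry full
#' segmentation labels, the rest carry only the binary T stage.  Exactly
#' `round(n * seg_labeled_fraction)` cases are fully labeled and exactly
#' `round(n * t3_fraction)` cases have T3 geometry; assignments are shuffled
#' reproducibly.  Per-case anatomy parameters are drawn uniformly from
#' `spec_ranges`.
#'
#' @param n number of cases (>= 1).
#' @param t3_fraction fraction of cases with mesorectal invasion.
#' @param seg_labeled_fraction fraction of cases carrying segmentation masks.
#' @param mucinous_fraction fraction of cases with mucinous signal.
#' @param spec_ranges named list of `c(min, max)` ranges, see
#'   [default_spec_ranges()].
#' @param seed master seed; all per-case draws derive from it.
#' @param grid_shape,spacing_mm synthesis grid, as in [phantom_spec()].
#' @return A list of [rs_case] objects.
#' @export
generate_cohort <- function(n, t3_fraction = 119 / 201,
                            seg_labeled_fraction = 135 / 201,
                            mucinous_fraction = 6 / 201,
                            spec_ranges = default_spec_ranges(),
                            seed = 1L,
                            grid_shape = c(96L, 96L, 20L),
                            spacing_mm = c(0.5, 0.5, 3.5)) {
  if (n < 1) stop("n must be >= 1")
  for (f in c(t3_fraction, seg_labeled_fraction, mucinous_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  defaults <- default_spec_ranges()
  for (nm in names(defaults))
    if (is.null(spec_ranges[[nm]])) spec_ranges[[nm]] <- defaults[[nm]]
  for (nm in names(spec_ranges)) {
    rg <- spec_ranges[[nm]]
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[2] < rg[1])
      stop("invalid (empty) range for ", nm)
  }
  if (any(spec_ranges$invasion_t3 <= 0))
    stop("invasion_t3 range must be strictly positive")
  if (any(spec_ranges$invasion_t2 > 0))
    stop("invasion_t2 range must be non-positive")

  n_t3 <- round(n * t3_fraction)
  n_lab <- round(n * seg_labeled_fraction)
  n_muc <- round(n * mucinous_fraction)
  with_seed(substream_seed(seed, "cohort"), {
    is_t3 <- sample(rep(c(TRUE, FALSE), c(n_t3, n - n_t3)))
    is_lab <- sample(rep(c(TRUE, FALSE), c(n_lab, n - n_lab)))
    is_muc <- sample(rep(c(TRUE, FALSE), c(n_muc, n - n_muc)))
    draws <- matrix(runif(n * length(spec_ranges)), nrow = n)
    colnames(draws) <- names(spec_ranges)
    lapply(seq_len(n), function(i) {
      val <- function(nm) {
        rg <- spec_ranges[[nm]]
        rg[1] + draws[i, nm] * (rg[2] - rg[1])
      }
      # keep the nesting invariant feasible for any draw combination
      meso_r <- max(val("mesorectum_radius_mm"),
                    val("lumen_radius_mm") + val("wall_thickness_mm") + 4)
      spec <- phantom_spec(
        grid_shape = grid_shape, spacing_mm = spacing_mm,
        lumen_radius_mm = val("lumen_radius_mm"),
        wall_thickness_mm = val("wall_thickness_mm"),
        mesorectum_radius_mm = meso_r,
        curvature_mm = val("curvature_mm"),
        tumor_angular_extent_deg = val("tumor_angular_extent_deg"),
        tumor_length_mm = val("tumor_length_mm"),
        tumor_angle_deg = val("tumor_angle_deg"),
        invasion_depth_mm = if (is_t3[i]) val("invasion_t3") else
          val("invasion_t2"),
        mucinous = is_muc[i],
        noise_sigma = val("noise_sigma"),
        seed = substream_seed(seed, paste0("phantom", i)))
      generate_phantom(spec, case_id = sprintf("case%03d", i),
                       keep_labels = is_lab[i])
    })
  })
}

#' Cohort manifest table
#'
#' @param cases list of [rs_case] objects.
#' @return A data.frame with case_id, stage, has_labels, center coordinates
#'   and mucinous flag.
#' @export
cohort_manifest <- function(cases) {
  data.frame(
    case_id = vapply(cases, function(c) c$case_id, ""),
    stage = vapply(cases, function(c) c$stage$category, ""),
    has_labels = vapply(cases, has_labels, TRUE),
    center_x_mm = vapply(cases, function(c) c$center_mm[1], 0),
    center_y_mm = vapply(cases, function(c) c$center_mm[2], 0),
    center_z_mm = vapply(cases, function(c) c$center_mm[3], 0),
    mucinous = vapply(cases, function(c) c$mucinous, TRUE))
}

#' Write a cohort to disk
#'
#' One volume NIfTI per case, a 4-channel label NIfTI per labeled case, and a
#' manifest CSV.
#'
#' @param cases list of [rs_case] objects.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (case in cases) {
    write_volume(case$volume, file.path(dir, paste0(case$case_id, ".nii.gz")))
    if (has_labels(case))
      write_labels(case$labels, case$volume,
                   file.path(dir, paste0(case$case_id, "_labels.nii.gz")))
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(cohort_manifest(cases), mp, row.names = FALSE)
  invisible(mp)
}
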