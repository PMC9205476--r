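#' 3D intensity volume with physical geometry
#'
#' A `voxel_grid` bundles a 3D scalar array with its per-axis voxel spacing
#' (mm) and the physical coordinate of the first voxel's center (mm).  All
#' geometry in the package uses physical millimeter coordinates, 0-based voxel
#' indices and a voxel-center convention: voxel `(i, j, k)` (0-based) sits at
#' `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param values 3D numeric array of intensities.
#' @param spacing_mm positive numeric length-3, voxel size per axis in mm.
#' @param origin_mm numeric length-3, physical coordinate of the first voxel.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("voxel_grid values must be a 3D array, got ",
         length(dim(values)), " dimensions")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite numbers")
  if (any(dim(values) < 1L)) stop("grid must have at least one voxel per axis")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s @ %s mm, origin (%s)>\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

grid_dims <- function(grid) dim(grid$values)

# Physical coordinate bounds of the voxel lattice (voxel centers).
grid_extent <- function(grid) {
  d <- grid_dims(grid)
  rbind(lo = grid$origin_mm, hi = grid$origin_mm + (d - 1) * grid$spacing_mm)
}

#' Binary segmentation masks for tumor, rectum and mesorectum
#'
#' Three binary masks on a shared grid.  The rectum mask covers everything
#' within the outer boundary of the muscularis propria (lumen included); the
#' mesorectum is the surrounding fat envelope; the tumor mask may overlap the
#' rectum and, for T3 disease, the mesorectum.  Masks are stored as logical
#' arrays.
#'
#' @param tumor,rectum,mesorectum logical/0-1 3D arrays of a common shape.
#' @return An object of class `seg_labels`.
#' @export
seg_labels <- function(tumor, rectum, mesorectum) {
  masks <- list(tumor = tumor, rectum = rectum, mesorectum = mesorectum)
  masks <- lapply(masks, function(m) {
    if (is.null(dim(m)) || length(dim(m)) != 3L)
      stop("each mask must be a 3D array")
    if (!is.logical(m)) {
      if (any(!(m %in% c(0, 1)))) stop("mask values must be 0/1")
      m <- array(m > 0.5, dim = dim(m))
    }
    m
  })
  d <- dim(masks$tumor)
  if (!identical(d, dim(masks$rectum)) || !identical(d, dim(masks$mesorectum)))
    stop("all three masks must share the same shape")
  structure(masks, class = "seg_labels")
}

#' @export
print.seg_labels <- function(x, ...) {
  cat(sprintf("<seg_labels %s; voxels tumor=%d rectum=%d mesorectum=%d>\n",
              paste(dim(x$tumor), collapse = "x"), sum(x$tumor),
              sum(x$rectum), sum(x$mesorectum)))
  invisible(x)
}

#' Per-voxel probability maps for the three structures
#'
#' Channel order is fixed throughout the package: tumor, rectum, mesorectum.
#'
#' @param tumor,rectum,mesorectum numeric 3D arrays with values in \[0, 1\].
#' @return An object of class `prob_maps`.
#' @export
prob_maps <- function(tumor, rectum, mesorectum) {
  maps <- list(tumor = tumor, rectum = rectum, mesorectum = mesorectum)
  d <- dim(maps$tumor)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (is.null(dim(m)) || length(dim(m)) != 3L)
      stop("each probability map must be a 3D array")
    if (!identical(dim(m), d)) stop("probability maps must share one shape")
    if (any(m < -1e-9 | m > 1 + 1e-9)) stop(nm, " probabilities outside [0, 1]")
  }
  structure(maps, class = "prob_maps")
}

#' Ground-truth T-stage label
#'
#' The binary stage distinguishes tumors confined within the muscularis
#' propria (`"LE_T2"`) from those invading the mesorectum (`"GE_T3"`).  The
#' staging loss uses the signed encoding `g_staging`: +1 for `GE_T3`, -1 for
#' `LE_T2`.
#'
#' @param category `"LE_T2"` or `"GE_T3"` (alternatively pass `g_staging`).
#' @param g_staging optional signed encoding, +1 or -1.
#' @return An object of class `stage_label` with fields `category`,
#'   `g_staging`.
#' @export
stage_label <- function(category = NULL, g_staging = NULL) {
  if (is.null(category)) {
    if (is.null(g_staging) || !(g_staging %in% c(-1, 1)))
      stop("g_staging must be -1 or +1")
    category <- if (g_staging > 0) "GE_T3" else "LE_T2"
  }
  if (!(category %in% c("LE_T2", "GE_T3")))
    stop("stage category must be 'LE_T2' or 'GE_T3'")
  g <- if (category == "GE_T3") 1L else -1L
  if (!is.null(g_staging) && g_staging != g)
    stop("g_staging inconsistent with category")
  structure(list(category = category, g_staging = g), class = "stage_label")
}

#' @export
print.stage_label <- function(x, ...) {
  cat(sprintf("<stage %s (g=%+d)>\n", x$category, x$g_staging))
  invisible(x)
}

#' A single subject: volume, tumor center, stage, optional masks
#'
#' Fully-annotated cases carry voxelwise `seg_labels`; staging-only cases
#' carry just the binary T stage (the two-group design of the training
#' cohort).  Every case carries a stage and a user-style tumor-center
#' coordinate in physical mm.
#'
#' @param volume a [voxel_grid].
#' @param center_mm numeric length-3 tumor center in physical mm.
#' @param stage a [stage_label] (or its category string).
#' @param labels a [seg_labels] on the same grid, or `NULL`.
#' @param case_id character identifier.
#' @param mucinous logical, high-signal mucinous intensity profile.
#' @return An object of class `rs_case`.
#' @export
rs_case <- function(volume, center_mm, stage, labels = NULL,
                    case_id = "case", mucinous = FALSE) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (is.character(stage)) stage <- stage_label(stage)
  stopifnot(inherits(stage, "stage_label"))
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "seg_labels"))
    if (!identical(dim(labels$tumor), dim(volume$values)))
      stop("labels must share the volume's grid shape")
  }
  ext <- grid_extent(volume)
  if (any(center_mm < ext["lo", ] - volume$spacing_mm / 2) ||
      any(center_mm > ext["hi", ] + volume$spacing_mm / 2))
    stop("center_mm lies outside the volume's physical extent")
  structure(list(case_id = as.character(case_id), volume = volume,
                 center_mm = as.numeric(center_mm), stage = stage,
                 labels = labels, mucinous = isTRUE(mucinous)),
            class = "rs_case")
}

#' @export
print.rs_case <- function(x, ...) {
  cat(sprintf("<case %s: %s, %s, labels %s%s>\n", x$case_id,
              paste(dim(x$volume$values), collapse = "x"), x$stage$category,
              if (is.null(x$labels)) "absent" else "present",
              if (x$mucinous) ", mucinous" else ""))
  invisible(x)
}

has_labels <- function(case) !is.null(case$labels)
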