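#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` / `.nii.gz` file containing a 3D image.
#' @return A [voxel_grid].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  nifti_to_grid(img)
}

nifti_to_grid <- function(img) {
  d <- dim(img)
  spacing <- abs(RNifti::pixdim(img))[seq_len(3)]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  voxel_grid(array(as.numeric(img), dim = d), spacing, origin)
}

grid_to_nifti <- function(grid, extra_dim = NULL) {
  vals <- grid$values
  if (!is.null(extra_dim)) dim(vals) <- extra_dim
  img <- RNifti::asNifti(vals)
  pd <- grid$spacing_mm
  if (!is.null(extra_dim) || length(dim(vals)) == 4L) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd                # before the xforms: `pixdim<-`
  aff <- diag(4)                           # rescales any existing xform
  aff[1:3, 1:3] <- diag(grid$spacing_mm)
  aff[1:3, 4] <- grid$origin_mm
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img
}

#' Write a 3D volume to a NIfTI file
#'
#' The voxel spacing and origin are stored in the NIfTI s/q-form so that a
#' read/write round trip preserves geometry.
#'
#' @param grid a [voxel_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  RNifti::writeNifti(grid_to_nifti(grid), path)
  invisible(path)
}

#' Read/write segmentation labels
#'
#' Labels are stored either as one 4D NIfTI file with 3 channels in the fixed
#' order (tumor, rectum, mesorectum), or as three single-channel files with
#' suffixes `_tumor`, `_rectum`, `_mesorectum`; both dialects are read.
#'
#' @param path for reading: the 4D file, or any one of the three
#'   single-channel files.
#' @return A list with the [seg_labels] and the grid geometry (`spacing_mm`,
#'   `origin_mm`).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("cannot read labels: file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) == 4L) {
    if (dim(img)[4] != 3L) stop("4D label file must have 3 channels")
    arr <- array(as.numeric(img), dim = dim(img))
    masks <- lapply(1:3, function(c) arr[, , , c] > 0.5)
    spacing <- abs(RNifti::pixdim(img))[seq_len(3)]
    xf <- RNifti::xform(img)
    return(list(labels = seg_labels(masks[[1]], masks[[2]], masks[[3]]),
                spacing_mm = spacing, origin_mm = as.numeric(xf[1:3, 4])))
  }
  base <- sub("_(tumor|rectum|mesorectum)(\\.nii(\\.gz)?)$", "\\2", path)
  parts <- lapply(c("tumor", "rectum", "mesorectum"), function(s) {
    p <- sub("(\\.nii(\\.gz)?)$", paste0("_", s, "\\1"),
             sub("_(tumor|rectum|mesorectum)", "", path))
    if (!file.exists(p)) stop("missing label channel file: ", p)
    read_volume(p)
  })
  list(labels = seg_labels(parts[[1]]$values > 0.5, parts[[2]]$values > 0.5,
                           parts[[3]]$values > 0.5),
       spacing_mm = parts[[1]]$spacing_mm, origin_mm = parts[[1]]$origin_mm)
}

#' @rdname read_labels
#' @param labels a [seg_labels].
#' @param grid the [voxel_grid] carrying the geometry of the masks.
#' @export
write_labels <- function(labels, grid, path) {
  stopifnot(inherits(labels, "seg_labels"))
  d <- dim(labels$tumor)
  arr <- array(0, dim = c(d, 3L))
  arr[, , , 1] <- labels$tumor
  arr[, , , 2] <- labels$rectum
  arr[, , , 3] <- labels$mesorectum
  RNifti::writeNifti(grid_to_nifti(list(values = arr,
                                        spacing_mm = grid$spacing_mm,
                                        origin_mm = grid$origin_mm)), path)
  invisible(path)
}

#' Resample a volume to isotropic voxels
#'
#' Rescales a grid to a cubic voxel of side `target_mm`, preserving the
#' physical extent within one voxel.  Intensities are interpolated
#' trilinearly; binary masks must use `method = "nearest"`.
#'
#' @param grid a [voxel_grid].
#' @param target_mm positive isotropic voxel size, default 0.5 mm.
#' @param method `"linear"` (intensities) or `"nearest"` (masks).
#' @param pad value used outside the input grid; defaults to the input
#'   minimum for linear and 0 for nearest.
#' @return A resampled [voxel_grid].
#' @export
resample_isotropic <- function(grid, target_mm = 0.5,
                               method = c("linear", "nearest"), pad = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), target_mm > 0)
  method <- match.arg(method)
  d <- grid_dims(grid)
  if (any(d < 1L)) stop("degenerate grid")
  if (is.null(pad)) pad <- if (method == "linear") min(grid$values) else 0
  dims_out <- pmax(1L, as.integer(round(d * grid$spacing_mm / target_mm)))
  vals <- cpp_resample(grid$values, as.integer(d), grid$spacing_mm,
                       grid$origin_mm, dims_out, rep(target_mm, 3),
                       grid$origin_mm, diag(3), rep(0, 3), method, pad)
  voxel_grid(vals, rep(target_mm, 3), grid$origin_mm)
}

#' Crop a fixed-shape block around a physical center
#'
#' Extracts exactly `out_shape` voxels such that the input voxel nearest
#' `center_mm` lands on the output's central voxel; regions outside the input
#' are padded.
#'
#' @param grid a [voxel_grid].
#' @param center_mm physical center coordinate (mm); must lie inside the
#'   input's physical extent.
#' @param out_shape integer length-3 output voxel counts.
#' @param pad pad value; defaults to the input minimum (use 0 for masks).
#' @return A [voxel_grid] of shape `out_shape`.
#' @export
crop_around <- function(grid, center_mm, out_shape, pad = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 3L || any(out_shape < 1L))
    stop("out_shape must be 3 positive integers")
  ext <- grid_extent(grid)
  if (any(center_mm < ext["lo", ] - grid$spacing_mm / 2) ||
      any(center_mm > ext["hi", ] + grid$spacing_mm / 2))
    stop("center_mm lies outside the input's physical extent")
  if (is.null(pad)) pad <- min(grid$values)
  d <- grid_dims(grid)
  ic <- pmin(pmax(as.integer(round((center_mm - grid$origin_mm) /
                                     grid$spacing_mm)), 0L), d - 1L)
  start <- ic - out_shape %/% 2L          # 0-based start in input
  out <- array(pad, dim = out_shape)
  in_lo <- pmax(start, 0L)
  in_hi <- pmin(start + out_shape - 1L, d - 1L)
  if (all(in_lo <= in_hi)) {
    o_lo <- in_lo - start
    o_hi <- in_hi - start
    out[(o_lo[1] + 1):(o_hi[1] + 1), (o_lo[2] + 1):(o_hi[2] + 1),
        (o_lo[3] + 1):(o_hi[3] + 1)] <-
      grid$values[(in_lo[1] + 1):(in_hi[1] + 1), (in_lo[2] + 1):(in_hi[2] + 1),
                  (in_lo[3] + 1):(in_hi[3] + 1)]
  }
  voxel_grid(out, grid$spacing_mm, grid$origin_mm + start * grid$spacing_mm)
}

#' Z-score intensity normalization
#'
#' Maps a volume to zero mean and unit standard deviation; a constant volume
#' maps to all zeros.
#'
#' @param grid a [voxel_grid].
#' @return A normalized [voxel_grid].
#' @export
normalize_intensity <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  v <- grid$values
  s <- sd(v)
  grid$values <- if (!is.finite(s) || s == 0) array(0, dim = dim(v))
                 else (v - mean(v)) / s
  grid
}

#' Preprocess a case for the network
#'
#' The standard preprocessing chain: resample to isotropic voxels, crop a
#' fixed block around the user-supplied tumor center, and z-score normalize
#' the intensities.  Labels, when present, follow the identical geometry with
#' nearest-neighbor interpolation and zero padding, and are not normalized.
#' Defaults follow the full-scale protocol (0.5 mm isotropic, 256x256x128
#' voxels); desk-scale work uses smaller crops.
#'
#' @param case an [rs_case].
#' @param target_mm isotropic voxel size in mm.
#' @param out_shape output voxel counts.
#' @return A list with `volume` (normalized [voxel_grid]), `labels`
#'   ([seg_labels] or `NULL`), and the crop geometry.
#' @export
preprocess_case <- function(case, target_mm = 0.5,
                            out_shape = c(256L, 256L, 128L)) {
  stopifnot(inherits(case, "rs_case"))
  iso <- resample_isotropic(case$volume, target_mm, "linear")
  vol <- crop_around(iso, case$center_mm, out_shape)
  vol <- normalize_intensity(vol)
  labs <- NULL
  if (has_labels(case)) {
    masks <- lapply(case$labels[c("tumor", "rectum", "mesorectum")],
                    function(m) {
      g <- voxel_grid(m + 0, case$volume$spacing_mm, case$volume$origin_mm)
      gi <- resample_isotropic(g, target_mm, "nearest", pad = 0)
      crop_around(gi, case$center_mm, out_shape, pad = 0)$values > 0.5
    })
    labs <- seg_labels(masks$tumor, masks$rectum, masks$mesorectum)
  }
  list(volume = vol, labels = labs, target_mm = target_mm,
       out_shape = out_shape, origin_mm = vol$origin_mm)
}
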