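#' Binarize probability maps
#'
#' Each channel is thresholded independently; a voxel becomes foreground only
#' when its probability strictly exceeds the threshold (a probability exactly
#' at the threshold maps to background).
#'
#' @param p_maps a [prob_maps].
#' @param threshold scalar in (0, 1), default 0.5.
#' @return A [seg_labels].
#' @export
binarize <- function(p_maps, threshold = 0.5) {
  stopifnot(inherits(p_maps, "prob_maps"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must lie in (0, 1)")
  seg_labels(p_maps$tumor > threshold, p_maps$rectum > threshold,
             p_maps$mesorectum > threshold)
}

#' Rule-based T2/T3 classification from masks
#'
#' A case is `LE_T2` when the predicted tumor is completely included in the
#' rectum mask, and `GE_T3` as soon as at least one tumor voxel lies outside
#' it (tumor tissue beyond the muscularis propria).  Contour voxels belong to
#' the rectum mask, so containment already implies no extramural tumor; the
#' optional `contour_strict` mode additionally calls `GE_T3` when the tumor
#' touches the outer rectum boundary from inside (face-connectivity boundary
#' extraction).  An empty tumor mask classifies as `LE_T2` with the
#' `tumor_empty` quality flag raised rather than erroring, so that batch
#' evaluation pipelines stay total.
#'
#' @param masks a [seg_labels] (the mesorectum channel is not consulted).
#' @param contour_strict also treat contact with the rectum contour as T3.
#' @return An object of class `stage_prediction` with fields `category`,
#'   `breach_voxel_count`, `tumor_empty`.
#' @export
classify_stage <- function(masks, contour_strict = FALSE) {
  stopifnot(inherits(masks, "seg_labels"))
  tumor <- masks$tumor; rectum <- masks$rectum
  if (!identical(dim(tumor), dim(rectum)))
    stop("tumor and rectum masks must share one shape")
  breach <- sum(tumor & !rectum)
  tumor_empty <- sum(tumor) == 0L
  category <- if (breach > 0L) "GE_T3" else "LE_T2"
  if (contour_strict && category == "LE_T2" && !tumor_empty) {
    if (any(tumor & mask_boundary(rectum))) category <- "GE_T3"
  }
  structure(list(category = category, breach_voxel_count = as.integer(breach),
                 tumor_empty = tumor_empty),
            class = "stage_prediction")
}

#' @export
print.stage_prediction <- function(x, ...) {
  cat(sprintf("<predicted %s, breach voxels %d%s>\n", x$category,
              x$breach_voxel_count,
              if (x$tumor_empty) ", tumor mask empty" else ""))
  invisible(x)
}

# Face-connected boundary of a mask: mask voxels with at least one of the six
# face neighbors outside the mask (volume border counts as outside).
mask_boundary <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, axis, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by > 0) { idx_dst[[axis]] <- seq(1 + by, n); idx_src[[axis]] <- seq(1, n - by) }
    else { idx_dst[[axis]] <- seq(1, n + by); idx_src[[axis]] <- seq(1 - by, n) }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(-1L, 1L))
    interior <- interior & shift_and(mask, axis, by)
  mask & !interior
}
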