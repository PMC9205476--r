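# Independent brute-force oracles (plain loops, no shared code with the
# package's vectorized implementations) and small fixture builders.

brute_staging_probability <- function(pm) {
  best <- -Inf
  d <- dim(pm$tumor)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    v <- pm$tumor[i, j, k] * (1 - pm$rectum[i, j, k])
    if (v > best) best <- v
  }
  best
}

brute_classify_stage <- function(masks) {
  d <- dim(masks$tumor)
  breach <- 0L
  n_tumor <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (masks$tumor[i, j, k]) {
      n_tumor <- n_tumor + 1L
      if (!masks$rectum[i, j, k]) breach <- breach + 1L
    }
  }
  list(category = if (breach > 0L) "GE_T3" else "LE_T2",
       breach_voxel_count = breach, tumor_empty = n_tumor == 0L)
}

brute_dsc <- function(p, g) {
  inter <- 0L; np <- 0L; ng <- 0L
  for (i in seq_along(p)) {
    if (p[i]) np <- np + 1L
    if (g[i]) ng <- ng + 1L
    if (p[i] && g[i]) inter <- inter + 1L
  }
  if (np + ng == 0L) return(1)
  2 * inter / (np + ng)
}

random_prob_maps <- function(dims = c(5L, 4L, 3L)) {
  prob_maps(array(runif(prod(dims)), dims), array(runif(prod(dims)), dims),
            array(runif(prod(dims)), dims))
}

random_masks <- function(dims = c(5L, 4L, 3L), p = 0.4) {
  seg_labels(array(runif(prod(dims)) < p, dims),
             array(runif(prod(dims)) < p, dims),
             array(runif(prod(dims)) < p, dims))
}

# small, fast phantom spec for unit tests
tiny_spec <- function(...) {
  args <- list(grid_shape = c(40L, 40L, 10L), spacing_mm = c(1, 1, 3.5),
               lumen_radius_mm = 3, wall_thickness_mm = 2.5,
               mesorectum_radius_mm = 12, curvature_mm = 1,
               tumor_angular_extent_deg = 120, tumor_length_mm = 14,
               noise_sigma = 5, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

tiny_ranges <- function() {
  list(lumen_radius_mm = c(2.5, 3.5), wall_thickness_mm = c(2, 3),
       mesorectum_radius_mm = c(10, 12), curvature_mm = c(0, 1.5),
       tumor_angular_extent_deg = c(90, 150), tumor_length_mm = c(10, 16),
       tumor_angle_deg = c(0, 360), invasion_t2 = c(-2, -0.5),
       invasion_t3 = c(2, 3.5), noise_sigma = c(5, 5))
}

tiny_cohort <- function(n, ...) {
  generate_cohort(n, spec_ranges = tiny_ranges(),
                  grid_shape = c(40L, 40L, 10L), spacing_mm = c(1, 1, 3.5),
                  ...)
}
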