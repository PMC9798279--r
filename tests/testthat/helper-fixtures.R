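# Shared fixtures: a reduced two-lobe ROI and synthetic configuration so
# unit tests run on hundreds rather than thousands of voxels. The
# full-size study configuration is exercised in test-acceptance.R.

small_mask <- function() {
  make_roi_mask(grid_shape = c(28L, 32L, 24L), voxel_size_mm = 1.0,
                total_volume_cc = 0.8)
}

small_synth_config <- function(seed = 1L, noise_sd = 0.25, ...) {
  synth_config(grid_shape = c(28L, 32L, 24L), voxel_size_mm = 1.0,
               total_volume_cc = 0.8, n_subjects_per_group = c(30L, 32L),
               k_sources = 3L, group_effect = c(1, 0, 0), noise_sd = noise_sd,
               seed = seed, ...)
}

small_pipeline_config <- function(seed = 1L, n_runs = 6L, ...) {
  sbm_config(synthetic = small_synth_config(seed = seed),
             k_policy = "fixed", k_fixed = 3L, n_runs = n_runs,
             seed = seed, ...)
}

# Unit-variance Laplace (double-exponential) sample: the super-Gaussian
# source family the Infomax score is consistent for.
rlaplace_unit <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# mm coordinates of the in-mask voxels, rows aligned with the stacked
# data-matrix columns.
mask_coords_mm <- function(mask) {
  idx <- which(mask$values)
  co <- arrayInd(idx, dim(mask$values))
  d <- dim(mask$values)
  sapply(1:3, function(a) {
    (co[, a] - (d[a] + 1) / 2) * mask$voxel_size_mm[a]
  })
}
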