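test_that("default ROI mask hits the target voxel counts", {
  m <- make_roi_mask()                      # 3 cc at 0.9 mm
  expect_lt(abs(sum(m$values) - 4115) / 4115, 0.01)
  m1 <- make_roi_mask(grid_shape = c(44L, 52L, 36L), voxel_size_mm = 1.0)
  expect_lt(abs(sum(m1$values) - 3000) / 3000, 0.01)
})

test_that("mask is mirror-symmetric with two disjoint lobes", {
  m <- small_mask()
  flipped <- m$values[dim(m$values)[1]:1, , ]
  expect_identical(m$values, flipped)
  xs <- mask_coords_mm(m)[, 1]
  expect_equal(sum(xs < 0), sum(xs > 0))    # equal lobes, nothing on the midline
  # lobes are separated: no mask voxel in the two columns nearest the midline
  gap <- abs(xs) < 1.5 * m$voxel_size_mm[1]
  expect_false(any(gap))
})

test_that("a too-small grid raises a sizing error", {
  expect_error(make_roi_mask(grid_shape = c(10L, 10L, 10L), voxel_size_mm = 0.9),
               class = "sizing_error")
})

test_that("sources are standardized and pairwise weakly correlated", {
  m <- small_mask()
  S <- make_sources(m, default_blob_spec(m, 3L))
  expect_equal(rowMeans(S), rep(0, 3), tolerance = 1e-9)
  expect_equal(apply(S, 1, sd), rep(1, 3), tolerance = 1e-9)
})

test_that("default full-size layout keeps sources nearly independent", {
  m <- make_roi_mask()
  S <- make_sources(m, default_blob_spec(m, 7L))
  cc <- abs(cor(t(S)))
  diag(cc) <- 0
  expect_lt(max(cc), 0.3)
})

test_that("bilateral sources are suprathreshold in both lobes", {
  m <- small_mask()
  p <- attr(m, "lobe_params")
  S <- make_sources(m, list(list(center = c(p$cx, 0, 0), radius_mm = 4,
                                 laterality = "bilateral")))
  z <- zscale_map(S[1, ])
  xs <- mask_coords_mm(m)[, 1]
  expect_gt(sum(z > 3 & xs < 0), 0)
  expect_gt(sum(z > 3 & xs > 0), 0)
})

test_that("far-separated disjoint blobs are nearly uncorrelated", {
  m <- make_roi_mask()
  p <- attr(m, "lobe_params")
  spec <- list(
    list(center = c(p$cx + p$bend_x * 0.49, -0.7 * p$ry, -0.7 * p$bend_z),
         radius_mm = 3, laterality = "left"),
    list(center = c(-(p$cx + p$bend_x * 0.49), 0.7 * p$ry, 0.7 * p$bend_z),
         radius_mm = 3, laterality = "right"))
  S <- make_sources(m, spec)
  expect_lt(abs(cor(S[1, ], S[2, ])), 0.05)
})

test_that("blobs outside the mask raise placement errors", {
  m <- small_mask()
  expect_error(make_sources(m, list(list(center = c(100, 0, 0), radius_mm = 2,
                                         laterality = "left"))),
               class = "placement_error")
})

test_that("loadings carry the configured group shift", {
  cfg0 <- synth_config(n_subjects_per_group = c(50L, 50L), k_sources = 3L,
                       group_effect = c(0, 0, 0), seed = 5L)
  sl0 <- make_subjects_and_loadings(cfg0)
  # null model: pooled column means vanish (exact standardisation)
  expect_equal(colMeans(sl0$A_true), rep(0, 3), tolerance = 1e-10)
  expect_identical(sl0$affected_components, integer(0))

  cfg1 <- synth_config(n_subjects_per_group = c(1000L, 1000L), k_sources = 2L,
                       group_effect = c(1, 0), seed = 9L)
  sl1 <- make_subjects_and_loadings(cfg1)
  grp <- sl1$subjects$group
  diff0 <- mean(sl1$A_true[grp == "MDD", 1]) - mean(sl1$A_true[grp == "HS", 1])
  # SE of the difference ~ sqrt(2/1000) = 0.045; 3-sigma band around 1.0
  expect_gt(diff0, 0.86)
  expect_lt(diff0, 1.14)
})

test_that("subject generation is deterministic and validates config", {
  cfg <- small_synth_config(seed = 21L)
  a <- make_subjects_and_loadings(cfg)
  b <- make_subjects_and_loadings(cfg)
  expect_identical(a, b)
  bad_cov <- default_covariate_spec()
  bad_cov$age$mdd["sd"] <- -1
  expect_error(synth_config(covariate_spec = bad_cov), class = "config_error")
  expect_error(synth_config(k_sources = 3L, group_effect = c(1, 0)),
               class = "config_error")
})

test_that("covariates are confounded by default and balanced when disabled", {
  cfg <- synth_config(n_subjects_per_group = c(200L, 200L), seed = 3L)
  sl <- make_subjects_and_loadings(cfg)
  g <- sl$subjects$group
  expect_gt(mean(sl$subjects$age[g == "MDD"]) - mean(sl$subjects$age[g == "HS"]), 5)
  cfg2 <- synth_config(n_subjects_per_group = c(200L, 200L), seed = 3L,
                       confound_covariates = FALSE)
  sl2 <- make_subjects_and_loadings(cfg2)
  g2 <- sl2$subjects$group
  expect_lt(abs(mean(sl2$subjects$age[g2 == "MDD"]) -
                mean(sl2$subjects$age[g2 == "HS"])), 5)
})

test_that("synthesized volumes invert to the exact product without noise", {
  m <- small_mask()
  cfg <- small_synth_config()
  S <- make_sources(m, default_blob_spec(m, 3L))
  sl <- make_subjects_and_loadings(cfg)
  vols <- synthesize_volumes(sl$A_true, S, m, noise_sd = 0)
  dm <- apply_mask_and_stack(vols, m)
  expect_equal(dm$X, sl$A_true %*% S, tolerance = 1e-12)
  expect_error(synthesize_volumes(sl$A_true[, 1:2], S, m), class = "shape_error")
})

test_that("voxel noise has the configured standard deviation", {
  m <- small_mask()
  S <- make_sources(m, default_blob_spec(m, 3L))
  cfg <- synth_config(grid_shape = c(28L, 32L, 24L), voxel_size_mm = 1.0,
                      total_volume_cc = 0.8, n_subjects_per_group = c(77L, 79L),
                      k_sources = 3L, group_effect = c(0, 0, 0), seed = 2L)
  sl <- make_subjects_and_loadings(cfg)
  vols <- synthesize_volumes(sl$A_true, S, m, noise_sd = 0.5, seed = 8L)
  dm <- apply_mask_and_stack(vols, m)
  resid <- dm$X - sl$A_true %*% S
  sds <- apply(resid, 2, sd)
  # chi-distribution spread of a sample SD at n = 156
  expect_gt(mean(sds), 0.44); expect_lt(mean(sds), 0.56)
  band <- 0.5 * sqrt(qchisq(c(5e-4, 1 - 5e-4), df = 155) / 155)
  expect_gt(mean(sds > band[1] & sds < band[2]), 0.995)
  # determinism
  vols2 <- synthesize_volumes(sl$A_true, S, m, noise_sd = 0.5, seed = 8L)
  expect_identical(vols[[10]]$values, vols2[[10]]$values)
})
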