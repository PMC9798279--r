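#' Configuration for the synthetic hippocampal SBM dataset
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: two groups of 77 (MDD) and 79
#' (HS) subjects with group-confounded age and education, a bilateral
#' two-lobe ROI of about 3 cc sampled at 0.9 mm isotropic resolution, seven
#' planted spatial sources (four homotopic bilateral, three along a lobe's
#' longitudinal axis), a 0.6-SD group mean shift on the loadings of the
#' first two (bilateral) sources, and i.i.d. Gaussian voxel noise.
#'
#' @param grid_shape integer triple, grid dimensions in voxels.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param n_subjects_per_group integer pair `c(n_mdd, n_hs)`.
#' @param k_sources number of planted sources (>= 1).
#' @param blob_spec optional per-source list of
#'   `list(center = c(x, y, z) [mm], radius_mm, laterality)` with laterality
#'   one of `"left"`, `"right"`, `"bilateral"`, `"longitudinal"`; `NULL`
#'   uses [default_blob_spec()].
#' @param group_effect numeric vector (length `k_sources`) of loading mean
#'   shifts, in within-group SD units, added to the MDD rows.
#' @param noise_sd SD of the additive i.i.d. voxel noise (>= 0).
#' @param noise_smooth_fwhm_mm optional FWHM (mm) used to smooth the noise
#'   field, giving spatially correlated noise; 0 (default) keeps it i.i.d.
#' @param covariate_spec per-group covariate distributions; `NULL` uses
#'   [default_covariate_spec()].
#' @param total_volume_cc total in-mask ROI volume, cc.
#' @param confound_covariates if `FALSE`, both groups share the pooled
#'   covariate distributions (removes the group confound).
#' @param seed master seed; identical seeds reproduce identical datasets.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(48L, 56L, 40L),
                         voxel_size_mm = 0.9,
                         n_subjects_per_group = c(77L, 79L),
                         k_sources = 7L,
                         blob_spec = NULL,
                         group_effect = NULL,
                         noise_sd = 0.25,
                         noise_smooth_fwhm_mm = 0,
                         covariate_spec = NULL,
                         total_volume_cc = 3,
                         confound_covariates = TRUE,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    stop_hippsbm("grid_shape must be three integers >= 4", "config_error")
  if (voxel_size_mm <= 0) stop_hippsbm("voxel_size_mm must be > 0", "config_error")
  if (length(n_subjects_per_group) != 2L || any(n_subjects_per_group < 2))
    stop_hippsbm("need at least 2 subjects per group", "config_error")
  if (k_sources < 1L) stop_hippsbm("k_sources must be >= 1", "config_error")
  if (is.null(group_effect))
    group_effect <- c(0.6, 0.6, rep(0, max(0, k_sources - 2)))[seq_len(k_sources)]
  if (length(group_effect) != k_sources)
    stop_hippsbm("group_effect must have one entry per source", "config_error")
  if (noise_sd < 0) stop_hippsbm("noise_sd must be >= 0", "config_error")
  if (!is.null(blob_spec)) {
    if (length(blob_spec) != k_sources)
      stop_hippsbm("blob_spec must have one entry per source", "config_error")
    for (b in blob_spec)
      if (b$radius_mm <= 0) stop_hippsbm("all blob radii must be > 0", "config_error")
  }
  cov_spec <- covariate_spec %||% default_covariate_spec()
  for (v in c("age", "education")) for (g in c("mdd", "hs"))
    if (cov_spec[[v]][[g]]["sd"] < 0)
      stop_hippsbm("covariate SDs must be >= 0", "config_error")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 k_sources = as.integer(k_sources),
                 blob_spec = blob_spec,
                 group_effect = group_effect,
                 noise_sd = noise_sd,
                 noise_smooth_fwhm_mm = noise_smooth_fwhm_mm,
                 covariate_spec = cov_spec,
                 total_volume_cc = total_volume_cc,
                 confound_covariates = confound_covariates,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default per-group covariate distributions
#'
#' Age is drawn from truncated normals (MDD: mean 52.0, SD 15.1, range
#' 22-73; HS: mean 38.9, SD 10.2, range 20-65), years of education from
#' normals (13.4 +/- 2.5 vs 16.7 +/- 3.0), sex from Bernoulli draws with
#' female probabilities 44/77 (MDD) and 34/79 (HS), and the MDD depression
#' severity score from a truncated normal (22.6 +/- 5.9, minimum 14, the
#' usual moderate-severity inclusion floor).
#'
#' @return a nested list used as `covariate_spec` in [synth_config()].
#' @export
default_covariate_spec <- function() {
  list(age = list(mdd = c(mean = 52.0, sd = 15.1, lo = 22, hi = 73),
                  hs  = c(mean = 38.9, sd = 10.2, lo = 20, hi = 65)),
       education = list(mdd = c(mean = 13.4, sd = 2.5, lo = 6, hi = Inf),
                        hs  = c(mean = 16.7, sd = 3.0, lo = 6, hi = Inf)),
       sex_female_p = c(mdd = 44 / 77, hs = 34 / 79),
       hamd17 = c(mean = 22.6, sd = 5.9, lo = 14, hi = Inf))
}

## Lobe shape parameters, all in mm, scaled from the 3 cc reference design
## by the cube root of the volume ratio so smaller test ROIs keep the same
## proportions.
lobe_params <- function(total_volume_cc) {
  s <- (total_volume_cc / 3)^(1 / 3)
  list(scale = s,
       a = 4.73 * s,        # transverse (x, z) radius
       ry = 16 * s,         # longitudinal (y) radius
       cx = -11 * s,        # left lobe centre (x)
       bend_x = 2.5 * s,    # medial curvature of the lobe axis
       bend_z = 2.0 * s)    # inferior-superior tilt
}

## Implicit lobe function: <= 1 roughly inside the curved ellipsoid whose
## long axis runs along y, bending medially at both ends.
lobe_field <- function(x, y, z, p) {
  u <- y / p$ry
  lx <- p$cx + p$bend_x * u^2
  lz <- p$bend_z * u
  ((x - lx) / p$a)^2 + u^2 + ((z - lz) / p$a)^2
}

#' Generate a two-lobe bilateral ROI mask
#'
#' Builds a mirror-symmetric pair of curved ellipsoidal lobes (a toy
#' bilateral hippocampus) on a centred grid. The in-mask voxel count is
#' calibrated exactly: each lobe keeps the `floor(target / 2)` voxels with
#' the smallest implicit-shape value, where the target is
#' [voxel_count()]`(total_volume_cc, voxel_size_mm)`, so a 3 cc ROI at
#' 0.9 mm holds 4114 voxels (target 4115) and at 1 mm exactly 3000.
#'
#' @param grid_shape integer triple of grid dimensions.
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @param total_volume_cc total in-mask volume, cc.
#' @param seed accepted for interface symmetry with the other generator
#'   operations; the mask is deterministic in its parameters.
#' @return a `volume_grid` with logical values, classed `roi_mask`; lobe
#'   shape parameters are attached as attribute `lobe_params`.
#' @export
make_roi_mask <- function(grid_shape = c(48L, 56L, 40L), voxel_size_mm = 0.9,
                          total_volume_cc = 3, seed = 1L) {
  target <- voxel_count(total_volume_cc, voxel_size_mm)
  per_lobe <- target %/% 2L
  d <- as.integer(grid_shape)
  grid <- volume_grid(array(FALSE, d), voxel_size_mm)
  ax <- grid_axis_mm(grid)
  p <- lobe_params(total_volume_cc)
  left <- which(ax[[1]] < 0)
  if (length(left) < 2L)
    stop_hippsbm("grid too small: no voxels strictly left of the midline", "sizing_error")
  co <- expand.grid(i = left, j = seq_len(d[2]), k = seq_len(d[3]))
  f <- lobe_field(ax[[1]][co$i], ax[[2]][co$j], ax[[3]][co$k], p)
  if (length(f) < per_lobe)
    stop_hippsbm("grid too small to hold the requested lobe volume", "sizing_error")
  sel <- co[order(f)[seq_len(per_lobe)], ]
  if (any(sel$i == 1L | sel$j %in% c(1L, d[2]) | sel$k %in% c(1L, d[3])))
    stop_hippsbm("grid too small: lobe touches the grid boundary", "sizing_error")
  vals <- array(FALSE, d)
  vals[cbind(sel$i, sel$j, sel$k)] <- TRUE
  vals <- vals | vals[d[1]:1, , , drop = FALSE]  # mirror across the midline
  mask <- volume_grid(vals, voxel_size_mm)
  attr(mask, "lobe_params") <- p
  attr(mask, "target_count") <- target
  class(mask) <- c("roi_mask", class(mask))
  mask
}

#' Default planted-source layout
#'
#' Places `k_sources` (up to 7) Gaussian-bump sources in the two-lobe mask:
#' four homotopic bilateral sources spaced along the longitudinal axis,
#' then three two-bump sources running along a single lobe's long axis,
#' offset towards the superior edge of the lobe so their overlap with the
#' bilateral set stays small. Positions follow the lobe centreline stored
#' on masks produced by [make_roi_mask()].
#'
#' @param mask an `roi_mask` from [make_roi_mask()].
#' @param k_sources number of sources (1-7).
#' @return a blob-spec list as accepted by [make_sources()].
#' @export
default_blob_spec <- function(mask, k_sources = 7L) {
  p <- attr(mask, "lobe_params")
  if (is.null(p))
    stop_hippsbm("mask has no lobe parameters; supply blob_spec explicitly",
                 "config_error")
  if (k_sources > 7L)
    stop_hippsbm("default layout defines at most 7 sources; supply blob_spec",
                 "config_error")
  on_axis <- function(u, dz = 0) {
    c(p$cx + p$bend_x * u^2, u * p$ry, p$bend_z * u + dz)
  }
  radius <- 4.4 * p$scale
  spec <- list(
    list(center = on_axis(-0.75, -1.0 * p$scale), radius_mm = radius, laterality = "bilateral"),
    list(center = on_axis(-0.25, -1.0 * p$scale), radius_mm = radius, laterality = "bilateral"),
    list(center = on_axis(0.25, -1.0 * p$scale), radius_mm = radius, laterality = "bilateral"),
    list(center = on_axis(0.75, -1.0 * p$scale), radius_mm = radius, laterality = "bilateral"),
    list(center = rbind(on_axis(-0.55, 2.4 * p$scale), on_axis(-0.05, 2.4 * p$scale)),
         radius_mm = radius, laterality = "longitudinal"),
    list(center = rbind(mirror_x(on_axis(0.05, 2.4 * p$scale)),
                        mirror_x(on_axis(0.55, 2.4 * p$scale))),
         radius_mm = radius, laterality = "longitudinal"),
    list(center = rbind(on_axis(0.45, 2.4 * p$scale), on_axis(0.90, 2.4 * p$scale)),
         radius_mm = radius, laterality = "longitudinal"))
  spec[seq_len(k_sources)]
}

mirror_x <- function(v) {
  if (is.matrix(v)) t(apply(v, 1, mirror_x)) else c(-v[1], v[2], v[3])
}

#' Generate planted spatial sources
#'
#' Each source is a sum of isotropic Gaussian bumps (SD = `radius_mm / 2`)
#' evaluated at the in-mask voxels and standardised to zero mean and unit
#' SD over the mask. Laterality `"bilateral"` mirrors the bump(s) across
#' the x midline into the homotopic position; `"longitudinal"` expects (or
#' creates) at least two bumps along one lobe's long axis; `"left"` and
#' `"right"` place the bump in the stated hemisphere (mirroring the given
#' centre if it lies on the wrong side).
#'
#' @param mask the ROI mask `volume_grid`.
#' @param blob_spec per-source list of `list(center, radius_mm, laterality)`;
#'   `center` is a length-3 mm coordinate or a matrix of bump centres
#'   (one row per bump).
#' @param seed accepted for interface symmetry; sources are deterministic.
#' @return matrix `S_true` (`k` x `V`) over the mask voxels in grid raster
#'   order, rows standardised to mean 0 / SD 1.
#' @export
make_sources <- function(mask, blob_spec, seed = 1L) {
  idx <- which(mask$values)
  V <- length(idx)
  if (V < 2L) stop_hippsbm("mask must contain at least 2 voxels", "value_error")
  co <- arrayInd(idx, dim(mask$values))
  ax <- grid_axis_mm(mask)
  xyz <- cbind(ax[[1]][co[, 1]], ax[[2]][co[, 2]], ax[[3]][co[, 3]])
  bbox <- apply(xyz, 2, range)
  S <- matrix(0, length(blob_spec), V)
  for (k in seq_along(blob_spec)) {
    b <- blob_spec[[k]]
    centers <- if (is.matrix(b$center)) b$center else matrix(b$center, 1)
    lat <- match.arg(b$laterality, c("left", "right", "bilateral", "longitudinal"))
    if (lat == "bilateral") {
      centers <- rbind(centers, t(apply(centers, 1, mirror_x)))
    } else if (lat == "left") {
      centers[centers[, 1] > 0, 1] <- -centers[centers[, 1] > 0, 1]
    } else if (lat == "right") {
      centers[centers[, 1] < 0, 1] <- -centers[centers[, 1] < 0, 1]
    } else if (lat == "longitudinal" && nrow(centers) < 2L) {
      off <- c(0, 1.5 * b$radius_mm, 0)
      centers <- rbind(centers[1, ] - off, centers[1, ] + off)
    }
    sigma <- b$radius_mm / 2
    g <- numeric(V)
    reachable <- FALSE
    for (r in seq_len(nrow(centers))) {
      ctr <- centers[r, ]
      if (any(ctr < bbox[1, ] - 1e-9) || any(ctr > bbox[2, ] + 1e-9))
        stop_hippsbm(sprintf("source %d: bump centre outside the mask bounding box", k),
                     "placement_error")
      d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
      if (min(d2) <= (2 * sigma)^2) reachable <- TRUE
      g <- g + exp(-d2 / (2 * sigma^2))
    }
    if (!reachable)
      stop_hippsbm(sprintf("source %d: blob lies entirely outside the mask", k),
                   "placement_error")
    S[k, ] <- (g - mean(g)) / sd(g)
  }
  S
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate the subject table and ground-truth loadings
#'
#' Draws per-group covariates from the configured distributions (by default
#' confounded between groups, so covariate adjustment in the group tests is
#' genuinely exercised) and a loading matrix whose columns are standardised
#' to zero mean and unit SD before the configured group mean shift is added
#' to the MDD rows of the affected components.
#'
#' @param config a [synth_config()].
#' @return list with `subjects` (data.frame: subject_id, group, age, sex,
#'   education_years, hamd17), `A_true` (N x k loading matrix) and
#'   `affected_components` (indices with nonzero group effect).
#' @export
make_subjects_and_loadings <- function(config) {
  n_mdd <- config$n_subjects_per_group[1]
  n_hs <- config$n_subjects_per_group[2]
  n <- n_mdd + n_hs
  cs <- config$covariate_spec
  withr::with_seed(config$seed, {
    draw <- function(spec_mdd, spec_hs) {
      if (!config$confound_covariates) {
        pooled <- (spec_mdd + spec_hs) / 2
        pooled[c("lo", "hi")] <- c(min(spec_mdd["lo"], spec_hs["lo"]),
                                   max(spec_mdd["hi"], spec_hs["hi"]))
        spec_mdd <- spec_hs <- pooled
      }
      c(rtrunc_norm(n_mdd, spec_mdd["mean"], spec_mdd["sd"], spec_mdd["lo"], spec_mdd["hi"]),
        rtrunc_norm(n_hs, spec_hs["mean"], spec_hs["sd"], spec_hs["lo"], spec_hs["hi"]))
    }
    age <- draw(cs$age$mdd, cs$age$hs)
    edu <- draw(cs$education$mdd, cs$education$hs)
    p_f <- if (config$confound_covariates) cs$sex_female_p
           else c(mdd = mean(cs$sex_female_p), hs = mean(cs$sex_female_p))
    sex <- c(rbinom(n_mdd, 1, p_f["mdd"]), rbinom(n_hs, 1, p_f["hs"]))
    hamd <- c(round(rtrunc_norm(n_mdd, cs$hamd17["mean"], cs$hamd17["sd"],
                                cs$hamd17["lo"], cs$hamd17["hi"])),
              rep(NA_real_, n_hs))
    A <- matrix(rnorm(n * config$k_sources), n, config$k_sources)
    A <- scale(A)                      # unit variance before the group shift
    attr(A, "scaled:center") <- attr(A, "scaled:scale") <- NULL
    mdd_rows <- seq_len(n_mdd)
    for (k in which(config$group_effect != 0))
      A[mdd_rows, k] <- A[mdd_rows, k] + config$group_effect[k]
  })
  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = factor(rep(c("MDD", "HS"), c(n_mdd, n_hs)), levels = c("HS", "MDD")),
    age = age,
    sex = factor(ifelse(sex == 1, "F", "M"), levels = c("M", "F")),
    education_years = edu,
    hamd17 = hamd,
    stringsAsFactors = FALSE)
  list(subjects = subjects, A_true = unclass(A),
       affected_components = which(config$group_effect != 0))
}

#' Synthesise subject volumes from loadings and sources
#'
#' Subject i's in-mask voxel vector is `sum_k A[i, k] * S[k, ]` plus
#' Gaussian noise of SD `noise_sd` (optionally smoothed into a spatially
#' correlated field); voxels outside the mask are zero.
#'
#' @param A_true N x k loading matrix.
#' @param S_true k x V source matrix over the mask voxels.
#' @param mask the ROI mask `volume_grid`.
#' @param noise_sd additive voxel noise SD.
#' @param seed seed for the noise draw.
#' @param noise_smooth_fwhm_mm if > 0, the noise field is Gaussian-smoothed
#'   with this FWHM (and rescaled back to SD `noise_sd`) before masking.
#' @return named list of `volume_grid` objects, one per subject row.
#' @export
synthesize_volumes <- function(A_true, S_true, mask, noise_sd = 0.25, seed = 1L,
                               noise_smooth_fwhm_mm = 0) {
  if (ncol(A_true) != nrow(S_true))
    stop_hippsbm("column count of A_true must equal row count of S_true", "shape_error")
  idx <- which(mask$values)
  if (ncol(S_true) != length(idx))
    stop_hippsbm("S_true columns must match the mask voxel count", "shape_error")
  n <- nrow(A_true)
  X <- A_true %*% S_true
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      if (noise_smooth_fwhm_mm > 0) {
        for (i in seq_len(n)) {
          e <- array(rnorm(prod(dim(mask$values))), dim(mask$values))
          e <- smooth_array(e, fwhm_to_sigma(noise_smooth_fwhm_mm, mask$voxel_size_mm))
          X[i, ] <- X[i, ] + noise_sd * (e[idx] / sd(e))
        }
      } else {
        X <- X + matrix(rnorm(n * length(idx), 0, noise_sd), n)
      }
    })
  }
  vols <- lapply(seq_len(n), function(i) scatter_to_grid(X[i, ], mask))
  names(vols) <- sprintf("sub-%03d", seq_len(n))
  vols
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [make_roi_mask()], [make_sources()],
#' [make_subjects_and_loadings()] and [synthesize_volumes()] from one
#' configuration, with stage seeds derived deterministically from the
#' master seed.
#'
#' @param config a [synth_config()].
#' @return list with `mask`, `S_true`, `A_true`, `subjects`,
#'   `affected_components`, `volumes` and the `config`.
#' @export
generate_synthetic_dataset <- function(config) {
  seeds <- derive_seeds(config$seed, 3L)
  mask <- make_roi_mask(config$grid_shape, config$voxel_size_mm,
                        config$total_volume_cc, seed = seeds[1])
  blob_spec <- config$blob_spec %||% default_blob_spec(mask, config$k_sources)
  S_true <- make_sources(mask, blob_spec, seed = seeds[1])
  subj <- make_subjects_and_loadings(config)
  volumes <- synthesize_volumes(subj$A_true, S_true, mask,
                                noise_sd = config$noise_sd, seed = seeds[2],
                                noise_smooth_fwhm_mm = config$noise_smooth_fwhm_mm)
  names(volumes) <- subj$subjects$subject_id
  list(mask = mask, S_true = S_true, A_true = subj$A_true,
       subjects = subj$subjects, affected_components = subj$affected_components,
       volumes = volumes, config = config)
}

#' Write a synthetic dataset to disk
#'
#' Persists the volumes and mask as NIfTI-1 (`.nii.gz`), the subject table
#' as TSV, and the ground truth (sources, loadings, affected set) as CSV
#' matrices with a JSON manifest.
#'
#' @param dataset result of [generate_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
  write_volume(dataset$mask, file.path(dir, "mask.nii.gz"))
  for (id in names(dataset$volumes))
    write_volume(dataset$volumes[[id]], file.path(dir, "volumes", paste0(id, ".nii.gz")))
  write.table(dataset$subjects, file.path(dir, "subjects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$S_true, file.path(dir, "S_true.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(dataset$A_true, file.path(dir, "A_true.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  manifest <- list(k_sources = dataset$config$k_sources,
                   affected_components = dataset$affected_components,
                   group_effect = dataset$config$group_effect,
                   noise_sd = dataset$config$noise_sd,
                   voxel_size_mm = dataset$config$voxel_size_mm,
                   grid_shape = dataset$config$grid_shape,
                   seed = dataset$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
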