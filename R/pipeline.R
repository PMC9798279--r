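#' Pipeline configuration
#'
#' Collects every setting of the end-to-end SBM analysis. The defaults
#' reproduce the reference analysis protocol: 3 mm FWHM smoothing, MDL
#' model-order selection, Infomax ICA repeated 20 times under ICASSO
#' RandInit with a [16, 20] cluster-size stability band, z-maps
#' thresholded at |z| > 3.0 with 0.1 cc minimum reported clusters,
#' covariate-adjusted group tests Bonferroni-corrected at family alpha
#' 0.05, and a 0.5 probability cutoff for the logistic classifier.
#'
#' @param synthetic a [synth_config()] to generate the inputs, or `NULL`
#'   when reading real data from `paths`.
#' @param paths list with `volumes` (character vector of NIfTI paths, in
#'   subject-table order), `mask` (NIfTI path) and `subjects` (TSV path);
#'   ignored when `synthetic` is given.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 3).
#' @param k_policy `"mdl"` (data-determined order) or `"fixed"`.
#' @param k_fixed component count when `k_policy = "fixed"`.
#' @param k_max largest order considered by MDL.
#' @param n_runs ICASSO repetitions (default 20).
#' @param icasso_mode only `"RandInit"`.
#' @param min_cluster_size,max_cluster_size ICASSO stability band.
#' @param iq_threshold minimum cluster quality index.
#' @param z_threshold component z-map display threshold.
#' @param min_report_cc minimum reported cluster volume, cc.
#' @param edge_fraction artifact boundary-fraction limit.
#' @param exclude_flagged drop flagged (unstable or artifact-like)
#'   components from the group statistics (default FALSE: flags are
#'   advisory).
#' @param covariates covariate columns for the adjusted group tests.
#' @param family_alpha family-wise alpha.
#' @param cutoff logistic probability cutoff.
#' @param seed master seed fixing all stochastic stages.
#' @return an object of class `sbm_pipeline_config`.
#' @export
sbm_config <- function(synthetic = synth_config(),
                       paths = NULL,
                       fwhm_mm = 3,
                       k_policy = c("mdl", "fixed"),
                       k_fixed = NULL,
                       k_max = 30L,
                       n_runs = 20L,
                       icasso_mode = "RandInit",
                       min_cluster_size = NULL,
                       max_cluster_size = NULL,
                       iq_threshold = 0.8,
                       z_threshold = 3.0,
                       min_report_cc = 0.1,
                       edge_fraction = 0.5,
                       exclude_flagged = FALSE,
                       covariates = c("age", "sex", "education_years"),
                       family_alpha = 0.05,
                       cutoff = 0.5,
                       seed = 1L) {
  k_policy <- match.arg(k_policy)
  if (k_policy == "fixed" && is.null(k_fixed))
    stop_hippsbm("k_policy = 'fixed' requires k_fixed", "config_error")
  if (is.null(synthetic) && is.null(paths))
    stop_hippsbm("either a synthetic config or input paths are required", "config_error")
  structure(list(synthetic = synthetic, paths = paths, fwhm_mm = fwhm_mm,
                 k_policy = k_policy, k_fixed = k_fixed, k_max = as.integer(k_max),
                 n_runs = as.integer(n_runs), icasso_mode = icasso_mode,
                 min_cluster_size = min_cluster_size,
                 max_cluster_size = max_cluster_size,
                 iq_threshold = iq_threshold, z_threshold = z_threshold,
                 min_report_cc = min_report_cc, edge_fraction = edge_fraction,
                 exclude_flagged = exclude_flagged, covariates = covariates,
                 family_alpha = family_alpha, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "sbm_pipeline_config")
}

read_pipeline_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- derive_seeds(config$seed, 2L)[1]
    ds <- generate_synthetic_dataset(syn)
    list(volumes = ds$volumes, mask = ds$mask, subjects = ds$subjects,
         truth = list(S_true = ds$S_true, A_true = ds$A_true,
                      affected_components = ds$affected_components))
  } else {
    p <- config$paths
    subjects <- read.table(p$subjects, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    subjects$group <- factor(subjects$group, levels = c("HS", "MDD"))
    if ("sex" %in% names(subjects))
      subjects$sex <- factor(subjects$sex, levels = c("M", "F"))
    if (length(p$volumes) != nrow(subjects))
      stop_hippsbm("one volume per subject-table row is required", "config_error")
    list(volumes = lapply(p$volumes, read_volume),
         mask = read_mask(p$mask),
         subjects = subjects, truth = NULL)
  }
}

#' Run the full SBM pipeline
#'
#' Executes smooth, mask-and-stack, centre, model-order selection,
#' ICASSO-stabilised Infomax ICA, component z-map reports, and the group
#' statistics (demographics, covariate-adjusted loading tests, logistic
#' classification with ROC), from either synthetic or on-disk inputs.
#'
#' @param config an [sbm_config()].
#' @param output_dir optional directory; when given, statistical tables
#'   (TSV), the stability report and a run manifest (JSON) and the
#'   component z-maps (NIfTI) are written there.
#' @return an object of class `sbm_run` collecting every stage output:
#'   `data` (the stacked `data_matrix`), `K`, `mdl_order`, `icasso`,
#'   `decomposition`, `reports`, `demographics`, `group_stats`,
#'   `logistic`, `roc`, `included_components`, `truth` (for synthetic
#'   inputs) and the `config`.
#' @export
run_sbm <- function(config, output_dir = NULL) {
  inputs <- read_pipeline_inputs(config)
  icasso_seed <- derive_seeds(config$seed, 2L)[2]

  smoothed <- lapply(inputs$volumes, gaussian_smooth, fwhm_mm = config$fwhm_mm)
  dm <- apply_mask_and_stack(smoothed, inputs$mask,
                             subject_ids = inputs$subjects$subject_id)
  ctr <- center_matrix(dm$X)

  k_max <- min(config$k_max, nrow(dm$X) - 1L, ncol(dm$X) - 1L)
  ## smoothing leaves ~one independent sample per kernel volume
  fwhm_vox <- config$fwhm_mm / inputs$mask$voxel_size_mm
  v_eff <- if (config$fwhm_mm > 0) ncol(dm$X) / prod(pmax(1, fwhm_vox)) else NULL
  mdl_k <- estimate_order_mdl(dm$X, k_max = k_max, effective_samples = v_eff)
  K <- if (config$k_policy == "fixed") config$k_fixed else as.integer(mdl_k)

  wh <- pca_whiten(ctr$X_centered, K)
  ica <- run_icasso(wh$Z, K, n_runs = config$n_runs, mode = config$icasso_mode,
                    seed = icasso_seed, min_size = config$min_cluster_size,
                    max_size = config$max_cluster_size)
  dec <- select_stable_components(ica, ctr$X_centered,
                                  iq_threshold = config$iq_threshold)

  reports <- component_reports(dec, inputs$mask, threshold = config$z_threshold,
                               min_report_cc = config$min_report_cc,
                               edge_fraction = config$edge_fraction)
  artifact <- vapply(reports, function(r) r$artifact$flag, logical(1))
  included <- if (config$exclude_flagged) unname(which(!(dec$flagged | artifact)))
              else seq_len(dec$K)
  if (length(included) == 0L)
    stop_hippsbm("no components left after exclusion", "stability_error")

  demographics <- compare_demographics(inputs$subjects)
  A_inc <- dec$A[, included, drop = FALSE]
  stats <- mancova_loadings(A_inc, inputs$subjects, covariates = config$covariates,
                            family_alpha = config$family_alpha)
  stats$component <- included
  logistic <- fit_logistic(A_inc, inputs$subjects, family_alpha = config$family_alpha)
  roc <- roc_and_classify(logistic, cutoff = config$cutoff)

  run <- structure(list(config = config, data = dm, subjects = inputs$subjects,
                        mask = inputs$mask, mdl_order = as.integer(mdl_k),
                        mdl_curve = attr(mdl_k, "mdl"), K = K, icasso = ica,
                        decomposition = dec, reports = reports,
                        artifact_flags = artifact,
                        included_components = included,
                        demographics = demographics, group_stats = stats,
                        logistic = logistic, roc = roc,
                        truth = inputs$truth),
                   class = "sbm_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' @export
print.sbm_run <- function(x, ...) {
  cat(sprintf("<sbm_run> %d subjects x %d voxels; K = %d (MDL suggested %d)\n",
              nrow(x$data$X), ncol(x$data$X), x$K, x$mdl_order))
  cat(sprintf("  ICASSO: cluster sizes %s; Iq %s\n",
              paste(x$icasso$cluster_sizes, collapse = "/"),
              paste(sprintf("%.2f", x$icasso$iq), collapse = "/")))
  sig <- x$group_stats$component[x$group_stats$significant]
  cat(sprintf("  Bonferroni-significant components: %s\n",
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  cat(sprintf("  classifier: AUC %.3f, accuracy %.1f%%\n", x$roc$auc, x$roc$accuracy))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(format(as.data.frame(d), digits = 8, trim = TRUE),
                                   file.path(dir, f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(run$demographics, "demographics.tsv")
  wt(run$group_stats, "group_stats.tsv")
  wt(run$logistic$coefficients, "logistic_model.tsv")
  wt(run$roc$roc, "roc_points.tsv")
  write_component_reports(run$reports, file.path(dir, "component_clusters.tsv"))
  write_stability_report(run$icasso, file.path(dir, "stability.json"))
  for (k in seq_len(run$decomposition$K))
    write_volume(scatter_to_grid(run$reports[[k]]$z_map, run$mask),
                 file.path(dir, sprintf("component_%02d_zmap.nii.gz", k)))
  cfg <- run$config
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic) else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("hippsbm")),
                   config = unclass(cfg),
                   K = run$K, mdl_order = run$mdl_order,
                   icasso = list(cluster_sizes = run$icasso$cluster_sizes,
                                 iq = run$icasso$iq,
                                 n_failed = run$icasso$n_failed),
                   artifact_flags = run$artifact_flags,
                   included_components = run$included_components,
                   auc = run$roc$auc, accuracy_pct = run$roc$accuracy)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Score a run against the planted ground truth
#'
#' Matches estimated sources to the planted ones by maximising summed
#' absolute spatial correlation (exact assignment), and reports the
#' matched spatial and loading correlations, the confusion between the
#' planted affected set and the Bonferroni-significant set, and the
#' achieved classifier AUC against the AUC of a logistic model fitted to
#' the planted loadings. Matching uses absolute correlations throughout,
#' so the report is invariant to any permutation or sign flip of the
#' planted sources.
#'
#' @param run an `sbm_run` (from synthetic inputs).
#' @param truth optional truth list (defaults to `run$truth`).
#' @return list of class `sbm_recovery`: `matching`, `spatial_correlation`
#'   (per matched pair), `loading_correlation`, `mean_spatial_correlation`,
#'   `detected_affected`, `planted_affected` (as estimated-component
#'   indices), `true_positive`, `false_positive`, `auc_achieved`,
#'   `auc_planted`.
#' @export
evaluate_against_truth <- function(run, truth = run$truth) {
  if (is.null(truth)) stop_hippsbm("run has no ground truth attached", "usage_error")
  S_est <- run$decomposition$S
  C <- abs(cor(t(S_est), t(truth$S_true)))
  k <- min(nrow(C), ncol(C))
  if (nrow(C) != ncol(C)) {
    ## unequal counts: greedy best pairs
    pairs <- integer(0)
    Cw <- C
    for (i in seq_len(k)) {
      best <- arrayInd(which.max(Cw), dim(Cw))
      pairs <- rbind(pairs, best)
      Cw[best[1], ] <- -1; Cw[, best[2]] <- -1
    }
    matching <- pairs
  } else {
    matching <- cbind(seq_len(k), match_components(C))
  }
  sp <- C[matching]
  lc <- abs(vapply(seq_len(k), function(i)
    cor(run$decomposition$A[, matching[i, 1]], truth$A_true[, matching[i, 2]]),
    numeric(1)))
  est_of_true <- setNames(matching[, 1], matching[, 2])
  planted_est <- unname(est_of_true[as.character(truth$affected_components)])
  sig <- run$group_stats$component[run$group_stats$significant]
  auc_planted <- tryCatch({
    m <- fit_logistic(truth$A_true, run$subjects)
    rank_auc(m$fitted_probabilities, m$labels)
  }, error = function(e) NA_real_)
  structure(list(matching = matching,
                 spatial_correlation = sp,
                 loading_correlation = lc,
                 mean_spatial_correlation = mean(sp),
                 detected_affected = sig,
                 planted_affected = sort(planted_est),
                 true_positive = sum(sig %in% planted_est),
                 false_positive = sum(!(sig %in% planted_est)),
                 exact_recovery = setequal(sig, planted_est),
                 auc_achieved = run$roc$auc,
                 auc_planted = auc_planted),
            class = "sbm_recovery")
}

#' @export
print.sbm_recovery <- function(x, ...) {
  cat(sprintf("<sbm_recovery> mean matched spatial |corr| %.3f (min %.3f)\n",
              x$mean_spatial_correlation, min(x$spatial_correlation)))
  cat(sprintf("  affected set: planted {%s}, detected {%s}\n",
              paste(x$planted_affected, collapse = ", "),
              paste(x$detected_affected, collapse = ", ")))
  cat(sprintf("  AUC achieved %.3f vs planted-model %.3f\n",
              x$auc_achieved, x$auc_planted))
  invisible(x)
}
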