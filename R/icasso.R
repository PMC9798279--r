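#' ICASSO run-stability analysis
#'
#' Repeats Infomax ICA `n_runs` times from random initialisations
#' (`RandInit` mode: same data, new unmixing matrix each run), computes
#' the absolute spatial correlation between every pair of estimated
#' components across all runs, clusters them by average-linkage
#' agglomeration on `1 - |corr|` cut at `K` clusters, and scores each
#' cluster with the quality index
#' `Iq = mean intra-cluster |corr| - mean |corr| to non-members`.
#' Each cluster's canonical component is its centrotype, the member with
#' the largest summed similarity to the other members. With `n_runs`
#' runs, a perfectly stable component recurs once per run, so clusters
#' whose size falls outside `[min_size, max_size]` (defaults 16 and 20
#' at the default 20 runs) are flagged unstable.
#'
#' @param Z whitened K x V matrix from [pca_whiten()].
#' @param K number of components.
#' @param n_runs number of ICA repetitions (>= 2; default 20).
#' @param mode initialisation mode; only `"RandInit"` is implemented.
#' @param seed master seed; per-run seeds are derived from it.
#' @param min_size,max_size stability acceptance band on cluster sizes;
#'   `NULL` defaults to `ceiling(0.8 * n_runs)` and `n_runs` (16 and 20
#'   for 20 runs).
#' @param run_seeds optional explicit per-run seeds (length `n_runs`),
#'   overriding the derived ones.
#' @param ... further arguments passed to [infomax_ica()].
#' @return an object of class `icasso_result`: list with `runs`,
#'   `similarity` ((R K) x (R K)), `cluster` (assignment vector),
#'   `clusters` (list of member index sets), `iq`, `centrotypes` (global
#'   component indices), `cluster_sizes`, `unstable` (logical per
#'   cluster), `n_failed`, and the run bookkeeping (`run_of`,
#'   `comp_of`).
#' @export
run_icasso <- function(Z, K, n_runs = 20L, mode = "RandInit", seed = 1L,
                       min_size = NULL, max_size = NULL, run_seeds = NULL, ...) {
  mode <- match.arg(mode, "RandInit")
  if (n_runs < 2L) stop_hippsbm("n_runs must be >= 2", "value_error")
  min_size <- min_size %||% ceiling(0.8 * n_runs)
  max_size <- max_size %||% n_runs
  run_seeds <- run_seeds %||% derive_seeds(seed, n_runs)
  if (length(run_seeds) != n_runs)
    stop_hippsbm("run_seeds must have length n_runs", "value_error")
  runs <- vector("list", n_runs)
  ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(infomax_ica(Z, seed = run_seeds[r], ...),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      runs[[r]] <- list(W = fit$W, S = fit$S, seed = run_seeds[r],
                        convergence_info = fit$convergence_info)
      ok[r] <- TRUE
    }
  }
  if (mean(!ok) > 0.2)
    stop_hippsbm(sprintf("%d of %d ICA runs failed", sum(!ok), n_runs),
                 "stability_error")
  used <- which(ok)
  S_all <- do.call(rbind, lapply(runs[used], `[[`, "S"))
  run_of <- rep(used, each = K)
  comp_of <- rep(seq_len(K), times = length(used))
  sim <- abs(cor(t(S_all)))
  sim[sim > 1] <- 1
  diag(sim) <- 1
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = K)
  clusters <- split(seq_along(cl), cl)
  iq <- vapply(seq_len(K), function(c) cluster_iq(sim, clusters[[c]]), numeric(1))
  centrotypes <- vapply(seq_len(K), function(c) {
    members <- clusters[[c]]
    members[which.max(rowSums(sim[members, members, drop = FALSE]))]
  }, integer(1))
  sizes <- lengths(clusters)
  structure(list(runs = runs, similarity = sim, cluster = cl,
                 clusters = clusters, iq = iq, centrotypes = centrotypes,
                 cluster_sizes = as.integer(sizes),
                 unstable = unname(sizes < min_size | sizes > max_size),
                 min_size = min_size, max_size = max_size,
                 n_runs = n_runs, n_failed = sum(!ok), K = as.integer(K),
                 run_of = run_of, comp_of = comp_of, seed = seed),
            class = "icasso_result")
}

## Quality index of one cluster: average within-cluster similarity over
## distinct member pairs (1 for singletons) minus the average similarity
## between members and all non-members.
cluster_iq <- function(sim, members) {
  m <- length(members)
  intra <- if (m > 1L) {
    block <- sim[members, members, drop = FALSE]
    (sum(block) - m) / (m * (m - 1L))
  } else 1
  outside <- setdiff(seq_len(nrow(sim)), members)
  extra <- if (length(outside) > 0L) mean(sim[members, outside, drop = FALSE]) else 0
  intra - extra
}

#' @export
print.icasso_result <- function(x, ...) {
  cat(sprintf("<icasso_result> K = %d, %d runs (%d failed)\n",
              x$K, x$n_runs, x$n_failed))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  Iq:", paste(sprintf("%.3f", x$iq), collapse = ", "), "\n")
  if (any(x$unstable))
    cat("  unstable clusters:", paste(which(x$unstable), collapse = ", "), "\n")
  invisible(x)
}

#' Select stable centrotype components
#'
#' Extracts each cluster's centrotype source, re-standardises and
#' sign-fixes it, and back-reconstructs the loading coefficients by least
#' squares against the centred data (`A = X_c St (S St)^-1`). Components
#' whose cluster size lies outside the stability band or whose quality
#' index falls below `iq_threshold` are flagged but retained, so the
#' caller decides about exclusion.
#'
#' @param result an `icasso_result` from [run_icasso()].
#' @param X_centered the column-centred data matrix the decomposition was
#'   computed from.
#' @param iq_threshold minimum cluster quality index (default 0.8).
#' @return an `ica_decomposition` with additional fields `iq`,
#'   `cluster_sizes`, `flagged` and `flag_reasons`.
#' @export
select_stable_components <- function(result, X_centered, iq_threshold = 0.8) {
  S_all <- do.call(rbind, lapply(result$runs[!vapply(result$runs, is.null, logical(1))],
                                 `[[`, "S"))
  S <- S_all[result$centrotypes, , drop = FALSE]
  A_ls <- X_centered %*% t(S) %*% solve(tcrossprod(S))
  std <- standardize_sources(S, A_ls)
  flagged <- result$unstable | result$iq < iq_threshold
  reasons <- ifelse(result$unstable,
                    sprintf("cluster size %d outside [%d, %d]",
                            result$cluster_sizes, result$min_size, result$max_size),
                    ifelse(result$iq < iq_threshold,
                           sprintf("Iq %.3f below %.2f", result$iq, iq_threshold), ""))
  if (all(flagged))
    stop_hippsbm("no stable components (all clusters flagged)", "stability_error")
  res <- norm(X_centered - std$A %*% std$S, "F") / norm(X_centered, "F")
  structure(list(A = std$A, S = std$S, K = result$K, residual = res,
                 convergence_info = NULL, seed = result$seed,
                 iq = result$iq, cluster_sizes = result$cluster_sizes,
                 flagged = flagged, flag_reasons = reasons),
            class = "ica_decomposition")
}

#' Write an ICASSO stability report
#'
#' @param result an `icasso_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(result, path) {
  rep <- list(K = result$K, n_runs = result$n_runs, n_failed = result$n_failed,
              clusters = lapply(seq_len(result$K), function(c) list(
                size = result$cluster_sizes[c],
                iq = result$iq[c],
                unstable = result$unstable[c],
                centrotype_run = result$run_of[result$centrotypes[c]],
                centrotype_component = result$comp_of[result$centrotypes[c]])))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
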