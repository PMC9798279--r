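make_small_Z <- function(K = 2L, V = 1500L, seed = 5L, noise = 0.02) {
  set.seed(seed)
  S <- do.call(rbind, replicate(K, rlaplace_unit(V), simplify = FALSE))
  A <- matrix(rnorm(20 * K), 20)
  X <- A %*% S + matrix(rnorm(20 * V, 0, noise), 20)
  ctr <- center_matrix(X)
  list(Z = pca_whiten(ctr$X_centered, K)$Z, X_centered = ctr$X_centered,
       S_true = S)
}

test_that("identical initializations give perfectly tight clusters", {
  zz <- make_small_Z()
  res <- run_icasso(zz$Z, 2L, n_runs = 2L, seed = 1L, run_seeds = c(7L, 7L))
  expect_identical(res$cluster_sizes, c(2L, 2L))
  for (c in 1:2) {
    members <- res$clusters[[c]]
    block <- res$similarity[members, members]
    expect_equal(block, matrix(1, 2, 2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("similarity matrix is symmetric with unit diagonal in [0, 1]", {
  zz <- make_small_Z(K = 3L, seed = 9L)
  res <- run_icasso(zz$Z, 3L, n_runs = 4L, seed = 2L)
  s <- res$similarity
  expect_equal(s, t(s), tolerance = 1e-12)
  expect_equal(unname(diag(s)), rep(1, nrow(s)))
  expect_true(all(s >= 0 & s <= 1 + 1e-12))
  expect_true(all(res$iq <= 1 + 1e-12 & res$iq >= -1 - 1e-12))
  expect_true(all(vapply(seq_len(res$K), function(c)
    res$centrotypes[c] %in% res$clusters[[c]], logical(1))))
  # clusters partition all run-components
  expect_identical(sort(unname(unlist(res$clusters))), seq_len(nrow(s)))
})

test_that("clustering matches the exhaustive best two-partition", {
  zz <- make_small_Z(K = 2L, seed = 13L, noise = 0.02)
  res <- run_icasso(zz$Z, 2L, n_runs = 4L, seed = 3L)
  sim <- res$similarity
  n <- nrow(sim)   # 8 components: enumerate all 2^(n-1)-1 bipartitions
  best_score <- -Inf; best_part <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    if (!any(grp) || all(grp)) next
    score <- mean(sim[grp, grp][lower.tri(sim[grp, grp])]) +
      mean(sim[!grp, !grp][lower.tri(sim[!grp, !grp])])
    if (is.finite(score) && score > best_score) {
      best_score <- score; best_part <- grp
    }
  }
  got <- res$cluster == res$cluster[1]
  expect_true(identical(got, best_part) || identical(got, !best_part))
})

test_that("quality index is sign-invariant and one for perfect clusters", {
  zz <- make_small_Z()
  res <- run_icasso(zz$Z, 2L, n_runs = 3L, seed = 4L)
  flipped <- lapply(seq_along(res$runs), function(r) res$runs[[r]]$S * -1)
  S_all <- do.call(rbind, lapply(res$runs, `[[`, "S"))
  S_flip <- do.call(rbind, flipped)
  sim_flip <- abs(cor(t(S_flip)))
  expect_equal(sim_flip, res$similarity, tolerance = 1e-10)
  # synthetic perfect similarity: two identical-up-to-sign clusters
  sim <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(hippsbm:::cluster_iq(sim, 1:2), 1)
  expect_equal(hippsbm:::cluster_iq(sim, 3:4), 1)
})

test_that("clustering is invariant to run order", {
  zz <- make_small_Z(K = 2L, seed = 23L)
  seeds <- c(101L, 202L, 303L, 404L)
  a <- run_icasso(zz$Z, 2L, n_runs = 4L, seed = 1L, run_seeds = seeds)
  b <- run_icasso(zz$Z, 2L, n_runs = 4L, seed = 1L, run_seeds = rev(seeds))
  part <- function(res) {
    key <- lapply(res$clusters, function(m)
      sort(paste(res$run_of[m], res$comp_of[m])))
    unname(key[order(vapply(key, paste, character(1), collapse = "|"))])
  }
  # relabel b's run ids back to a's ordering
  b$run_of <- (4L:1L)[b$run_of]
  expect_identical(part(a), part(b))
})

test_that("stable components are selected and flagged correctly", {
  zz <- make_small_Z(K = 3L, seed = 31L)
  res <- run_icasso(zz$Z, 3L, n_runs = 5L, seed = 6L)
  dec <- select_stable_components(res, zz$X_centered, iq_threshold = 0.8)
  expect_s3_class(dec, "ica_decomposition")
  expect_identical(dec$K, 3L)
  expect_equal(apply(dec$S, 1, sd), rep(1, 3), tolerance = 1e-9)
  expect_false(any(dec$flagged))
  # an absurd quality threshold flags everything and errors
  expect_error(select_stable_components(res, zz$X_centered, iq_threshold = 1.1),
               class = "stability_error")
  # a single raised threshold flags but keeps the component
  dec2 <- select_stable_components(res, zz$X_centered,
                                   iq_threshold = sort(res$iq)[2] - 1e-9)
  expect_identical(sum(dec2$flagged), 1L)
  expect_identical(dec2$K, 3L)
})

test_that("centrotype loadings are never materially worse than single runs", {
  # when every run converges the centrotype coincides with the common
  # solution, so score differences are ~1e-4; the guard is that the
  # centrotype never falls materially below a single run
  wins <- 0L
  for (s in 1:6) {
    m <- small_mask()
    S_true <- make_sources(m, default_blob_spec(m, 3L))
    sl <- make_subjects_and_loadings(small_synth_config(seed = 40L + s))
    vols <- synthesize_volumes(sl$A_true, S_true, m, noise_sd = 0.4, seed = 50L + s)
    ctr <- center_matrix(apply_mask_and_stack(vols, m)$X)
    wh <- pca_whiten(ctr$X_centered, 3L)
    res <- run_icasso(wh$Z, 3L, n_runs = 6L, seed = 60L + s)
    cen <- select_stable_components(res, ctr$X_centered)
    single <- back_reconstruct(ctr$X_centered, res$runs[[1]]$S, wh$dewhitening,
                               res$runs[[1]]$W)
    score <- function(A) {
      C <- abs(cor(A, sl$A_true))
      mean(C[cbind(1:3, match_components(C))])
    }
    if (score(cen$A) >= score(single$A) - 0.002) wins <- wins + 1L
  }
  expect_gte(wins, 5L)
})
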