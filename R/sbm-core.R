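#' Remove voxel-wise (column) means
#'
#' Centres each column of the subjects-by-voxels matrix. Row (subject)
#' means are deliberately retained: with columns centred, the
#' subject-space covariance `X Xt / (V - 1)` is the object whose
#' eigenstructure the MDL criterion and the whitening step evaluate.
#'
#' @param X numeric matrix (N subjects x V voxels), N >= 2.
#' @return list with `X_centered` and `column_means`.
#' @export
center_matrix <- function(X) {
  if (nrow(X) < 2L) stop_hippsbm("X must have at least 2 rows", "value_error")
  mu <- colMeans(X)
  list(X_centered = sweep(X, 2L, mu), column_means = mu)
}

subject_cov_eigen <- function(X_centered) {
  V <- ncol(X_centered)
  C <- tcrossprod(X_centered) / (V - 1)
  e <- eigen(C, symmetric = TRUE)
  if (any(!is.finite(e$values)))
    stop_hippsbm("non-finite covariance eigenvalues", "numeric_error")
  e
}

#' MDL model-order selection
#'
#' Chooses the number of retained components by the minimum description
#' length criterion of Wax & Kailath evaluated on the eigenvalues
#' `lambda_1 >= ... >= lambda_N` of the subject-space covariance of the
#' column-centred data:
#' `MDL(k) = -V (N - k) log(g_k / a_k) + k (2N - k) log(V) / 2`,
#' where `g_k` and `a_k` are the geometric and arithmetic means of the
#' trailing eigenvalues `lambda_{k+1} .. lambda_N`, and V is the number of
#' voxels (samples). Returns the `k` in `1..k_max` minimising the
#' criterion; the full MDL curve is attached as attribute `"mdl"`.
#'
#' The criterion assumes the V voxel samples are independent. Smoothed
#' images violate this: every kernel-sized neighbourhood carries roughly
#' one sample's worth of information, and with the raw V the penalty term
#' is overwhelmed, driving the selected order to `k_max`. Passing
#' `effective_samples` (e.g. V divided by the smoothing-kernel volume in
#' voxels, as [run_sbm()] does) replaces V in the criterion with an
#' effective independent-sample count.
#'
#' @param X subjects-by-voxels matrix (centred internally).
#' @param k_max largest order considered; must satisfy
#'   `1 <= k_max < min(N, V)`.
#' @param effective_samples optional effective number of independent
#'   voxel samples used in the criterion; `NULL` (default) uses V, the
#'   correct choice for spatially independent voxels.
#' @return integer order.
#' @export
estimate_order_mdl <- function(X, k_max = min(dim(X)) - 1L,
                               effective_samples = NULL) {
  N <- nrow(X); V <- ncol(X)
  k_max <- as.integer(k_max)
  if (k_max < 1L || k_max >= min(N, V))
    stop_hippsbm("k_max must satisfy 1 <= k_max < min(N, V)", "value_error")
  V_eff <- max(2, effective_samples %||% V)
  lam <- subject_cov_eigen(center_matrix(X)$X_centered)$values
  lam <- pmax(lam, .Machine$double.eps * max(lam))
  mdl <- vapply(seq_len(k_max), function(k) {
    tail_l <- lam[(k + 1L):N]
    log_g <- mean(log(tail_l))
    log_a <- log(mean(tail_l))
    -V_eff * (N - k) * (log_g - log_a) + 0.5 * k * (2 * N - k) * log(V_eff)
  }, numeric(1))
  structure(which.min(mdl), mdl = mdl)
}

#' PCA whitening in subject space
#'
#' Projects the column-centred data onto its top-K subject-space principal
#' directions and rescales them to unit variance, producing the K x V
#' matrix `Z` whose row covariance is the identity. The returned
#' dewhitening matrix maps whitened rows back to subject space;
#' `dewhitening %*% whitening` is the orthogonal projector onto the
#' retained subspace.
#'
#' @param X_centered column-centred N x V matrix.
#' @param K number of components to retain (`K <= rank(X_centered)`).
#' @return list with `Z` (K x V), `whitening` (K x N), `dewhitening`
#'   (N x K) and the covariance `eigenvalues`.
#' @export
pca_whiten <- function(X_centered, K) {
  e <- subject_cov_eigen(X_centered)
  if (K < 1L || K > nrow(X_centered))
    stop_hippsbm("K out of range", "value_error")
  if (e$values[K] <= max(e$values) * 1e-10)
    stop_hippsbm("K exceeds the numerical rank of the data", "rank_error")
  U <- e$vectors[, seq_len(K), drop = FALSE]
  d <- sqrt(e$values[seq_len(K)])
  whitening <- t(U) / d          # rows scaled by 1/sqrt(lambda)
  dewhitening <- U * rep(d, each = nrow(U))
  list(Z = whitening %*% X_centered, whitening = whitening,
       dewhitening = dewhitening, eigenvalues = e$values)
}

random_orthogonal <- function(K) {
  q <- qr.Q(qr(matrix(rnorm(K * K), K)))
  q * sign(diag(q))  # fix reflection signs for reproducibility across BLAS
}

#' Infomax independent component analysis
#'
#' Maximum-information-preservation ICA with the logistic nonlinearity
#' `y = 1 / (1 + exp(-u))`, fitted by stochastic natural-gradient ascent:
#' for each mini-batch `u = W z`,
#' `W <- W + eta * (I + (1 - 2 y) ut / B) W`.
#' Mini-batches are random voxel permutations drawn from the seed; the
#' learning rate starts at `0.01 / max(log(K), 1)` and is halved whenever
#' successive sweep updates turn by more than 60 degrees (oscillation).
#' Iteration stops when the Frobenius norm of a full sweep's update falls
#' below `tol` or after `max_iter` sweeps; non-convergence is recorded in
#' `convergence_info`, not raised. A non-finite update triggers a restart
#' with a halved initial rate, up to three times.
#'
#' The plain (non-extended) logistic score is used: ROI grey-matter
#' sources are sparse spatial maps, i.e. super-Gaussian, which is the
#' regime where this score is consistent.
#'
#' @param Z whitened K x V matrix from [pca_whiten()].
#' @param learning_rate initial step size; `NULL` uses the default.
#' @param max_iter maximum number of sweeps through the data.
#' @param tol convergence tolerance on the per-sweep update norm.
#' @param seed seed for the initial unmixing matrix and batch order.
#' @param W_init optional K x K initial unmixing matrix (overrides the
#'   random initialisation; the batch order still comes from the seed).
#' @return list with `W` (K x K unmixing matrix), `S = W Z`, and
#'   `convergence_info` (iterations, final_update_norm, converged,
#'   restarts).
#' @export
infomax_ica <- function(Z, learning_rate = NULL, max_iter = 512L, tol = 1e-6,
                        seed = 1L, W_init = NULL) {
  K <- nrow(Z); V <- ncol(Z)
  if (K == 1L) {
    return(list(W = matrix(1, 1, 1), S = Z,
                convergence_info = list(iterations = 0L, final_update_norm = 0,
                                        converged = TRUE, restarts = 0L)))
  }
  eta0 <- learning_rate %||% (0.01 / max(log(K), 1))
  batch <- min(ceiling(5 * sqrt(V)), V)
  I_K <- diag(K)
  starts <- seq(1L, V, by = batch)
  for (attempt in 0:3) {
    res <- withr::with_seed(seed, {
      W <- W_init %||% random_orthogonal(K)
      eta <- eta0 / 2^attempt
      dW_prev <- NULL
      nrm <- Inf
      blown <- FALSE
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        perm <- sample.int(V)
        W_old <- W
        for (b in starts) {
          cols <- perm[b:min(b + batch - 1L, V)]
          u <- W %*% Z[, cols, drop = FALSE]
          y <- 1 / (1 + exp(-u))
          W <- W + eta * (I_K + tcrossprod(1 - 2 * y, u) / length(cols)) %*% W
        }
        if (!all(is.finite(W))) { blown <- TRUE; break }
        dW <- W - W_old
        nrm <- sqrt(sum(dW^2))
        if (!is.null(dW_prev)) {
          denom <- sqrt(sum(dW^2) * sum(dW_prev^2))
          if (denom > 0 && sum(dW * dW_prev) / denom < 0.5) eta <- eta / 2
        }
        dW_prev <- dW
        if (nrm < tol) break
      }
      list(W = W, iterations = it, final_update_norm = nrm, blown = blown)
    })
    if (!res$blown) {
      return(list(W = res$W, S = res$W %*% Z,
                  convergence_info = list(iterations = res$iterations,
                                          final_update_norm = res$final_update_norm,
                                          converged = res$final_update_norm < tol,
                                          restarts = attempt)))
    }
  }
  stop_hippsbm("Infomax update diverged repeatedly; reduce the learning rate",
               "numeric_error")
}

#' Back-reconstruct loading coefficients
#'
#' Maps the unmixing solution back to subject space: with `S = W Z` and
#' `Z = whitening X_c`, the loadings satisfy `X_topK = A S` with
#' `A = dewhitening W^-1`. Each source row is then standardised to unit SD
#' with the scale absorbed into the corresponding column of `A`, and each
#' source's sign is fixed so that its largest-magnitude voxel is positive
#' (sign likewise absorbed into `A`).
#'
#' @param X_centered column-centred data matrix (N x V).
#' @param S source matrix from [infomax_ica()] (K x V).
#' @param dewhitening N x K dewhitening matrix from [pca_whiten()].
#' @param W K x K unmixing matrix.
#' @param convergence_info optional convergence record to carry through.
#' @param seed seed recorded on the result.
#' @return an object of class `ica_decomposition`: list with `A` (N x K),
#'   `S` (K x V, unit-SD sign-fixed rows), `K`, `residual` (relative
#'   Frobenius reconstruction error), `convergence_info`, `seed`.
#' @export
back_reconstruct <- function(X_centered, S, dewhitening, W,
                             convergence_info = NULL, seed = NA_integer_) {
  Winv <- tryCatch(solve(W),
                   error = function(e) stop_hippsbm("singular unmixing matrix",
                                                    "numeric_error"))
  A <- dewhitening %*% Winv
  std <- standardize_sources(S, A)
  res <- norm(X_centered - std$A %*% std$S, "F") / norm(X_centered, "F")
  structure(list(A = std$A, S = std$S, K = nrow(S), residual = res,
                 convergence_info = convergence_info, seed = seed),
            class = "ica_decomposition")
}

## Unit-SD rows, sign fixed so the largest-|value| voxel is positive;
## scale and sign absorbed into the loading columns.
standardize_sources <- function(S, A) {
  sds <- apply(S, 1L, sd)
  if (any(sds == 0)) stop_hippsbm("degenerate source with zero variance", "numeric_error")
  signs <- vapply(seq_len(nrow(S)), function(k) {
    v <- S[k, which.max(abs(S[k, ]))]
    if (v < 0) -1 else 1
  }, numeric(1))
  list(S = S * (signs / sds), A = A * rep(sds * signs, each = nrow(A)))
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> K = %d components, %d subjects x %d voxels\n",
              x$K, nrow(x$A), ncol(x$S)))
  cat(sprintf("  relative reconstruction residual: %.4g\n", x$residual))
  if (!is.null(x$convergence_info))
    cat(sprintf("  converged: %s (%d iterations)\n",
                x$convergence_info$converged, x$convergence_info$iterations))
  if (!is.null(x$flagged) && any(x$flagged))
    cat("  flagged unstable:", paste(which(x$flagged), collapse = ", "), "\n")
  invisible(x)
}
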