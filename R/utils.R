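#' @importFrom stats rnorm runif rbinom cor sd var dnorm qnorm pnorm pf pt
#'   lm lm.fit glm manova binomial coef fitted predict chisq.test t.test
#'   anova as.formula model.matrix setNames
#' @importFrom utils write.table read.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Deterministic child seeds from a master seed. Kept strictly below
## .Machine$integer.max so downstream set.seed() calls stay in range.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

stop_hippsbm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hippsbm_error")))
}

#' Maximum-trace assignment between two component sets
#'
#' Finds the one-to-one matching of rows to columns of a similarity matrix
#' (typically absolute correlations between estimated and ground-truth
#' components) that maximises the summed similarity. Exact solution by
#' bitmask dynamic programming, so it is practical for the component counts
#' used in SBM (up to ~20).
#'
#' @param sim square numeric matrix of similarities (larger is better).
#' @return integer vector `p` with `p[i]` the column assigned to row `i`.
#' @examples
#' m <- diag(3)[, c(2, 3, 1)]
#' match_components(m)
#' @export
match_components <- function(sim) {
  k <- nrow(sim)
  if (ncol(sim) != k) stop_hippsbm("similarity matrix must be square", "value_error")
  if (k == 1L) return(1L)
  nmask <- bitwShiftL(1L, k)
  best <- rep(-Inf, nmask)
  choice <- integer(nmask)
  best[1L] <- 0
  for (m in seq_len(nmask) - 1L) {
    if (!is.finite(best[m + 1L])) next
    i <- sum(bitwAnd(bitwShiftR(m, seq_len(k) - 1L), 1L)) + 1L  # next row
    if (i > k) next
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) != 0L) next
      m2 <- bitwOr(m, bit)
      val <- best[m + 1L] + sim[i, j]
      if (val > best[m2 + 1L]) {
        best[m2 + 1L] <- val
        choice[m2 + 1L] <- j
      }
    }
  }
  perm <- integer(k)
  m <- nmask - 1L
  for (i in rev(seq_len(k))) {
    j <- choice[m + 1L]
    perm[i] <- j
    m <- bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  perm
}
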