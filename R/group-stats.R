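#' Compare demographics between groups
#'
#' Welch two-sample t-tests for age and years of education and a Pearson
#' chi-squared test (1 df, no continuity correction) for sex, MDD vs HS.
#'
#' @param table subject data.frame with columns `group` (levels HS, MDD),
#'   `age`, `sex`, `education_years`.
#' @return data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @export
compare_demographics <- function(table) {
  if (any(table(table$group) < 2))
    stop_hippsbm("each group needs at least 2 subjects", "insufficient_data_error")
  g <- table$group
  rows <- lapply(c(age = "age", education_years = "education_years"), function(v) {
    tt <- t.test(table[[v]][g == "MDD"], table[[v]][g == "HS"])
    data.frame(variable = v, test = "Welch t", statistic = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, stringsAsFactors = FALSE)
  })
  ct <- chisq.test(base::table(g, table$sex), correct = FALSE)
  rows$sex <- data.frame(variable = "sex", test = "Pearson chi-squared",
                         statistic = unname(ct$statistic),
                         df = unname(ct$parameter), p = ct$p.value,
                         stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected per-test threshold
#'
#' `family_alpha / n_tests`, exact value (display rounding is up to the
#' caller): 0.05 over 7 components gives 0.00714..., printed as 0.007.
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param family_alpha family-wise error rate, in (0, 1).
#' @return per-test alpha.
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop_hippsbm("n_tests must be >= 1", "value_error")
  if (family_alpha <= 0 || family_alpha >= 1)
    stop_hippsbm("family_alpha must lie in (0, 1)", "value_error")
  family_alpha / n_tests
}

#' Covariate-adjusted group comparison of loading coefficients
#'
#' For every component, fits the linear model
#' `loading ~ group + age + sex + education` by least squares and reports
#' the partial F-statistic of the group term (1 numerator df;
#' `N - 2 - n_covariates` denominator df), its p-value, and partial eta
#' squared `SS_group / (SS_group + SS_error)`. Significance is judged
#' against the Bonferroni-corrected threshold for the component family.
#' An omnibus multivariate test (Wilks' lambda for the group term,
#' covariates entered first) is attached because the per-component F
#' tables are conventionally reported alongside a MANCOVA.
#'
#' @param A N x K loading matrix (columns = components).
#' @param table subject data.frame aligned with the rows of `A`.
#' @param covariates covariate column names (default age, sex, education).
#' @param family_alpha family-wise alpha for the Bonferroni correction.
#' @param wilks compute the omnibus Wilks' lambda (default TRUE).
#' @return data.frame of class `group_stats` with per-component `F`, `p`,
#'   `partial_eta_sq`, `significant`; attributes `bonferroni_alpha` and
#'   (optionally) `wilks`.
#' @export
mancova_loadings <- function(A, table,
                             covariates = c("age", "sex", "education_years"),
                             family_alpha = 0.05, wilks = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != nrow(table))
    stop_hippsbm("loadings and subject table have different lengths", "shape_error")
  K <- ncol(A)
  form <- as.formula(paste("~ group +", paste(covariates, collapse = " + ")))
  mm <- model.matrix(form, data = table)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop_hippsbm(paste0("design matrix is rank deficient; collinear columns: ",
                        paste(bad, collapse = ", ")), "design_error")
  }
  grp_col <- which(colnames(mm) == "groupMDD")
  fit <- lm.fit(mm, A)
  res <- as.matrix(fit$residuals)
  df_err <- n - ncol(mm)
  ## partial F for the group coefficient via its sampling variance
  xtx_inv <- solve(crossprod(mm))
  ss_err <- colSums(res^2)
  se2 <- xtx_inv[grp_col, grp_col] * ss_err / df_err
  bhat <- as.matrix(fit$coefficients)[grp_col, ]
  Fstat <- bhat^2 / se2
  ## perfectly covariate-explained loadings: zero group effect by convention
  tot <- colSums(sweep(A, 2, colMeans(A))^2)
  degen <- ss_err <= 1e-12 * pmax(tot, .Machine$double.eps)
  Fstat[degen] <- 0
  p <- pf(Fstat, 1, df_err, lower.tail = FALSE)
  ss_group <- Fstat * ss_err / df_err
  alpha <- bonferroni_alpha(K, family_alpha)
  eta <- ifelse(degen, 0, ss_group / (ss_group + ss_err))
  out <- data.frame(component = seq_len(K),
                    F = Fstat, df1 = 1, df2 = df_err, p = p,
                    partial_eta_sq = eta,
                    significant = p < alpha)
  rownames(out) <- NULL
  attr(out, "bonferroni_alpha") <- alpha
  if (wilks && K >= 2L && K < df_err) {
    mform <- as.formula(paste("A ~", paste(covariates, collapse = " + "), "+ group"))
    mv <- manova(mform, data = cbind(table, A = I(A)))
    wt <- summary(mv, test = "Wilks")$stats
    attr(out, "wilks") <- list(lambda = wt["group", "Wilks"],
                               approx_F = wt["group", "approx F"],
                               p = wt["group", "Pr(>F)"])
  }
  class(out) <- c("group_stats", class(out))
  out
}

#' Logistic prediction of group from loading coefficients
#'
#' Maximum-likelihood binomial logistic regression of diagnosis (MDD = 1)
#' on the loading coefficients alone - deliberately no demographic
#' predictors, so the classifier uses only image-derived information.
#' Reports per-component odds ratios with Wald 95% confidence intervals.
#'
#' @param A N x K loading matrix.
#' @param table subject data.frame aligned with `A` (uses `group`).
#' @param family_alpha family-wise alpha for the Bonferroni-corrected
#'   significance column.
#' @return object of class `logistic_model`: list with `coefficients`
#'   (data.frame: term, coefficient, se, odds_ratio, ci_low, ci_high, p,
#'   significant), `fitted_probabilities`, `labels` (1 = MDD), `fit`.
#' @export
fit_logistic <- function(A, table, family_alpha = 0.05) {
  A <- as.matrix(A)
  colnames(A) <- paste0("IC", seq_len(ncol(A)))
  y <- as.integer(table$group == "MDD")
  if (length(unique(y)) < 2L)
    stop_hippsbm("outcome must contain both classes", "value_error")
  dat <- data.frame(y = y, A)
  fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
  p_hat <- fitted(fit)
  if (all(abs(y - p_hat) < 1e-6))
    stop_hippsbm(paste("perfect separation: the loadings separate the groups",
                       "exactly; consider a penalized fit"), "separation_error")
  cf <- summary(fit)$coefficients
  all_terms <- c("(Intercept)", colnames(A))
  alpha <- bonferroni_alpha(ncol(A), family_alpha)
  rows <- lapply(all_terms, function(tm) {
    if (tm %in% rownames(cf)) {
      b <- cf[tm, "Estimate"]; se <- cf[tm, "Std. Error"]; pv <- cf[tm, "Pr(>|z|)"]
    } else {                   # aliased (constant) predictor: zero effect
      b <- 0; se <- NA_real_; pv <- NA_real_
    }
    data.frame(term = tm, coefficient = b, se = se,
               odds_ratio = exp(b),
               ci_low = exp(b - qnorm(0.975) * se),
               ci_high = exp(b + qnorm(0.975) * se),
               p = pv,
               significant = !is.na(pv) & tm != "(Intercept)" & pv < alpha,
               stringsAsFactors = FALSE)
  })
  structure(list(coefficients = do.call(rbind, rows),
                 fitted_probabilities = as.numeric(p_hat),
                 labels = y, bonferroni_alpha = alpha, fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> group ~ loading coefficients\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

## AUC by the Mann-Whitney rank statistic; ties count one half.
rank_auc <- function(probabilities, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_hippsbm("need both classes for ROC", "value_error")
  r <- rank(probabilities)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve, AUC and cutoff classification metrics
#'
#' Computes the empirical ROC curve of fitted MDD probabilities, the area
#' under it via the Mann-Whitney rank formulation (ties counted one
#' half), and the confusion-matrix summary at a probability cutoff
#' (default 0.5; ties classify as positive). Sensitivity is
#' `TP / (TP + FN)` with MDD as the positive class, specificity
#' `TN / (TN + FP)`, accuracy `(TP + TN) / N`, all in percent.
#'
#' @param model a `logistic_model`, or a list with elements
#'   `fitted_probabilities` and `labels` (1 = positive).
#' @param cutoff probability cutoff (default 0.5).
#' @return list of class `roc_result`: `roc` (data.frame of fpr, tpr,
#'   threshold), `auc`, `sensitivity`, `specificity`, `accuracy` (%),
#'   `confusion` (2 x 2 table), `cutoff`.
#' @export
roc_and_classify <- function(model, cutoff = 0.5) {
  p <- model$fitted_probabilities
  y <- model$labels
  if (length(unique(y)) < 2L) stop_hippsbm("need both classes for ROC", "value_error")
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  roc <- data.frame(threshold = thr,
                    tpr = vapply(thr, function(t) sum(p >= t & y == 1) / n1, numeric(1)),
                    fpr = vapply(thr, function(t) sum(p >= t & y == 0) / n0, numeric(1)))
  pred <- as.integer(p >= cutoff)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(roc = roc,
                 auc = rank_auc(p, y),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / length(y),
                 confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                                    dimnames = list(predicted = c("MDD", "HS"),
                                                    actual = c("MDD", "HS"))),
                 cutoff = cutoff),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f; at cutoff %.2f: sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' K-fold cross-validated logistic accuracy (extension)
#'
#' The headline classification metrics of the pipeline are apparent
#' (in-sample), matching common SBM practice. This optional helper
#' estimates out-of-sample accuracy by k-fold cross-validation; it is an
#' extension, not part of the standard report.
#'
#' @param A N x K loading matrix.
#' @param table subject data.frame aligned with `A`.
#' @param k number of folds.
#' @param cutoff probability cutoff.
#' @param seed seed for the fold assignment.
#' @return list with `accuracy` (%), `auc`, `fold_assignment`.
#' @export
cv_logistic <- function(A, table, k = 5L, cutoff = 0.5, seed = 1L) {
  A <- as.matrix(A)
  y <- as.integer(table$group == "MDD")
  n <- length(y)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  p_out <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    dat <- data.frame(y = y, A)
    fit <- suppressWarnings(glm(y ~ ., data = dat[tr, ], family = binomial()))
    p_out[!tr] <- predict(fit, newdata = dat[!tr, , drop = FALSE], type = "response")
  }
  list(accuracy = 100 * mean((p_out >= cutoff) == y),
       auc = rank_auc(p_out, y),
       fold_assignment = folds)
}
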