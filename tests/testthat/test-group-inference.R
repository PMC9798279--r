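null_table <- function(n1 = 30L, n2 = 30L, seed = 1L) {
  set.seed(seed)
  data.frame(subject_id = sprintf("s%03d", 1:(n1 + n2)),
             group = factor(rep(c("MDD", "HS"), c(n1, n2)), levels = c("HS", "MDD")),
             age = rnorm(n1 + n2, 45, 12),
             sex = factor(sample(c("M", "F"), n1 + n2, TRUE), levels = c("M", "F")),
             education_years = rnorm(n1 + n2, 15, 3))
}

test_that("demographic tests behave on identical and hand-computed inputs", {
  tab <- null_table()
  tab2 <- tab
  tab2$age <- rep(rnorm(30), 2)           # identical age values per group
  tab2$age[tab2$group == "HS"] <- tab2$age[tab2$group == "MDD"]
  rep_tab <- compare_demographics(tab2)
  age_row <- rep_tab[rep_tab$variable == "age", ]
  expect_equal(age_row$statistic, 0, tolerance = 1e-12)
  expect_equal(age_row$p, 1, tolerance = 1e-12)
  # chi-squared for a (30,20)/(20,30) table: sum (O-E)^2/E = 4
  tab3 <- data.frame(group = factor(rep(c("MDD", "HS"), each = 50),
                                    levels = c("HS", "MDD")),
                     age = rnorm(100), education_years = rnorm(100),
                     sex = factor(c(rep("F", 30), rep("M", 20),
                                    rep("F", 20), rep("M", 30)),
                                  levels = c("M", "F")))
  sex_row <- compare_demographics(tab3)
  sex_row <- sex_row[sex_row$variable == "sex", ]
  expect_equal(sex_row$statistic, 4.0, tolerance = 1e-12)
  expect_error(compare_demographics(tab[1:31, ]), class = "insufficient_data_error")
})

test_that("the planted age confound is detectable at study size", {
  hits <- vapply(1:10, function(s) {
    sl <- make_subjects_and_loadings(synth_config(seed = 700L + s))
    rep_s <- compare_demographics(sl$subjects)
    rep_s$p[rep_s$variable == "age"] < 0.01
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("Bonferroni threshold is the exact division", {
  expect_equal(bonferroni_alpha(7, 0.05), 0.05 / 7, tolerance = 1e-15)
  expect_equal(round(bonferroni_alpha(7, 0.05), 3), 0.007)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(bonferroni_alpha(10, 0.05), 0.005)
  expect_error(bonferroni_alpha(0, 0.05), class = "value_error")
  expect_error(bonferroni_alpha(5, 1.2), class = "value_error")
})

test_that("covariate-adjusted group F matches lm and absorbs covariate effects", {
  tab <- null_table(seed = 5L)
  set.seed(6)
  A <- cbind(rnorm(60) + (tab$group == "MDD") * 0.8, rnorm(60))
  res <- mancova_loadings(A, tab)
  # oracle: textbook lm partial F = squared t of the group coefficient
  for (k in 1:2) {
    fit <- lm(A[, k] ~ group + age + sex + education_years, data = tab)
    tstat <- summary(fit)$coefficients["groupMDD", "t value"]
    expect_equal(res$F[k], tstat^2, tolerance = 1e-10)
    expect_equal(res$df2[k], 60 - 5)
    eta <- res$F[k] / (res$F[k] + res$df2[k])
    expect_equal(res$partial_eta_sq[k], eta, tolerance = 1e-10)
  }
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
  expect_false(is.null(attr(res, "wilks")))
  # loading that is an exact function of age: the covariate absorbs it
  A2 <- cbind(0.3 * tab$age - 1)
  res2 <- mancova_loadings(A2, tab, wilks = FALSE)
  expect_equal(res2$F[1], 0)
  expect_equal(res2$p[1], 1)
})

test_that("rank-deficient designs fail loudly with the collinear column named", {
  tab <- null_table(seed = 8L)
  tab$edu2 <- tab$education_years
  expect_error(
    mancova_loadings(matrix(rnorm(60), 60), tab,
                     covariates = c("age", "education_years", "edu2")),
    "edu2", class = "design_error")
})

test_that("planted loading shifts carry the largest F statistic", {
  # per-seed probability of the planted component winning is ~0.91 at a
  # 0.5 SD shift (measured over 200 replicates); 16/20 is a safe bound
  hits <- vapply(1:20, function(s) {
    sl <- make_subjects_and_loadings(
      synth_config(k_sources = 7L, group_effect = c(0.5, rep(0, 6)),
                   confound_covariates = FALSE, seed = 900L + s))
    res <- mancova_loadings(sl$A_true, sl$subjects, wilks = FALSE)
    which.max(res$F) == 1L
  }, logical(1))
  expect_gte(sum(hits), 16L)
})

test_that("logistic closed forms hold for null and saturated models", {
  tab <- null_table(n1 = 25L, n2 = 35L, seed = 11L)
  # all-zero predictors: aliased terms report OR 1; intercept log(n1/n0)
  m0 <- fit_logistic(matrix(0, 60, 2), tab)
  expect_equal(m0$coefficients$odds_ratio[2:3], c(1, 1))
  expect_equal(m0$coefficients$coefficient[1], log(25 / 35), tolerance = 1e-8)
  # single binary predictor, counts (40,10)/(20,30): OR = cross-product ratio
  tab2 <- data.frame(group = factor(rep(c("MDD", "HS"), each = 50),
                                    levels = c("HS", "MDD")))
  x <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
  m1 <- fit_logistic(matrix(x, ncol = 1), tab2)
  expect_equal(m1$coefficients$odds_ratio[2], (40 * 30) / (10 * 20),
               tolerance = 1e-6)
  expect_equal(m1$coefficients$ci_low[2], exp(m1$coefficients$coefficient[2] -
    qnorm(0.975) * m1$coefficients$se[2]), tolerance = 1e-12)
  # perfect separation is refused
  tab3 <- tab2
  sep <- ifelse(tab3$group == "MDD", 1, -1) * (1 + runif(100))
  expect_error(fit_logistic(matrix(sep, ncol = 1), tab3),
               class = "separation_error")
})

test_that("rank AUC equals brute-force pairs and the trapezoidal ROC area", {
  skip_if_not_installed("pROC")
  brute <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  # printed example: 3 of 4 pairs concordant
  ex <- list(fitted_probabilities = c(0.9, 0.8, 0.85, 0.1), labels = c(1, 1, 0, 0))
  expect_equal(brute(ex$fitted_probabilities, ex$labels), 0.75)
  expect_equal(roc_and_classify(ex)$auc, 0.75)
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    p <- round(runif(n), sample(c(1, 2, 8), 1))   # coarse rounding forces ties
    res <- roc_and_classify(list(fitted_probabilities = p, labels = y))
    expect_equal(res$auc, brute(p, y), tolerance = 1e-12)
    ord <- order(res$roc$fpr, res$roc$tpr)
    trap <- sum(diff(res$roc$fpr[ord]) *
                  (head(res$roc$tpr[ord], -1) + tail(res$roc$tpr[ord], -1)) / 2)
    expect_equal(res$auc, trap, tolerance = 1e-12)
    expect_equal(res$auc, as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<",
                          levels = c(0, 1))))), tolerance = 1e-12)
  }
})

test_that("cutoff classification metrics have their closed forms", {
  mod <- list(fitted_probabilities = c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1),
              labels = c(1, 1, 1, 0, 0, 0))
  r <- roc_and_classify(mod, cutoff = 0.5)
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$accuracy, 100)
  # ties at the cutoff classify as positive
  mod2 <- list(fitted_probabilities = c(0.5, 0.5, 0.2, 0.6), labels = c(1, 0, 0, 1))
  r2 <- roc_and_classify(mod2, cutoff = 0.5)
  expect_equal(r2$sensitivity, 100)        # both positives called
  expect_equal(r2$specificity, 50)         # the tied negative is called positive
  expect_equal(r2$accuracy, 75)
  expect_error(roc_and_classify(list(fitted_probabilities = c(0.5, 0.6),
                                     labels = c(1, 1))), class = "value_error")
})

test_that("permuted labels give chance-level AUC", {
  set.seed(31)
  p <- runif(200)
  aucs <- replicate(200, {
    y <- sample(rep(c(0, 1), each = 100))
    hippsbm:::rank_auc(p, y)
  })
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("cross-validated accuracy is computed and labeled as an extension", {
  sl <- make_subjects_and_loadings(small_synth_config(seed = 77L))
  cv <- cv_logistic(sl$A_true, sl$subjects, k = 4L, seed = 2L)
  expect_true(cv$accuracy >= 0 && cv$accuracy <= 100)
  expect_identical(sort(unique(cv$fold_assignment)), 1:4)
})
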