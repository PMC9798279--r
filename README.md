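# hippsbm

Source-based morphometry (SBM) of structural covariance networks inside a
small region of interest — the bilateral hippocampus sampled at 0.9 mm
isotropic resolution — for researchers studying grey-matter co-variation in
psychiatric and neurological populations.

Conventional voxel-based morphometry treats every voxel separately. SBM
instead decomposes the subjects-by-voxels matrix of modulated grey-matter
values,

    X (N x V)  ≈  A (N x K) · S (K x V),

into K spatially independent **sources** (rows of S, the structural
covariance networks) and per-subject **loading coefficients** (columns of
A, how strongly each subject expresses each network). At 0.9 mm a 3 cc
hippocampus contains about 4115 voxels, enough to resolve networks that a
2 mm functional grid (375 voxels) or 3 mm grid (~111 voxels) cannot.

The pieces, each exposed as its own function:

* **Model order** — K chosen by the minimum description length criterion on
  the eigenvalues of the subject-space covariance (Wax–Kailath form), with
  an optional effective-sample correction for smoothed images.
* **Unmixing** — Infomax ICA (logistic nonlinearity, natural-gradient
  mini-batch updates, annealed learning rate) on PCA-whitened data.
* **Stability** — ICASSO: the ICA is repeated (default 20 times) from
  random initialisations, components are clustered across runs by absolute
  spatial correlation (average linkage), each cluster is scored with the
  quality index Iq and represented by its centrotype; clusters recurring in
  fewer than 16 of 20 runs are flagged unstable.
* **Maps** — sources are z-scaled, thresholded at |z| > 3.0, and reported
  as 26-connected clusters (side, volume in cc, peak |z|, peak mm
  coordinate) with an advisory boundary-fraction artifact flag.
* **Inference** — Welch t / Pearson chi-squared demographics; per-component
  covariate-adjusted group F-tests (age, sex, education) with partial
  eta-squared and Bonferroni control (0.05 / 7 ≈ 0.007); binomial logistic
  regression of diagnosis on the loadings alone with odds ratios, Wald 95%
  CIs, ROC/AUC (Mann–Whitney rank form) and cutoff-0.5 sensitivity /
  specificity / accuracy.
* **Synthetic data** — a seeded generator building a mirror-symmetric
  two-lobe ROI mask, planted bilateral and longitudinal-axis Gaussian-bump
  sources, group-confounded covariates and a group mean shift on selected
  loadings, so the full analysis is testable without clinical data.

## Worked example

A complete synthetic study — 77 + 79 subjects, seven planted sources, a
0.6 SD group shift on two of them — decomposed and analysed end to end:

```r
library(hippsbm)

run <- run_sbm(sbm_config(seed = 7))
print(run)
#> <sbm_run> 156 subjects x 4114 voxels; K = 7 (MDL suggested 7)
#>   ICASSO: cluster sizes 20/20/20/20/20/20/20; Iq 0.99/0.99/0.98/0.98/0.99/0.98/0.98
#>   Bonferroni-significant components: 6
#>   classifier: AUC 0.752, accuracy 73.1%

evaluate_against_truth(run)
#> <sbm_recovery> mean matched spatial |corr| 0.964 (min 0.950)
#>   affected set: planted {5, 6}, detected {6}
#>   AUC achieved 0.752 vs planted-model 0.752

round(run$group_stats[, c("F", "p", "partial_eta_sq")], 4)
#>        F      p partial_eta_sq
#> 1 0.3573 0.5509         0.0024
#> 2 4.1024 0.0446         0.0264
#> 3 0.2050 0.6513         0.0014
#> 4 0.0429 0.8362         0.0003
#> 5 4.5757 0.0340         0.0294
#> 6 9.3153 0.0027         0.0581
#> 7 1.8939 0.1708         0.0124
```

Reading the output: every ICASSO cluster has exactly 20 members with
quality near 1, i.e. all seven components are rock stable across restarts,
and the estimated source maps correlate 0.95–0.97 with the planted ones.
Of the two components carrying the planted 0.6 SD loading shift (estimated
components 5 and 6), only component 6 survives the Bonferroni threshold of
0.05/7 ≈ 0.007 here — at this effect size the covariate-adjusted test has
moderate power, so partial detection is the expected outcome for many
seeds. The in-sample classifier built from the loadings alone reaches an
AUC of 0.75.

`run_sbm(config, output_dir = "...")` additionally writes the demographic,
group-statistics, logistic and ROC tables as TSV, the cluster report, the
ICASSO stability report (JSON), per-component z-maps (NIfTI) and a run
manifest. Real data enter through
`sbm_config(synthetic = NULL, paths = list(volumes = ..., mask = ...,
subjects = ...))` with spatially normalized modulated grey-matter NIfTI
volumes, an ROI mask and a TSV subject table.

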