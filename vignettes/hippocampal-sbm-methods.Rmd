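---
title: "Methods: ROI-restricted source-based morphometry with ICASSO-stabilised Infomax ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROI-restricted source-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Source-based morphometry treats the grey-matter values of N subjects over
V region-of-interest voxels as a linear mixture

$$X \;\approx\; A\,S, \qquad X \in \mathbb{R}^{N\times V},\;
A \in \mathbb{R}^{N\times K},\; S \in \mathbb{R}^{K\times V},$$

where the rows of $S$ are spatially independent sources — structural
covariance networks, sets of voxels whose grey-matter volume co-varies
across subjects — and $A$ holds each subject's loading coefficients on
each network. Group inference is then performed on the columns of $A$,
which turns a massively univariate voxel problem into K scalar tests.

The assumptions behind each stage:

* **Linearity and spatial independence.** The mixture is linear in the
  loadings, and the sources are assumed statistically independent across
  voxels. Real networks are only approximately independent; the ICA
  rotation is therefore identified up to that approximation (see the
  limitations section).
* **Super-Gaussian sources.** The networks are sparse spatial maps —
  most voxels near zero, a minority strongly involved — i.e.
  super-Gaussian. This licenses the plain (non-extended) Infomax score
  (below).
* **Noise.** Whatever is not captured by the K retained principal
  directions is treated as noise and discarded by the PCA step.

## Pipeline stages and their parameters

`run_sbm()` executes, in order: Gaussian smoothing, ROI masking and
stacking, voxel-wise centering, model-order selection, PCA whitening,
ICASSO-stabilised Infomax ICA, component z-maps and cluster reports, and
the group statistics. Defaults (all in `sbm_config()`):

| parameter | default | role |
|---|---|---|
| `fwhm_mm` | 3 mm | smoothing kernel full width at half maximum |
| `k_policy` | `"mdl"` | component count from data (or `"fixed"`) |
| `n_runs` | 20 | ICASSO repetitions |
| `min/max_cluster_size` | 16 / 20 | stability acceptance band |
| `iq_threshold` | 0.8 | minimum cluster quality index |
| `z_threshold` | 3.0 | display threshold on component z-maps |
| `min_report_cc` | 0.1 cc | smallest reported cluster |
| `family_alpha` | 0.05 | family-wise error rate (Bonferroni) |
| `cutoff` | 0.5 | logistic classification cutoff |

A single master `seed` fixes every stochastic stage; stage seeds are
derived from it deterministically, so a seeded run is reproducible down to
the bytes of its output tables.

### Smoothing

Separable Gaussian filtering with $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
per axis, converted to voxel units by each axis's voxel size (3 mm at
0.9 mm voxels gives $\sigma = 1.41553$ voxels). Boundaries use constant
(nearest) extension so that the kernel rows sum to one exactly: a constant
image is unchanged and small-ROI edges are not dimmed. Smoothing runs
*before* masking, mirroring the usual order (smooth the whole map, then
extract the ROI); the order is configurable. Out-of-grid mass is clipped,
so exact mass conservation holds only for signals supported a few
$\sigma$ inside the grid — the property the tests assert.

### Masking and stacking

`apply_mask_and_stack()` places each subject's in-mask voxels into one row
of $X$ using the fixed column-major grid raster (x fastest, then y, then
z). The order is arbitrary but frozen, and the voxel-index map is carried
along so every matrix column can be traced back to a grid coordinate.
Voxel counts follow the floor rule
$\lfloor \mathrm{cc} \cdot 1000 / \mathrm{edge}^3 \rfloor$, which
reproduces all the printed reference counts (4115 at 0.9 mm, 3000 at 1 mm,
375 at 2 mm, 111 at 3 mm for a 3 cc ROI).

### Centering

Voxel (column) means are removed; subject (row) means are retained. With
columns centred, the subject-space covariance $X_cX_c^\top/(V-1)$ is
exactly the object whose eigenstructure the MDL criterion and the
whitening step analyse. Column centering also annihilates the all-ones
subject direction, so the centred matrix has rank at most $N-1$.

### Model-order selection

The Wax–Kailath minimum description length criterion on the subject-space
eigenvalues $\lambda_1 \ge \dots \ge \lambda_N$:

$$\mathrm{MDL}(k) = -V\,(N-k)\,\log\frac{g_k}{a_k}
  + \tfrac12\,k\,(2N-k)\,\log V,$$

with $g_k, a_k$ the geometric and arithmetic means of the trailing
eigenvalues. This assumes the V voxel samples are independent. Smoothed
images violate that assumption badly: each kernel-sized neighbourhood
carries roughly one independent sample, the log-likelihood term is
overweighted by the raw V, and the criterion loses its interior minimum —
on the default synthetic data it simply returns `k_max`. The pipeline
therefore passes an effective sample count
$V_\mathrm{eff} = V / \prod_\mathrm{axes} \max(1, \mathrm{FWHM_{vox}})$
(one sample per kernel volume, the same idea as the i.i.d.-sampling
correction used by the common group-ICA toolboxes). With that correction
the criterion recovers the planted order on the synthetic study.
`estimate_order_mdl()` itself defaults to the uncorrected form, which is
correct for spatially independent voxels and is what the order-selection
tests exercise. On real data the selected order should be read as an
estimate whose exact value depends on this correction; the pipeline also
reports it alongside the stability results, and `k_policy = "fixed"`
bypasses it entirely.

### Whitening

Eigendecomposition of the subject-space covariance; the top-K directions
are scaled to unit variance giving $Z$ (K x V) with identity row
covariance. `K` must not exceed the numerical rank (eigenvalues below
$10^{-10}$ of the largest are treated as zero).

### Infomax ICA

Maximum-information-preservation learning with the logistic nonlinearity
$y = 1/(1+e^{-u})$ and the natural-gradient mini-batch update

$$W \leftarrow W + \eta\,\bigl(I + (1-2y)\,u^\top / B\bigr)\,W .$$

Choices and their reasons:

* **Plain, not extended, Infomax.** The logistic score is consistent for
  super-Gaussian sources, which sparse grey-matter maps are. (It provably
  fails for sub-Gaussian sources — e.g. uniformly distributed ones — which
  is why the separation tests use Laplace sources.)
* **Learning rate** $\eta_0 = 0.01/\max(\log K, 1)$, halved whenever
  successive sweep updates turn by more than 60 degrees (oscillation
  detection), and on a non-finite update the fit restarts with a halved
  initial rate (up to three times) before raising a numeric error.
* **Mini-batches** of $\min(\lceil 5\sqrt{V}\rceil, V)$ voxels in a fresh
  random permutation per sweep, drawn from the run seed.
* **Convergence** when the Frobenius norm of a full sweep's update falls
  below `tol` (default 1e-6) within `max_iter` (512) sweeps;
  non-convergence is recorded, not raised, so ICASSO can still cluster the
  run.
* **Initialisation** is a seeded random orthogonal matrix (RandInit). The
  sign of each Q-R reflection is fixed so results do not depend on the
  BLAS/LAPACK build.

Back-reconstruction recovers $A = \mathrm{dewhiten}\cdot W^{-1}$, then
standardises every source row to unit SD and fixes its sign so the
largest-magnitude voxel is positive, absorbing both into the loading
columns. The scale/sign conventions are arbitrary; freezing them makes
tables reproducible.

### ICASSO stability

ICA is rerun `n_runs` times from fresh random initialisations on the same
data. All $R\cdot K$ estimated sources are compared by absolute spatial
correlation; average-linkage agglomeration on $1-|\rho|$ cut at K clusters
groups re-occurring components. Each cluster is scored by
$I_q = \overline{|\rho|}_\mathrm{within} - \overline{|\rho|}_\mathrm{between}$
and represented by its **centrotype** (the member with the largest summed
within-cluster similarity) — not the cluster mean, which would blur maps.
With R runs an ideally stable component recurs exactly R times, so the
cluster-size band [16, 20] at the default 20 runs is read as a stability
acceptance rule: a cluster smaller than 16 means the component was missed
in some runs; one larger than 20 means distinct components merged.
Components failing the band or the `iq_threshold` are *flagged, never
silently dropped*; exclusion from the group statistics is an explicit
configuration choice (`exclude_flagged`). Loadings for the centrotypes are
re-estimated by least squares against the centred data.

### Component maps

Sources are z-scaled over the in-mask voxels and thresholded at
|z| > 3.0. Suprathreshold voxels are grouped by 26-connectivity
(SPM-style; positive and negative voxels separately, so an adjacent
positive and negative cluster are never merged), clusters below 0.1 cc are
omitted from the report, and each cluster carries its side (peak x
relative to the x = 0 midline of the centred grid), volume in cc, extreme
z and peak coordinate in the grid's mm frame. No stereotaxic conversion is
attempted — coordinates are native-grid mm.

The artifact rule operationalises what is otherwise a visual judgment
("sharp edges at the boundary"): the fraction of suprathreshold voxels
lying within one voxel of the mask boundary. Strictly exceeding
`edge_fraction` (default 0.5) flags the component. The flag is advisory: a
genuinely peripheral network would trip it too, so the decision to exclude
stays with the analyst.

### Group statistics

* Demographics: Welch two-sample t for age and education (no
  equal-variance assumption, since none is warranted), Pearson chi-squared
  without continuity correction for sex.
* Per component, the loading is regressed on group plus age, sex and
  education; the group term's partial F (1, N-5 df), p-value and partial
  $\eta^2 = SS_\mathrm{group}/(SS_\mathrm{group}+SS_\mathrm{error})$ are
  reported, with significance at the Bonferroni threshold
  `family_alpha / K` kept at full precision (0.05/7 = 0.00714...,
  displayed as 0.007). An omnibus Wilks' $\Lambda$ for the group term
  (covariates entered first) accompanies the per-component table, since
  the per-component Fs are what is conventionally printed but the design
  is multivariate.
* The classifier is a maximum-likelihood binomial logistic regression of
  diagnosis on *all* loadings and nothing else — deliberately no
  demographic predictors, so prediction rests on image information alone.
  Loadings enter unstandardised; odds ratios are per unit loading, with
  Wald 95% intervals. Perfect separation raises an error rather than
  reporting divergent estimates. Sex is coded F = 1, M = 0 where it
  appears as a covariate.
* ROC/AUC uses the Mann–Whitney rank formulation with ties counted one
  half (equal to trapezoidal integration of the empirical curve, which the
  tests verify); the confusion matrix at the 0.5 cutoff classifies ties as
  positive. All headline classification metrics are apparent (in-sample),
  matching field practice for this design; `cv_logistic()` offers k-fold
  cross-validation as a clearly-labelled extension.

## The synthetic-data generator

`synth_config()` defaults encode the reference study design:

* 77 + 79 subjects; age truncated-normal 52.0 (SD 15.1, range 22-73) vs
  38.9 (SD 10.2, range 20-65); education 13.4 (2.5) vs 16.7 (3.0); female
  probability 44/77 vs 34/79; a severity score for the patient group only
  (22.6 ± 5.9, floor 14). Covariate confounding with group is **on** by
  default, so the covariate adjustment in the group tests is genuinely
  exercised.
* A mirror-symmetric pair of curved ellipsoidal lobes, total 3 cc at
  0.9 mm (4114 voxels; each lobe keeps exactly the floor(target/2)
  best-fitting voxels of the implicit lobe shape, so the count is
  calibrated, not approximate).
* Seven planted sources: four homotopic bilateral Gaussian-bump pairs
  spaced along the lobe axis plus three two-bump sources along a single
  lobe's long axis — the two shape families the method is meant to
  distinguish. Bumps are isotropic Gaussians (SD = radius/2) truncated at
  the mask and standardised; the layout keeps pairwise |correlation|
  below 0.3.
* Loadings are standard normal, columns standardised to unit variance,
  then a group mean shift is added to the patient rows of the affected
  components — by default 0.6 SD on the first two (bilateral) sources,
  mirroring a design with two discriminative bilateral networks. The
  real-data loading variance and voxel noise level are unknown, so
  `noise_sd = 0.25` was chosen once for reliable recoverability (matched
  spatial correlations around 0.95 at full scale) rather than realism.
* Noise is i.i.d. Gaussian per voxel; `noise_smooth_fwhm_mm` optionally
  smooths the noise field (real modulated grey-matter noise is smooth)
  and rescales it back to `noise_sd`.

What the generator does **not** emulate: scanner physics, intensity
inhomogeneity, registration/normalisation error, the true spatial
autocorrelation structure of modulated grey matter, non-Gaussian loading
distributions, and any dependence of loadings on covariates. Passing tests
therefore demonstrate that the estimation machinery recovers what it
assumes — linear mixtures of sparse, near-independent sources — not that
it is robust to every failure mode of real data.

## Numerical choices

* Degenerate inputs: zero-variance sources raise errors at z-scaling; a
  loading that is an exact linear function of a covariate yields group
  F = 0 / p = 1 by convention (the residual is numerically zero, so the
  ratio is defined by its limit).
* Whitening rank tolerance $10^{-10}$ relative; reconstruction residuals
  are reported as relative Frobenius norms.
* Eigenvalues are floored at machine precision before logs in the MDL
  criterion.
* Component matching in the recovery report is an exact
  maximum-assignment over absolute correlations (bitmask dynamic
  programming), so recovery scores are invariant to permutation and sign
  of the planted truth.
* Ties: probability ties at the classification cutoff go to the positive
  class; rank ties in the AUC count one half.
* ICASSO cluster-size defaults follow `ceiling(0.8 * n_runs)` and
  `n_runs`, giving the canonical [16, 20] at 20 runs.

## Problem sizes used by the test-suite

Unit tests run on a reduced ROI (0.8 cc at 1 mm, 800 voxels, 62 subjects,
3 sources) chosen to keep the full suite fast while preserving every
geometric property (two lobes, bilateral/longitudinal sources, boundary
shell). Full study scale — 156 subjects, ~4114 voxels, K = 7, 20 ICASSO
runs — is exercised by the acceptance tests (10 master seeds) and by
`scripts/acceptance.R`. The type-I-error check uses 1000 simulated null
datasets at full subject count.

## Known limitations

* ICA identifies sources only up to the independence approximation: when
  planted (or real) networks overlap, matched correlations saturate below
  1 even in the noise-free, exactly-factorised regime.
* With all runs converging, the ICASSO centrotype coincides with the
  common solution, so stabilisation mainly protects against occasional
  non-convergence rather than improving the typical run.
* At a 0.6 SD loading shift with confounded covariates, the per-component
  power of the adjusted group test at the Bonferroni threshold is modest
  (~0.6); detecting *exactly* the affected set in a single study is
  therefore the exception, not the rule — the worked example in the
  README shows a typical partial detection.
* The MDL order on smoothed real data depends on the effective-sample
  correction; treat it as a starting point and check stability flags.
* Coordinates are native-grid mm; anatomical labelling of components is
  out of scope and remains a human task.
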