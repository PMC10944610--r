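---
title: "Functional principal component regression for intensive longitudinal data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional principal component regression for intensive longitudinal data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpcreg)
```

## The problem

Mobile health devices produce *intensive longitudinal data* (ILD): daily or
near-daily self-measurements — blood glucose from a glucometer, weight,
activity — that are irregular, noisy and incomplete. A clinical outcome such
as HbA1c is measured once, at a follow-up visit. The scientific questions are
(i) how the whole trajectory of the longitudinal predictor relates to the
scalar outcome, (ii) how well the outcome can be predicted from the preceding
window of measurements, and (iii) what each subject's underlying smooth
trajectory looks like.

`fpcreg` answers these with the two-stage functional principal component
regression (FPCR). The scalar-on-function model is

$$Y_i = \alpha + \int X_i(t)\,\beta(t)\,dt + \epsilon_i,
  \qquad \epsilon_i \sim N(0, \sigma^2),$$

where $X_i(t)$ is subject $i$'s latent smooth predictor trajectory over the
observation window (by default the 91 days $t = -90, \dots, 0$ preceding the
outcome date) and $\beta(t)$ is the time-varying coefficient function — the
weight that a measurement at day $t$ carries for the outcome.

## Stage 1: sparse functional PCA

Each subject is observed on a sparse, irregular subset of days, with
measurement error:
$y_{ij} = X_i(t_{ij}) + e_{ij}$, $e_{ij} \sim N(0, \sigma_x^2)$.
The Karhunen–Loève expansion approximates the centered trajectory by a small
number of orthonormal eigenfunctions of the covariance function
$G(s,t) = \mathrm{Cov}\{X(s), X(t)\}$:

$$X_i(t) - \mu(t) \approx \sum_{j=1}^{p} \zeta_{ij}\,\upsilon_j(t),
  \qquad \zeta_{ij} \sim N(0, \lambda_j) \ \text{independent}.$$

The estimation recipe is the standard one for sparse designs:

1. **Mean.** $\hat\mu(t)$ is a penalized cubic B-spline fit to the pooled
   scatter of all observations (35 equally spaced interior knots,
   second-order difference penalty, smoothing parameter by GCV over a
   log-spaced grid). A `pointwise` mode (per-day cross-sectional means,
   interior gaps linearly interpolated) is available for dense data and for
   exact oracle comparisons.
2. **Covariance.** Off-diagonal raw cross-products
   $(y_{ij} - \hat\mu)(y_{ik} - \hat\mu)$, $j \neq k$, are unbiased for
   $G(t_{ij}, t_{ik})$; same-day products are inflated by $\sigma_x^2$ and
   are excluded. Because times are daily indices, the products are binned
   exactly onto the $91 \times 91$ grid and the binned means are smoothed by
   a tensor-product penalized B-spline (35 knots per margin, one shared
   smoothing parameter, second-order penalties). $\hat\sigma_x^2$ is the
   average gap between the smoothed raw diagonal and the fitted surface
   diagonal over the middle 60% of the window (boundary days are excluded
   because spline fits are least stable there), floored at zero.
3. **Eigenanalysis.** With $W$ the diagonal trapezoid quadrature weights, the
   symmetric problem $W^{1/2} \hat G W^{1/2}$ is eigendecomposed and
   eigenvectors mapped back by $W^{-1/2}$, giving functions orthonormal in
   the quadrature inner product. Eigenvalues below $10^{-10}\hat\lambda_1$
   are discarded (truncation, not shifting, so orthonormality is exact).
   $p$ is the smallest number of components whose cumulative eigenvalue
   share reaches the `pve` threshold (default 0.95).
4. **Scores.** $\hat\zeta_i = \hat\Lambda \Phi_i^\top (\Phi_i \hat\Lambda
   \Phi_i^\top + \hat\sigma_x^2 I)^{-1} y_i$, the conditional expectation
   under joint normality, with $\Phi_i$ the eigenfunctions at subject $i$'s
   observation times (linear interpolation off the grid — negligible for
   daily data). The conditional covariance
   $\hat\Lambda - \hat\Lambda\Phi_i^\top(\cdot)^{-1}\Phi_i\hat\Lambda$ feeds
   the pointwise 95% bands of the recovered trajectories
   $\hat X_i = \hat\mu + \sum_j \hat\zeta_{ij}\hat\upsilon_j$. A
   `projection` mode (quadrature projection of the centered data) is exact
   for dense complete data and serves as the oracle route in the tests.

## Stage 2: regression on scores

Expanding $\beta(t) = \sum_j \beta_j \upsilon_j(t)$ in the same basis reduces
the functional model to ordinary least squares on the score matrix,

$$Y_i = \alpha + \sum_{j=1}^p \hat\zeta_{ij}\beta_j + \epsilon_i,$$

fit with `stats::lm`. The coefficient function is reconstructed as
$\hat\beta(t) = \sum_j \hat\beta_j \hat\upsilon_j(t)$ with pointwise standard
errors $\sqrt{\upsilon(t)^\top \widehat{\mathrm{Cov}}(\hat\beta)\,
\upsilon(t)}$. The band conditions on the estimated eigenfunctions — the
usual two-stage convention; stage-1 uncertainty is not propagated. Model fit
is summarized by $R^2$, adjusted $R^2$ and the overall F-test; predictive
performance by leave-one-subject-out cross-validation (MSE and Spearman's
rank correlation, average ranks on ties). No multiplicity adjustment is
applied anywhere: there is a single model and a single test.

### Cross-validation refit scope

The default `refit = "full"` re-estimates mean, covariance, eigenbasis and
regression on every fold, so nothing about the held-out subject leaks into
its prediction; the truncation order is fixed at the full-data choice so all
folds share the model dimension. `refit = "scores_only"` freezes the fPCA
stage and refits only the score regression — it is exactly leave-one-out OLS
on the score matrix, which makes it both fast and a convenient oracle target.

## Tunable parameters

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| window, grid | days −90..0 | days relative to outcome | "preceding 3 months" fixed to 91 calendar days; day 0 (the outcome date) is included — the data carry no evidence either way, so the inclusive convention is used and documented |
| `knots` | 35 | interior knots per margin | reference setting for penalized-spline covariance smoothing of daily data |
| `pve` | 0.95 | proportion | standard truncation threshold; applied to the smoothed (not raw) eigenvalue mass |
| `dedup` policy | `"first"` | — | "duplicates removed" leaves the survivor unstated; keeping the first input record is closest to removal, `"mean"` offered as a robust alternative |
| score method | `"ce"` | — | conditional expectation is the standard sparse-data estimator; `"projection"` for dense data |
| GCV gamma | 1.4 | — | see numerical choices |

## Numerical choices

* **Quadrature.** Trapezoid rule; exact for piecewise-linear integrands, and
  $\sum w = 90$ (the window width) on the default grid.
* **Eigenfunction signs.** Each $\hat\upsilon_j$ is flipped so
  $\int \hat\upsilon_j\,dt \ge 0$; if that integral is within $10^{-10}$ of
  zero the value at day 0 is made nonnegative. Deterministic output across
  platforms.
* **GCV with EDF inflation (gamma = 1.4).** Binned cross-products are
  heavily correlated within subject; plain GCV, derived under independent
  errors, responds by undersmoothing, which lets spurious wiggly components
  into the eigensystem. Inflating the effective degrees of freedom in the
  GCV denominator is the standard guard.
* **Flat-curve tie-break (2-D fit only).** At realistic noise levels the GCV
  curve of the covariance fit can be flat to within 1% across the whole
  lambda grid — the argmin is then arbitrary. Among candidates within 1% of
  the minimum the largest lambda is taken (the one-standard-error idea).
  Genuine covariance structure makes GCV rise steeply when oversmoothed, so
  the rule only acts on flat curves. The 1-D mean fit has far better
  signal-to-noise and uses the plain GCV minimum.
* **Ridge stabilization.** The normal-equations matrix receives a relative
  ridge of $10^{-8}$ (it can be singular when few cells are populated), and
  a per-subject score system that is numerically singular (e.g.
  $\sigma_x^2 = 0$ with dense data) is ridge-stabilized with a warning.
* **Degenerate inputs.** Constant outcomes give $R^2 = 0$ by convention;
  zero rank variance makes Spearman's correlation `NaN` with a warning;
  double centering is an error; a subject with no observations is an error
  at scoring (it should have been excluded by eligibility).

## The synthetic study generator

`simulate_study()` draws studies with known ground truth from the model
above: scores $\zeta_{ij} \sim N(0, \lambda_j)$ on a quadrature-orthonormal
basis (`orthonormal_basis()`: Gram–Schmidt polynomials or Fourier modes),
Gaussian measurement noise, per-day independent Bernoulli observation (a
fixed-count alternative is available), and outcomes
$Y_i = \alpha + \sum_j \zeta_{ij}\beta_j + N(0,\sigma^2)$. Subjects are
generated sequentially from one seeded stream with a fixed per-subject draw
order, so the first $k$ subjects are identical whatever $n$ is — stable
fixtures for tests.

`default_study_config()` emulates the glucose-to-HbA1c design: $n = 46$
subjects, 91-day window, observation probability 0.5 per day (median ≈ 46 of
91 days observed, ≈ 54% missing), two components with score variances
$(\lambda_1, \lambda_2) = (400, 50)$ on the mg/dL scale, measurement noise
SD 5, a gently varying glucose-like mean, $\alpha = 7.5$ on the HbA1c (%)
scale, component coefficients $(\beta_1, \beta_2) = (0.035, 0.02)$ — a
slightly increasing $\beta(t)$ — and outcome noise SD 0.6. The implied
population $R^2$ is
$\sum_j \beta_j^2\lambda_j / (\sum_j \beta_j^2\lambda_j + \sigma^2)
 = 0.51/0.87 \approx 0.586$. The eigenvalue and noise scales are a plausible
invention for a self-monitoring cohort, chosen once for the package's tests
and demonstrations; they are not a reconstruction of any particular dataset.

What the generator deliberately does **not** emulate: meal-label structure
beyond a single label, within-day (circadian) variation, informative
(outcome-dependent) missingness, skewed or heteroscedastic measurement
error, and drift in measurement adherence over time. Passing tests therefore
demonstrate correctness of the estimators under the stated generative model,
not robustness to those real-data features.

### Problem sizes used by the test suite

Oracle-equivalence checks run at $n = 100$ dense subjects; parameter-recovery
properties average 20 seeds at $n = 300$ with ~50% missingness;
theoretical-$R^2$ consistency uses $n = 2000$ dense; band coverage uses
$n = 200$. These sizes give stable Monte-Carlo summaries while keeping the
suite quick to run.

## Design decisions in open territory

* The estimation recipe (smoothed mean → smoothed off-diagonal covariance →
  discretized eigenproblem → conditional-expectation scores) is the
  published standard for sparse fPCA; alternatives (local-linear surface
  smoothing, REML-based covariance estimation) were out of scope.
* Whether centering should use a smoothed or raw mean is not settled;
  both estimators are exposed (`mean_method`), smoothed by default.
* The PVE threshold is applied to the smoothed eigenvalue mass (the raw
  cross-products do not define a proper eigensystem).
* LOSO-CV could in principle re-select $p$ per fold; the package fixes $p$
  at the full-data choice to keep folds comparable in dimension, and this is
  the only information that crosses fold boundaries in `refit = "full"`.
* The window endpoint convention (91 days, day 0 inclusive) and the
  outcome tie-break (record closest to a supplied anchor date, later on
  ties) are documented defaults rather than claims about any source study.

## Known limitations

* A low-variance component whose eigenfunction lies outside the
  second-difference penalty null space (e.g. a fast Fourier mode with
  $\lambda_2 = 50$ under measurement noise SD 5 and ~46 observations per
  subject) sits at the edge of detectability: any prediction-error-based
  smoothing selector will shrink it. More data per subject or a larger
  eigengap resolves this.
* Eigenvalue estimates from cross-products inherit substantial sampling
  variability (the per-seed relative error of $\hat\lambda_2$ at $n = 300$
  is of order 20% even though its bias is a few percent); downstream,
  score-shrinkage calibration and hence individual $\hat\beta_j$ inherit
  that variability.
* Confidence bands (trajectories and coefficient function) condition on the
  estimated eigensystem; their coverage is honest for the score and
  regression uncertainty only.
* One functional predictor, Gaussian scalar outcome, no extra covariates:
  multivariate fPCA, generalized outcomes and joint longitudinal-outcome
  models are out of scope.
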