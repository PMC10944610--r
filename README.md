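# fpcreg

Functional principal component regression (FPCR) for intensive longitudinal
data: relate a scalar health outcome to a sparsely, irregularly observed
longitudinal predictor, recover each subject's smooth trajectory, and
reconstruct the time-varying association.

## Who this is for

Analysts of mobile-health and self-monitoring studies: a cohort measures
something daily-ish over a window (e.g. blood glucose before breakfast over
the 3 months preceding an HbA1c lab draw), every subject misses many days,
and the outcome is one number per subject. Summarizing the trajectory by its
average throws away the time course; fitting 91 correlated daily values in a
regression is singular. FPCR reduces each trajectory to a few functional
principal component scores and regresses the outcome on those.

## The model

The scalar-on-function regression is

    Y_i = alpha + ∫ X_i(t) beta(t) dt + eps_i,     eps_i ~ N(0, sigma^2)

with `X_i(t)` the latent smooth predictor trajectory on the window
(default: days −90..0, day 0 = outcome date) and `beta(t)` the coefficient
function. Estimation is two-stage:

1. **Sparse fPCA.** The Karhunen–Loève expansion
   `X_i(t) ≈ mu(t) + Σ_j zeta_ij upsilon_j(t)` is estimated from all
   subjects jointly: penalized-spline mean, tensor-product penalized-spline
   smoothing of pooled off-diagonal cross-products for the covariance
   surface (35 knots per margin, GCV), measurement-error variance from the
   diagonal gap, discretized eigenproblem under trapezoid quadrature, and
   conditional-expectation (shrinkage) scores. The number of components `p`
   is the smallest explaining ≥ 95% of variance.
2. **Score regression.** OLS of `Y` on the scores gives `alpha` and
   `beta_j`; the coefficient function is rebuilt as
   `beta(t) = Σ_j beta_j upsilon_j(t)` with pointwise confidence bands.

Prediction quality is assessed by leave-one-subject-out cross-validation
(MSE and Spearman's rank correlation), with full per-fold refits by default.

## Worked example

The package bundles a synthetic study generator emulating the
glucose-to-HbA1c design (46 subjects, 91-day window, ~50% of days observed,
two dominant components, known ground truth), so the full workflow runs
without any data download:

```r
library(fpcreg)

study <- simulate_study(default_study_config(n = 46, seed = 1))
study$data
#> fpcr_data: 46 subjects, 2077 observations
#>   enrolled 46; excluded: no_outcome=0, no_predictor=0

fit <- fpcr(study$data)            # sparse fPCA + score regression
summary(fit)
#> Functional principal component regression
#>   n = 46 subjects, p = 2 component(s) (pve 1.0000)
#>   alpha = 7.434; beta = 0.03638, 0.06767
#>   R2 = 0.6176, adjusted R2 = 0.5998, F-test p = 1.06e-09
#>
#> Coefficients:
#>              Estimate Std. Error t value  Pr(>|t|)
#> (Intercept) 7.4344419  0.0915373 81.2176 < 2.2e-16 ***
#> pc1         0.0363821  0.0052488  6.9316 1.617e-08 ***
#> pc2         0.0676664  0.0166842  4.0557 0.0002064 ***

cv <- loso_cv(study$data, refit = "full")
cv
#> Leave-one-subject-out CV (full refit, p = 2)
#>   folds = 46
#>   MSE = 0.4105, Spearman rho = 0.7569
```

Reading the output: two components explain essentially all trajectory
variance; the outcome regression recovers the generating intercept 7.5 and
first component weight 0.035 within their standard errors, and an adjusted
R² of 0.60 against the preset's theoretical R² of 0.586. Held-out
predictions correlate strongly with the actual outcomes (rho = 0.76).

```r
cf <- coefficient_function(fit)    # beta(t) with a 95% pointwise band
head(cf, 3)
#>   time        value          se       lower         upper
#> 1  -90 -0.006775506 0.003019387 -0.01269340 -0.0008576156
#> 2  -89 -0.006167782 0.002857346 -0.01176808 -0.0005674864
#> 3  -88 -0.005757158 0.002748060 -0.01114326 -0.0003710595

plot(fit)                          # coefficient function with band
plot(fit$fpca, "scree")            # variance explained per component
plot(fit$fpca, "trajectories")     # recovered curves over observed points
plot(cv)                           # predicted vs actual with 45-degree line
```

`beta(t)` rises toward day 0: recent measurements carry more weight for the
outcome, matching how the generator was configured.

For real data, start from delimited text instead:

```r
ds  <- read_ild("glucose.csv")                     # subject_id, time, value[, label]
ds  <- filter_label(ds, "before-breakfast")
ds  <- dedup_daily(ds, "first")
out <- read_outcomes("hba1c.csv")                  # subject_id, outcome[, outcome_date]
ds  <- align_window(ds, out, window_length_days = 91)
ads <- analysis_dataset(ds, out)                   # eligibility + pairing
fit <- fpcr(ads)
```

`run_simulate()`, `run_analyze()` and `run_report()` (or the
`inst/cli/fpcreg-cli.R` script) drive the same workflow from YAML
configuration files and write all canonical tables, JSON reports and a
hash-verified manifest.

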