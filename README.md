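# gwgpr

Count regression for spatially indexed data with over- or underdispersion:
global Poisson and generalized Poisson regression, and **geographically
weighted generalized Poisson regression (GWGPR)**, in which the regression
coefficients and the dispersion parameter are re-estimated at every
observation location with distance-decaying kernel weights.

## Who this is for

Analysts modelling areal counts of rare events — disease or mortality
counts per district, accidents per zone — where (a) the counts are not
equidispersed, so a Poisson model understates or overstates uncertainty,
and (b) covariate effects plausibly differ across the map, so one global
coefficient vector misrepresents every location.

## The models

With counts `y_i`, predictors `x_i`, and planar coordinates `(u_i, v_i)`:

* **Poisson**: `y_i ~ Poisson(mu_i)`, `log mu_i = x_i' beta`, fitted by
  Newton–Raphson maximum likelihood.
* **GPR** (generalized Poisson): density
  `f(y; mu, phi) = (mu/(1+phi mu))^y (1+phi y)^(y-1)/y! exp(-mu(1+phi y)/(1+phi mu))`
  with `Var(y) = mu (1 + phi mu)^2`; `phi = 0` recovers the Poisson,
  `phi > 0` models overdispersion. `beta` by Newton–Raphson, `phi` by the
  Pearson moment condition (default) or profile Newton.
* **GWGPR**: at each location `i`, maximise the kernel-weighted local
  log-likelihood `sum_j w_ij log f(y_j; exp(x_j' beta_i), phi_i)`, where
  `w_ij` is a compact-support kernel (fixed bisquare, fixed tricube, or
  adaptive bisquare) of the Euclidean distance `d_ij`, with bandwidth
  selected by leave-one-out cross-validation
  `CV(h) = sum_i (y_i - yhat_{-i}(h))^2`.

Inference: likelihood-ratio (deviance) tests against `chi^2_k` for the
slopes jointly, Wald `Z = beta_p / se_p` per parameter (per location for
GWGPR), a Breusch–Pagan test for spatial heterogeneity, dispersion-ratio
classification, VIF screening, and AIC (`-2 lnL + 2p`) to compare the
three models. Locations are grouped by identical sets of significant
predictors.

## Worked example

Generate a synthetic two-regime dataset (200 grid locations, `beta_1` is
+0.5 on the west half and -0.5 on the east, dispersion `phi = 0.3`), then
climb the model ladder:

```r
library(gwgpr)
g  <- generate_scenario(preset("heterogeneous_step"))
ds <- g$dataset

d <- diagnose(ds)
print(d$dispersion)
#> Dispersion (deviance): statistic 948.6884 / df 197 = 4.8157 -> overdispersed
print(d$bp)
#> Breusch-Pagan test: BP = 32.2907 on 2 df, p = 9.731e-08 (critical 5.991)
#>   -> variance differs between locations
```

The counts are overdispersed (ratio 4.8 > 1) and spatially heterogeneous
(BP rejects), so both GPR and a local model are indicated:

```r
gpr <- fit_gpr(ds)
#> phi: 0.39204 (se 0.04763)   Pearson/df: 1.0000
#> Deviance (vs intercept-only GPR): 7.6074   logLik: -484.8676   AIC: 977.7352

gw <- fit_gwgpr(ds, kernel_spec("fixed_bisquare", 0.3))
print(gw)
#> Kernel: fixed_bisquare, bandwidth h = 0.3
#> n = 200 locations, k = 2 predictors; 199/200 local fits converged
#> Local coefficient summaries (min / median / max):
#>                   0%     50%    100%
#> (Intercept)  0.56830 1.17412 1.94005
#> x1          -1.61372 0.16360 1.29210
#> x2          -0.31923 0.26804 1.24242
#> phi range: [0.0575, 0.7479]
#> Deviance: 113.0971   logLik: -432.1228   AIC: 872.2456
```

The global GPR averages the two `x1` regimes away (estimate -0.036, not
significant); the local fits spread from -1.6 to +1.3, recovering the sign
of the true surface at 95% of locations. The AIC ladder ranks the models:

```r
#> AIC: Poisson 1450.33   GPR 977.74   GWGPR 872.25
```

`run_pipeline(ds)` chains all of the above — diagnostics, both global
fits, CV bandwidth search over the three kernels, GWGPR with the best
kernel, tests and significance grouping — into one report object, and
`inst/cli/gwgpr-cli.R` exposes the same steps as shell subcommands
(`simulate`, `diagnose`, `fit-poisson`, `fit-gpr`, `select-bandwidth`,
`fit-gwgpr`, `compare`).

## Package layout

* `R/dataset.R` — `spatial_count_dataset`, CSV I/O, distance matrices
* `R/diagnostics.R` — VIF, KS vs Poisson, Breusch–Pagan, dispersion ratio
* `R/poisson.R` — Poisson Newton–Raphson MLE, deviance and Wald tests
* `R/gpr.R` — generalized Poisson likelihood machinery and global GPR
* `R/weights.R` — kernels, weight matrices, CV bandwidth selection
* `R/gwgpr.R` — local fits, GWGPR, partial tests, significance groups, AIC
* `R/synthetic.R` — generalized Poisson sampler, scenario generator, presets
* `R/pipeline.R` — `run_pipeline()` and report assembly
* `vignettes/gwgpr-methods.Rmd` — models, estimation details, numerical
  safeguards and design rationale
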