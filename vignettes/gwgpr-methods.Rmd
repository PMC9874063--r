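---
title: "Geographically weighted generalized Poisson regression: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographically weighted generalized Poisson regression: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgpr)
```

## The problem

District-level counts of rare health events — the motivating case is
postpartum maternal deaths across the districts of a province — typically
violate the two assumptions that make a global Poisson regression adequate:
the variance of the counts exceeds (or falls short of) the mean, and the
effect of a covariate is not the same everywhere in the study region. This
package fits a ladder of three count models of increasing flexibility and
compares them by AIC:

1. **Poisson regression**: $y_i \sim \mathrm{Poisson}(\mu_i)$ with
   $\log \mu_i = \mathbf{x}_i^\top\boldsymbol\beta$.
2. **Generalized Poisson regression (GPR)**: the generalized Poisson
   density
   $$f(y;\mu,\varphi) = \left(\frac{\mu}{1+\varphi\mu}\right)^{y}
     \frac{(1+\varphi y)^{y-1}}{y!}
     \exp\!\left(-\frac{\mu(1+\varphi y)}{1+\varphi\mu}\right),$$
   which has mean $\mu$ and variance $\mu(1+\varphi\mu)^2$. The dispersion
   $\varphi = 0$ recovers the Poisson; $\varphi > 0$ models
   overdispersion, $\varphi < 0$ underdispersion on a truncated support.
3. **GWGPR**: the same density, but with $\boldsymbol\beta$ and $\varphi$
   re-estimated at every location $(u_i, v_i)$ by maximising a
   kernel-weighted local log-likelihood
   $$\ell_i(\boldsymbol\beta,\varphi) =
     \sum_j w_{ij}\,\log f\big(y_j;\exp(\mathbf{x}_j^\top\boldsymbol\beta),
     \varphi\big),$$
   where $w_{ij}$ decays with the planar Euclidean distance between
   locations $i$ and $j$.

The geographic weights enter as multipliers on the per-observation
log-likelihood terms. This is the standard local-likelihood construction:
an unweighted product would make every "local" fit identical, which would
defeat the purpose of a locally varying model.

## Estimation

**Poisson.** Newton–Raphson on the log-likelihood
$\sum_i [y_i\eta_i - e^{\eta_i} - \log y_i!]$, initialised from a least
squares fit of $\log(y+1)$ on the predictors. Pure Newton steps can
overshoot on the log scale, so any step that fails to increase the
log-likelihood (or leaves the finite domain) is halved, up to 30 times.
Convergence is declared when the infinity norm of the parameter change
drops below $10^{-8}$ (default; `tol`). Standard errors come from the
inverse observed information.

**GPR.** An alternating scheme: Newton–Raphson for $\boldsymbol\beta$ at
the current $\varphi$ (same step-halving safeguard), then a dispersion
update, repeated to joint convergence. Two dispersion routes are offered:

* `phi_mode = "moments"` (default): solve the Pearson moment condition
  $$\sum_i \frac{(y_i-\hat\mu_i)^2}{\hat\mu_i(1+\varphi\hat\mu_i)^2}
    = n - (k+1)$$
  for $\varphi$ by a safeguarded Newton iteration. The left side is
  strictly decreasing in $\varphi$, so the root is unique when it exists.
  The degrees of freedom are $n$ minus the $k+1$ estimated mean
  parameters.
* `phi_mode = "newton"`: Newton ascent on the profile log-likelihood in
  $\varphi$, using analytic first and second derivatives.

$\varphi$ is clamped just above its support bound
$-1/\max(\max y, \max\hat\mu)$ whenever an update would leave the domain
of the density. `se(phi)` is obtained from a numerical second derivative
of the profile log-likelihood and should be read as approximate,
especially in moments mode where $\hat\varphi$ is not a maximiser.

**Likelihood-ratio testing with a moment-estimated dispersion.** The MLRT
compares the full model with the intercept-only model. Because the moments
route does not maximise the likelihood in $\varphi$, an intercept-only fit
with its *own* moment-estimated $\varphi$ is not nested in the full model:
in null simulations its log-likelihood exceeded the full model's in about
5% of replicates, producing negative deviances. The package therefore
evaluates the intercept-only log-likelihood **at the full model's
$\hat\varphi$** (a profile likelihood-ratio statistic). This restores
nesting — the deviance is non-negative by construction — and gives the
statistic its $\chi^2_k$ reference distribution; the measured type-I error
at $n = 100$ over 500 null replicates is 0.056 (the test suite and
`scripts/acceptance.R` recompute this).

**GWGPR.** Every location gets its own weighted fit, warm-started at the
global GPR estimates, with a local $\varphi$ (a `global_phi` flag reuses
the global estimate everywhere instead). The model-level log-likelihood
used for the deviance and AIC is the plug-in sum
$\sum_i \log f(y_i; \hat\mu_i, \hat\varphi_i)$ in which each observation
is evaluated under its own local fit; the comparison model for the
simultaneous test is the global intercept-only GPR. Local p-values are not
multiplicity-adjusted.

### A numerical safeguard specific to the generalized Poisson likelihood

For $\varphi > 0$ the per-observation GP log-density *flattens* as
$\mu \to \infty$: a zero count costs only $-1/\varphi$, and a positive
count approaches $y\log(1/\varphi) - (1+\varphi y)/\varphi$. The
likelihood surface therefore has near-plateau directions along which
$\boldsymbol\beta$ can run away, and because the moments update for
$\varphi$ is not likelihood-monotone, the alternating scheme can drift
onto a degenerate mode with enormous fitted means and $\varphi$ pinned
near zero. Small kernel windows that mix very small and very large counts
are the vulnerable case. All weighted likelihood evaluations therefore cap
the fitted mean at $50\times(1 + \max y)$ over the positively weighted
observations; no admissible mean for count data exceeds the observed
counts by orders of magnitude, so the cap removes the degenerate modes
without constraining realistic fits. (Local fits that run against this cap
are exactly the situation in which published GWGPR coefficient tables show
implausibly extreme local $Z$ statistics.)

## Kernels and bandwidth

Three compact-support kernels are provided: fixed bisquare
$(1-(d/h)^2)^2$, fixed tricube $(1-(d/h)^3)^3$, and adaptive bisquare, in
which the bandwidth at location $i$ is the distance to its $N$-th nearest
other location. The support is strict ($d < h$): a point at distance
exactly $h$ — including the $N$-th neighbour itself under the adaptive
rule — receives weight zero. Coordinates are treated as planar, so for
longitude/latitude input the distances are Euclidean on degrees; this
matches common practice for small study regions but is not a great-circle
computation.

The bandwidth is chosen by leave-one-out cross-validation: each location
is predicted from a local fit whose self-weight is forced to zero, and
$\mathrm{CV}(h) = \sum_i (y_i - \hat y_{\neq i}(h))^2$ is minimised. Fixed
kernels use a golden-section search warm-started by an 8-point coarse grid
on $[h_{\mathrm{lo}}, 2\max d]$, where $h_{\mathrm{lo}}$ is the smallest
bandwidth keeping every leave-one-out fit feasible ($k+2$ neighbours
strictly inside the support for every row). Golden section assumes a
unimodal CV curve; the coarse grid guards against local minima and the
full evaluation trace is returned so the curve can be audited. The
adaptive kernel scans every integer $N \in [k+2, n-1]$. An infeasible or
failed candidate scores $+\infty$ rather than raising an error.

Squared-error CV on strongly overdispersed counts is noisy: on synthetic
two-regime data some realisations yield a CV curve that decreases all the
way to near-global bandwidths even though a moderate bandwidth recovers
the coefficient surface far better. The bandwidth trace, not just the
optimum, is therefore part of the search result, and validation of the
estimator itself (below) is run at a kernel scale matched to the
structure being recovered.

## Diagnostics

* **VIF**: $1/(1-R^2_j)$ from the auxiliary least-squares regression of
  each predictor on the others; values above 10 are flagged, exact
  collinearity is reported as an infinite VIF rather than an error.
* **Kolmogorov–Smirnov vs Poisson**: the two-sided
  $D = \max_i\max\{i/N - F(y_{(i)}),\, F(y_{(i)}) - (i-1)/N\}$ with the
  Poisson CDF at the sample mean, and the asymptotic Kolmogorov p-value.
  For heavily tied discrete samples the lower envelope term absorbs the
  CDF jump, inflating $D$ by roughly the largest pmf mass; the statistic
  is reported as defined and should be read as a screening device.
* **Dispersion ratio**: deviance or Pearson $\chi^2$ over residual
  degrees of freedom; a ratio within $10^{-9}$ of 1 is classified
  equidispersed, above that overdispersed, below underdispersed.
* **Breusch–Pagan**: $\mathrm{BP} = \tfrac12 \mathbf{f}^\top
  \mathbf{Z}(\mathbf{Z}^\top\mathbf{Z})^{-1}\mathbf{Z}^\top\mathbf{f}$
  with the centred $f_i = e_i^2/\hat\sigma^2 - 1$ and $\mathbf{Z}$ an
  intercept plus column-standardised predictors; the centred form is
  required for the $\chi^2_k$ reference distribution. The `diagnose()`
  pipeline feeds **Pearson** residuals $(y-\hat\mu)/\sqrt{\hat\mu}$ from
  the Poisson fit: raw residuals have variance $\mu_i$ under a correctly
  specified Poisson model, so the BP test on raw residuals flags mean
  structure as heterogeneity even when none exists (97% false-alarm rate
  in our homogeneous simulations, versus 5% with Pearson residuals).
  `breusch_pagan()` itself accepts any residual vector.

All tests use strict inequality at the critical value and a single
$\alpha$ (default 0.05) throughout a pipeline run. AIC is
$-2\ln L + 2p$ with $p = k+1$ (Poisson), $k+2$ (GPR), and $k+2$ (GWGPR —
a recognised simplification: the effective parameter count of a locally
weighted model is larger, but no hat-matrix trace is defined for this
likelihood, so GWGPR's AIC advantage is, if anything, understated when
its likelihood gain is real).

## The synthetic-data generator

`synthetic_scenario()` fixes $n$, a coordinate layout (unit-square grid by
default, uniform-random optionally), one coefficient surface per parameter
(constant, linear in the coordinates, or a two-regime step in $u$), the
dispersion $\varphi$, and a seed; `generate_scenario()` draws iid standard
normal predictors, forms $\eta_i$ from the true surfaces, and samples
counts from the generalized Poisson distribution by CDF inversion. For
$\varphi < 0$ the density is improper, so the support is truncated where
$1 + \varphi y \le 0$ and renormalised; the truncation is reported and
means the effective dispersion is slightly less extreme than nominal.

Four presets define the validation conditions used throughout the tests:
$n = 200$, $k = 2$, and $\varphi \in \{0, 0.3\}$, with either constant
coefficients $(1.0, 0.4, -0.3)$ or a $\pm 0.5$ two-regime (or linear)
$\beta_1$ surface split at $u = 0.5$. These sizes mirror a realistic
district-census problem (a few hundred areal units, single-digit mean
counts) while keeping every check cheap. What the generator deliberately
does **not** emulate: spatially autocorrelated predictors, the covariate
distributions of any particular administrative dataset, or irregular
district geometries. Passing recovery tests on these scenarios shows the
estimator recovers known smooth or step coefficient structure under
generalized Poisson noise; it does not certify behaviour under covariate
spatial confounding.

Problem sizes used by the validation suite and the acceptance script:
parameter recovery at $n = 1000$ (global GPR, truth
$\beta = (1.0, 0.4)$, $\varphi = 0.3$); surface-sign recovery and the
AIC ladder on the $n = 200$ two-regime preset at a fixed bisquare
bandwidth of $0.3$ coordinate units, matched to the regime half-width;
test-size calibration from 500 null replicates at $n = 100$.

## Known limitations

* Planar coordinates only; no projection handling or great-circle
  distances.
* The GWGPR AIC parameter count ignores the effective-parameter inflation
  of local fitting.
* `se(phi)` is approximate in moments mode.
* Squared-error LOO CV is a noisy bandwidth criterion for strongly
  overdispersed counts; audit the CV trace before trusting the optimum.
* Local p-values are unadjusted for multiplicity; significance-set
  groupings should be read descriptively.

## A minimal worked run

```{r example, eval = FALSE}
g  <- generate_scenario(preset("heterogeneous_step"))
rep <- run_pipeline(g$dataset, kernels = "fixed_bisquare")
print(rep$aic_table)
print(rep$groups)
```
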