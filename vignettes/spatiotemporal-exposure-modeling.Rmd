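---
title: "Spatiotemporal exposure modeling for unbalanced monitoring networks"
author: "stfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal exposure modeling for unbalanced monitoring networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stfield)
```

## The problem

Cohort studies of chronic health effects of air pollution need long-term
average (LTA) outdoor concentrations at thousands of residential addresses,
over a decade or more, for several pollutants. The monitoring data available
for this are severely unbalanced: a few dozen regulatory monitors provide
multi-year series (with outages); a handful of study-operated fixed sites
provide a contiguous block of two-week samples; many home sites are visited
only one to three times, in different seasons; and clustered snapshot sites
near roads are sampled in three seasonal campaigns. `stfield` implements a
hierarchical Gaussian model that uses all of these tiers jointly, on a
common two-week time grid anchored on Wednesdays (the deployment cycle of
passive two-week samplers).

## The model

Let $C(s,t)$ be the natural log of the two-week average concentration at
site $s$ and period $t$. The decomposition is

$$C(s,t) \;=\; \beta_0(s) \;+\; \sum_{i=1}^{m} f_i(t)\,\beta_i(s) \;+\; \nu(s,t),$$

with three ingredients:

* **Smooth time trends** $f_1,\dots,f_m$ ($m$ = 1 or 2), empirical basis
  functions shared by the whole region. They are estimated from the
  long-series tiers only: site-by-period series are completed by an EM
  procedure that alternates low-rank SVD reconstruction with re-imputation
  of the missing cells, the leading left singular vectors of the
  column-centred completed matrix give raw trends, and each raw trend is
  projected onto a natural cubic spline basis with `df_per_year` (4 or 8)
  degrees of freedom per year. Each trend is normalised to zero mean and
  unit root-mean-square over the grid — the model is invariant to this
  scale (it is absorbed by $\beta_i$), so fixing it makes the parameters
  identifiable and results reproducible; each trend's sign is fixed by
  requiring a positive loading on the first source site. Trends are
  estimated once and then held fixed through fitting and cross-validation.

* **Spatially varying coefficients** $\beta_i(s)$, Gaussian random fields
  with mean $X_i(s)\,\alpha_i$ and either an exponential covariance
  (range $\phi_i$ km, partial sill $\sigma_i^2$, nugget $\tau_i^2$) or an
  independence structure (nugget only). $X_i(s)$ are reduced-dimension
  summaries of the geographic covariates (below), with a leading constant
  column.

* **A spatiotemporal residual** $\nu(s,t)$, independent across periods.
  Within a period its covariance is
  $\omega^2 + \sigma_\nu^2 e^{-d/\phi_\nu} + \tau_\nu^2 \mathbf{1}[d=0]$:
  the constant $\omega^2$ is a shared random period effect capturing
  region-wide short-term events (e.g. synoptic meteorology), mathematically
  equivalent to a random intercept per period.

### Covariate reduction by PLS

Geographic covariate sets (distances to roads, buffer measures of traffic,
land use, vegetation, emissions, dispersion-model output) contain hundreds
of strongly collinear columns. Rather than select variables, each site-level
outcome $\hat\gamma_i^s$ — the OLS coefficient of trend $i$ from regressing
each long-series site's observations on $[1, f_1, \dots, f_m]$ — is
regressed on the standardized covariates by univariate partial least
squares (NIPALS), extracting 2 or 3 orthogonal score directions that
maximize covariance with the outcome. This yields one score definition per
trend; scores at unmonitored locations come from the frozen training
centre/scale and rotation, never from re-fitting. Skewed covariates
(distances) are expected already transformed in the input table; the module
applies no transformations itself.

### Estimation

Covariance parameters are estimated by maximum likelihood on the log scale
of each positive parameter, with the mean coefficients $\alpha_i$ profiled
out by generalized least squares (their MLE given the covariance), so the
optimizer works in 4--13 dimensions only. The marginal covariance of the
stacked observation vector is

$$\Sigma \;=\; F\,\Sigma_\beta\,F^\top + \Sigma_\nu,$$

with $\Sigma_\beta$ block-diagonal over fields, $\Sigma_\nu$ block-diagonal
over periods, and $F$ the sparse expansion of the trend design. All solves
and determinants go through the Woodbury identity: one Cholesky per
residual pattern group (periods sharing an observation pattern share a
factorisation), one per field, and one of the $n(m{+}1)$-dimensional inner
matrix. The dense $N \times N$ covariance is never formed outside the test
suite's oracle. The gradient of the profiled likelihood is analytic (the
envelope theorem removes the $\partial\hat\alpha/\partial\theta$ term),
which makes L-BFGS-B fits of desk-scale regions take well under a second.
Optimization uses a data-driven start (variance components split from
per-site OLS residuals) plus seeded jittered restarts (3 by default), a
relative convergence tolerance of about $10^{-6}$, and an iteration cap of
500.

### Prediction

Predictions are conditional expectations of $C$ at target locations given
every observation in the region, with $\hat\alpha$ plugged in. Targets far
from all monitors revert smoothly to the mean surface
$\sum_i f_i(t) X_i(s)\hat\alpha_i$, plus the recovered shared period effect
in periods that have observations. Back-transformation is plain
exponentiation, matching the convention of the modeling tradition this
package follows; a lognormal bias-corrected option
($e^{\mu + \sigma^2/2}$) exists but is off by default. LTAs are arithmetic
means of the *exponentiated* two-week predictions over the requested date
range — the order matters (Jensen), and the arithmetic-of-exponentials
convention is the exposure quantity of interest.

### Evaluation

Cross-validation is stratified by tier: leave-one-out for the small set of
long-series sites, 10-fold for home sites, clustered 10-fold for snapshot
sites (clusters never split). Per fold, covariance parameters (and their
GLS by-product $\hat\alpha$) are re-estimated on the retained sites; time
trends and PLS score definitions are not. The headline metric is
$R^2_{CV} = \max(0,\, 1 - \mathrm{RMSE}^2/\mathrm{MSE}_{obs})$ on the
original concentration scale over site means — a fit-to-the-1:1-line
measure that is 0 whenever predictions do no better than the observed grand
mean, unlike the squared correlation $R^2_{CVreg}$ which is reported for
comparability only. Three temporally adjusted variants replace
$\mathrm{MSE}_{obs}$ with the MSE of a reference predictor built from the
long-series sites: their regional average, the nearest site's observations,
or the nearest site's fitted smooth trend; these isolate spatial skill for
temporally sparse tiers. The reference MSE is computed on site means,
parallel to the headline metric (the per-observation alternative is a
configuration option).

Model selection enumerates the 16 candidates
$\{1,2\}$ trends $\times$ $\{4,8\}$ df/year $\times$ $\{2,3\}$ scores
$\times$ spatial smoothing $\{$yes, no$\}$, ranks them by home-site
$R^2_{CV}$ first (then home RMSE, then fixed-site $R^2_{CV}$), and reports
the winner's structure. Home sites are prioritized because residential
spatial contrasts are the target of inference and because home sites play
no role in trend or score estimation, making their metrics immune to that
overfitting channel. The smoothing toggle applies to $\beta_0$ and the
$\beta_i$ jointly as one grid axis; the two can be decoupled via
`smooth_beta0` / `smooth_betai` since selected models in practice often
mix them.

## The synthetic campaign generator

No real monitoring data ship with the package; `generate_campaign()`
synthesizes a region with the full unbalanced design so that every module
is testable against known truth.

* **Geography and covariates.** Sites are uniform on a 75-km square
  (snapshot sites in tight clusters). Three latent smooth Gaussian fields
  (20-km correlation length, standardized across sites) drive both the
  covariates and the coefficient-field means; 20 informative covariates are
  noisy linear proxies of the latents (two exponentiated to a skewed
  distance-like scale) and 10 are pure noise. The latent-factor structure
  reproduces the massive collinearity of real GIS covariate sets — which is
  precisely what makes 2--3 PLS components sufficient. Effect sizes are
  fixed conditions (fixed weight norm, random direction), so replicate
  seeds vary the realization, not the signal-to-noise regime.

* **Scale calibration.** Defaults emulate a mid-sized metropolitan
  fine-particulate campaign: 29 regulatory + 5 fixed + 86 home sites and 26
  snapshot clusters of 4; regional mean $\log(13)$ ($\mu g/m^3$);
  covariate-driven site-mean log SD $\approx 0.25$; coefficient-field GP
  partial sill 0.01 and nugget 0.0025 (10-km range); residual components
  $\omega^2 = 0.04$, $\sigma_\nu^2 = 0.04$, $\tau_\nu^2 = 0.01$ (30-km
  range), i.e. two-week log residual SD $\approx 0.3$; common trend
  amplitudes 0.35 and 0.25 on the unit-RMS trend scale ($\pm$25--40%
  seasonal swings). The default axis spans 4 years.

* **Schedules.** Regulatory sites cover the axis minus one contiguous
  outage and 10% i.i.d. gaps; fixed sites a contiguous 4-year block; home
  sites 1--3 visits in distinct calendar quarters; snapshot clusters three
  shared periods in winter, summer, and one of spring/fall. Optional
  left-censoring at a configurable LOD quantile replaces censored values
  with LOD/2.

What the generator deliberately does **not** emulate: real meteorology and
chemistry, temporally varying covariates, instrument drift, or spatially
structured missingness. Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the model's own assumptions,
not robustness to their violation.

## Numerical and design choices

* One-based period indexing with half-open $[start, start+14)$ intervals;
  all time bookkeeping is by explicit period index, never by date
  arithmetic downstream of the axis.
* Coordinates are consumed as lon/lat and projected equirectangularly about
  the region centroid; at the ~75-km metropolitan scale the distance error
  of this projection is negligible relative to covariance range
  uncertainty. All distances are Euclidean km.
* EM imputation rank is $m+1$ (capped at one less than the number of
  series); natural-spline knots sit at time quantiles, which on the regular
  grid means equally spaced. SVD trends are not re-orthogonalized after
  smoothing.
* Aggregation completeness defaults to 75% at both the hourly-to-daily and
  daily-to-period steps, the conventional regulatory completeness
  criterion. An "irregular" regulatory monitor is one with any calendar
  quarter holding under 10% of its observations, generalizing the
  summer-only exemplar; both thresholds are configurable.
* The land-use exclusion threshold reads "maximum at most 10%"; the
  comparison direction and value are configurable.
* Near-singular covariance factorizations fall back to escalating-jitter
  Cholesky; parameters are bounded to $e^{\pm 25}$ on the log scale during
  optimization.
* ML, not REML, matching the estimation convention of this model family;
  per-fold re-estimation in cross-validation re-fits covariance parameters
  and the GLS coefficients but freezes trends and score definitions.
* Both the residual nugget and the period random effect are present by
  default; either can be fixed at zero through `st_structure()`.
* Samples straddling the axis end are dropped (and counted) rather than
  truncated; off-grid two-week samples are realigned only when the offset
  is exactly one week — the sanctioned realignment — and error otherwise.
* PLS outcomes are trained on all long-series tiers (regulatory, fixed,
  and reference sites); the training-set choice is exposed as an argument
  because defensible narrower readings exist.

## Problem sizes used by the tests

The test suite and acceptance checks run at desk scale, chosen as the
package's own study conditions: likelihood and kriging oracles on
instances up to 15 sites × 25 periods; parameter recovery on 20 replicates
of 100 sites × 50 periods at the default variance calibration; end-to-end
LTA recovery on the default campaign; and a 10-replicate trend-count
selection study on a reduced region (13 long-series + 16 home sites,
2 years) with strong spatially varying seasonal amplitude.

## Known limitations

* **Covariate extrapolation.** PLS scores are linear in the standardized
  covariates; a prediction location far outside the training covariate
  support extrapolates, and the error is amplified by $|f_i(t)|$ and by
  exponentiation. With heavy-tailed covariates this can produce large
  errors at isolated leverage sites — the covariate exclusion filters
  (rules a--d) mitigate but do not eliminate this, since an outlying value
  inflates the very SD used to detect it. In the trend-count selection
  study this mechanism penalizes richer models (two trend-coefficient
  fields carry twice the extrapolation exposure), and identification of
  the generating trend count succeeds in roughly 7 of 10 replicates rather
  than uniformly.
* The $\beta$-field nugget is weakly identified when it is small relative
  to the partial sill and the closest site pairs are closer than the
  range: the sum $\sigma_i^2 + \tau_i^2$ is what the data determine well.
  Ranges $\phi$ are likewise only order-of-magnitude identified.
* Likelihood evaluations scale with the number of *unique* observation
  patterns; pathological datasets where every period has a distinct
  pattern lose the factorisation sharing but remain correct.
* No Bayesian uncertainty on covariance parameters; prediction standard
  errors condition on the fitted covariance.

## A minimal run

```{r example, eval = FALSE}
camp <- generate_campaign(scenario_config(seed = 1))
data <- log_transform(camp$data)
basis <- estimate_trend_basis(data, m = 2, df_per_year = 4)
features <- build_feature_set(data, basis, n_comp = 3)
fit <- fit_ml(data, basis, features, st_structure(rep("exponential", 3)))
targets <- as.data.frame(data$sites[data$sites$site_type == "distributed", ])
pr <- predict(fit, targets = targets, covariates = data$covariates)
lta <- long_term_average(pr)
cor(lta$lta, camp$truth$lta[lta$site_id])
```

The same flow is available as a configuration-driven pipeline
(`run_pipeline()`, or the `exec/stfield` command-line wrapper), which
writes every stage's artifacts (cleaned CSVs, `trends.csv`,
`pls_scores.csv`, `model_params.json`, `predictions.csv`, `ltas.csv`)
together with the serialized configuration and its hash.
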