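---
title: "Methods: modelling oxidant-gas modification of PM2.5 mortality risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling oxidant-gas modification of PM2.5 mortality risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxmod)
```

## The scientific problem

Fine particulate matter (PM2.5) increases mortality risk, but populations
breathe mixtures: the oxidant gases NO2 and O3 deplete lung-lining
antioxidants and increase epithelial permeability, so the *same* PM2.5 mass
may be more harmful where oxidant concentrations are higher. `oxmod` models
this effect modification through the combined oxidant capacity

$$O_x = \frac{1.07\,\mathrm{NO_2} + 2.075\,\mathrm{O_3}}{3.145},$$

a redox-potential-weighted average of the two gases (ppb). The package
provides the full analysis chain a cohort study of this question needs —
exposure construction, stratified proportional-hazards models, tertile and
interaction analyses, and a joint nonlinear threshold model — together with
a synthetic-cohort generator, because the motivating class of national
census-linked cohorts is confidential and cannot ship with any software.

## The joint nonlinear model

The core model is a shape-constrained joint relative risk surface

$$R(\mathrm{PM_{2.5}}, O_x) = \exp\{\theta(O_x)\, T(\mathrm{PM_{2.5}})\},$$

with two pieces:

* a **hinge in oxidant capacity**,
  $\theta(O_x) = \eta + \lambda (O_x - \omega)_+$. Below the threshold
  $\omega$ (ppb) the oxidant environment does not modify PM2.5 risk; above
  it, the log-relative-risk coefficient grows linearly at rate $\lambda$
  per ppb. The model has *no* Ox main effect: it redistributes PM2.5 risk
  across oxidant levels rather than attributing deaths to Ox itself.
* a **PM2.5 transform**
  $T(z) = \log(\Im(z)) \big/ \left(1 + e^{-(z - \mu)/\pi}\right)$ with
  $\Im(z) = 1 + z$ (default) or $\Im(z) = e^z$. Depending on
  $(\Im, \mu, \pi)$ this family spans supra-linear, near-linear,
  sub-linear and sigmoidal concentration–response shapes. With
  $\Im(z) = 1+z$ the risk at zero exposure is exactly 1 and
  $R = (1+\mathrm{PM_{2.5}})^{\theta(O_x) w(\mathrm{PM_{2.5}})}$ with $w$
  the logistic weight.

The expression for $T$ is sometimes typeset ambiguously
("$\log(\Im(z))/1+\exp(\cdots)$"); `oxmod` reads the divisor as the full
logistic denominator, which is the only reading consistent with the
sigmoidal-family description and the closed form above. The logistic scale
default $\pi = 2$ µg/m³ echoes the $e^{-z/2}$ weight that appears in that
closed form; the location default $\mu = 5$ µg/m³ puts the inflection in
the lower half of the observed PM2.5 range. Both stay free parameters of
`schif_params()` and are profiled during fitting.

## Estimation

Given $(\omega, \mu, \pi)$, the model is linear in $(\eta, \lambda)$: the
log hazard contains the two constructed covariates $T(\mathrm{PM_{2.5}})$
and $(O_x-\omega)_+ T(\mathrm{PM_{2.5}})$. `fit_joint()` therefore profiles
an exhaustive grid over $(\omega, \mu, \pi)$ — by default $\omega$ runs
from the 5th to the 95th percentile of the person-year Ox distribution in
0.25-ppb steps, with small documented grids for $\mu \in \{2.5, 5, 10\}$
and $\pi \in \{1, 2, 4\}$ — and solves each inner problem as a stratified
2-coefficient Cox fit, the same code path as `fit_cox()`. Profiling was
chosen over smooth optimization because the hinge makes the likelihood
non-differentiable in $\omega$; a grid is robust, reproducible, and makes
the non-smoothness harmless. Grid points whose inner fit fails are flagged
in the retained profile table, not fatal.

Uncertainty uses a nonparametric person-level bootstrap
(`joint_bootstrap()`, default $B = 200$, seeded): whole follow-up
histories are resampled and the full grid profile is re-run per replicate,
so the intervals include threshold-estimation uncertainty that a Wald
interval at fixed $\omega$ would miss. Percentile intervals are widened
where necessary to bracket the central curve. Because hinge inference is
non-regular (under $\lambda = 0$ the threshold is unidentified), the
package reports $-2\log L$ differences between joint and linear
specifications but deliberately attaches no automatic significance test,
and percentile intervals near the null should be read as approximate;
the null-calibration simulations in the test suite quantify this at small
sample sizes.

Cox estimation itself is delegated to `survival::coxph()` behind the
`fit_cox()` surface: follow-up time is the timescale, age (5-year groups),
sex, airshed and population-centre size define the strata (separate
baseline hazards, shared coefficients), and ties are handled by Breslow's
approximation by default (Efron available via `model_spec(ties =)`); the
published analyses this design mirrors do not state their tie convention,
and Breslow keeps the package's from-scratch partial-likelihood oracle in
the test suite simple. The test suite verifies the fits against that
oracle by direct enumeration of risk sets on small tables.

## Exposure assembly conventions

* **Ox** is computed by `compute_ox()` everywhere — including inside the
  generator — so there is a single source of truth for the weights.
* **Moving average**: "3-year moving average with a 1-year lag" is read as
  calendar years $t-3, t-2, t-1$ for person-year $t$: the lag excludes the
  index year, the window counts back from there. Each contributing year
  uses the region the person occupied *that* year, so mobility mixes
  regions within a window. Partial windows are never averaged — the
  simulated calendar includes enough pre-baseline years that every
  baseline person-year has a complete window.
* **Exclusions**: baseline age outside 25–90 (inclusive bounds) drops the
  person; a PM2.5 estimate above 20 µg/m³ drops that *person-year* only,
  since such values flag bad retrievals rather than bad subjects (the
  person-vs-person-year semantics are genuinely ambiguous in the source
  design; the person-year reading is the package's choice and is
  documented at `apply_exclusions()`).
* **Reporting increments**: hazard ratios are expressed per the mean minus
  the 5th percentile of the person-year exposure distribution, with the
  percentile computed by linear interpolation between order statistics
  (`quantile()` type 7). Increments are always recomputed from the data in
  hand, never hard-coded: published increment tables are internally
  inconsistent at the ppb level (an O3 increment of 10.503 against printed
  summaries implying 10.68), indicating unrounded internal values upstream.
* **Tertiles**: cut points are empirical person-year tertiles of the
  modifier, boundary values assigned to the lower tertile. Tertile hazard
  ratios come from disjoint-subset fits (three separate models), all
  scaled to the increment of the *full* table so they are comparable; a
  single-model interaction parameterization of the same analysis is
  available through `fit_joint_tertile_grid()`.

## What the synthetic generator emulates

`generate_pollutant_surfaces()` draws region-year concentrations from a
Gaussian copula: each pollutant's latent field (a persistent region
component plus small year-to-year noise, `year_noise_sd = 0.15` on the
unit-variance latent scale) is mapped through a piecewise-linear quantile
function interpolating target percentiles (defaults: the person-year
summaries of a large Canadian cohort — PM2.5 mean 7.37 µg/m³ on (0, 20],
O3 mean 38.29 ppb, NO2 mean 11.47 ppb). Two structural choices matter:

* the upper tail is damped (an interior knot at probability 0.995, placed
  15% of the way from the 95th percentile to the maximum) because a
  straight line from the 95th percentile to the printed maximum would
  inflate the mean far beyond its target — NO2, whose maximum is more
  than five times its mean, is the worst case. Even so, a printed NO2 mean
  of 11.47 is unattainable exactly: any increasing tail forces the
  conditional mean above the 95th percentile (24.52) to exceed it, which
  already implies a mean of at least about 11.5. The damped tail lands
  within a few percent of all printed means.
* NO2 and O3 share a regional oxidant factor (loading 0.55), and the
  PM2.5 latent loads on the standardized redox-weighted combination of
  the gas latents. That loading is tuned by bisection *on the realized
  sample* until the sample PM2.5–Ox correlation hits its target (default
  0.66), which is exact up to bisection tolerance because the map from
  loading to correlation is monotone under common random numbers.

`generate_cohort()` draws baseline covariates from category marginals
loosely matching the published cohort composition (these are a realistic
mix, not calibration targets), and region trajectories from a Markov move
process with a 5%/year default mobility — a typical inter-region
residential move rate; the source design gives none.
`simulate_survival()` draws event times on a person-year grid
(piecewise-exponential, matching the annual exposure updating) from
cause-specific hazards: per-age-group baseline nonaccidental rates rising
log-linearly from roughly 0.2%/yr in the thirties to 11%/yr in the late
eighties (about 0.8% per person-year crude under the default covariate
mix), multiplied by $\exp\{\theta(O_x)T(\mathrm{PM_{2.5}}) + x'\beta\}$
evaluated through the same `theta_of_ox()`/`transform_T()` code the
fitting side uses. Causes (cardiovascular, respiratory, other — all nested
within nonaccidental) are drawn multinomially at event time with shares
0.33/0.09/0.58, following published nested death counts. Administrative
censoring ends follow-up at 10.6 years. The default hinge truth is
$\eta = 0.03$, $\lambda = 0.004$/ppb, $\omega = 24$ ppb.

The generator does **not** emulate: real geography or spatial
autocorrelation beyond the shared regional factors, measurement error in
exposure surfaces, missing postal-code years (no imputation is needed or
provided), immigration/linkage artifacts, or time trends in pollutant
levels. Passing tests therefore demonstrate that the *estimators* behave
correctly under the assumed data-generating structure — not that the
substantive findings would replicate in real cohorts, where exposure
error and unmeasured confounding operate.

## Simulation sizes and numerical choices

The test suite exercises the chain at sizes chosen to keep the full run
desk-scale while preserving statistical meaning; these are the package's
own choices of experimental scale:

* **Threshold recovery**: 20 cohorts of 15,000 persons (≈165,000
  person-years, ≈2,400 nonaccidental deaths each) simulated with
  $\omega = 24$ ppb and a planted modification of $\lambda = 0.04$/ppb
  with covariate effects zeroed — a signal strength at which $\hat\lambda$
  sits several standard errors from zero, the regime in which a threshold
  is meaningfully estimable at this scale (at the cohort sizes of the
  motivating studies, two orders of magnitude more deaths, proportionally
  weaker modification is recoverable; precision scales with the square
  root of the event count). The recovery fits profile $\omega$ over
  20–30 ppb in 0.5-ppb steps with $(\mu, \pi)$ held at the generator's
  values.
* **Null calibration**: 10 cohorts of 2,000 persons with $\lambda = 0$;
  the $\omega$-profile is checked for flatness and 40-replicate bootstrap
  intervals for $\theta$ at high Ox are checked for coverage of $\eta$.
  At $B = 40$ and these event counts percentile intervals are expected to
  be approximately, not exactly, calibrated.
* **Degenerate inputs**: constant exposure columns are refused (a zero
  increment cannot scale a hazard ratio; a constant modifier is
  inestimable); collinear exposure terms fail a rank check before
  fitting; monotone likelihoods (risk-set separation) are reported as
  divergence on the exposure terms rather than as an error, while
  aliased sparse covariate levels are dropped with a recorded warning.
* The logistic weight is evaluated through `plogis()`, so extreme
  standardized arguments neither overflow nor underflow.

## Known limitations

* The estimation procedure for the joint model reconstructs a plausible
  profile-likelihood approach from the model definition; the original
  studies' estimation details are not public, so estimated thresholds are
  comparable in kind, not in provenance.
* Percentile bootstrap intervals around a hinge are approximate,
  particularly near $\lambda = 0$ where the threshold is unidentified.
* Tertile contrasts under the $\log(1+z)$ transform are intrinsically
  modest (the transform saturates at high PM2.5), so tertile-pattern
  statistics need either large cohorts or strong planted signals.
* The generator's covariate hazard ratios and baseline rates are loosely
  calibrated defaults, adequate for exercising estimators, and are not
  authoritative epidemiology.
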