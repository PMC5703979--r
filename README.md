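# oxmod

Survival-analysis tools for a question in air-pollution epidemiology: do
oxidant gases make fine particulate matter more deadly? Outdoor PM2.5 is an
established mortality risk factor, but people breathe mixtures, and ozone
and nitrogen dioxide — summarized by their redox-weighted oxidant capacity

    Ox = (1.07 * NO2 + 2.075 * O3) / 3.145   [ppb]

— deplete lung-lining antioxidants and increase epithelial permeability,
plausibly potentiating PM2.5 effects. `oxmod` implements the full analysis
chain such a cohort study needs, exercised end-to-end on synthetic cohorts
(the motivating national census-linked cohorts are confidential):

* **Synthetic cohorts** — region-year pollutant surfaces from a Gaussian
  copula calibrated to target marginals and a target PM2.5–Ox correlation
  (default r = 0.66); covariates, residential mobility, and
  piecewise-exponential survival with a planted effect-modification truth.
* **Exposure assembly** — Ox, 3-year moving averages with a 1-year lag
  updated for residential mobility, cubic-spline year adjustment,
  age/PM2.5 exclusion rules, and mean-minus-5th-percentile reporting
  increments.
* **Stratified Cox analyses** (via `survival::coxph`, Breslow ties) —
  single-pollutant, two-pollutant, product-term, per-tertile and 3×3
  joint-tertile hazard ratios, stratified by age, sex, airshed and
  population-centre size.
* **A joint nonlinear threshold model** — the package's core:
  `R(PM2.5, Ox) = exp{theta(Ox) * T(PM2.5)}` with a hinge
  `theta(Ox) = eta + lambda * (Ox - omega)+` (no modification below the
  threshold `omega`) and a shape-constrained transform
  `T(z) = log(1 + z) / (1 + exp(-(z - mu)/pi))`, estimated by profile
  likelihood over `(omega, mu, pi)` with person-level bootstrap
  uncertainty.

See `vignettes/oxmod-methods.Rmd` for the model, conventions and design
choices.

## Worked example

Simulate a 10,000-person cohort with a planted modification
(`lambda = 0.02` per ppb above `omega = 24` ppb), assemble exposures, and
fit the main analyses:

```r
library(oxmod)

truth <- true_hazard(lam = 0.02)
cfg <- sim_config(n_persons = 10000, n_regions = 300, seed = 11,
                  true_params = truth)
surfaces <- generate_pollutant_surfaces(cfg)
cohort <- generate_cohort(cfg, surfaces)
exposures <- lagged_moving_average(cohort, surfaces)
kept <- apply_exclusions(cohort, exposures)
cohort <- simulate_survival(kept$cohort, kept$exposures, cfg)
py <- assemble_person_years(cohort, kept$exposures, cfg)

inc <- reporting_increment(py$pm25, "pm25")
#> Reporting increment for pm25: 3.631 (mean 7.306 - 5th pct 3.675)

spec <- model_spec(cause = "nonaccidental", terms = "pm25",
                   covariates = c("education", "income_quintile",
                                  "labour_force", "marital"))
hr_for_increment(fit_cox(py, spec), "pm25", inc)
#>   term    delta       hr   ci_low  ci_high
#> 1 pm25 3.631404 1.354549 1.244566 1.474252
```

The PM2.5 hazard ratio (here 1.35 per 3.63 µg/m³, pooled over all oxidant
levels) hides the modification. Splitting by Ox tertiles shows it:

```r
fit_tertile_series(py, spec, modifier = "ox")$hr_table
#>   tertile     n events modifier_mean    hr ci_low ci_high
#> 1       1 34774    272        22.727 0.916  0.696   1.205
#> 2       2 34748    336        29.266 1.402  1.093   1.799
#> 3       3 34745    433        35.406 1.372  1.179   1.596
```

— a null PM2.5 association in the lowest oxidant tertile and clearly
elevated risk in the upper two. The joint nonlinear model localizes the
change-point directly:

```r
fit_joint(py, model_spec(cause = "nonaccidental",
                         covariates = c("education", "income_quintile",
                                        "labour_force", "marital")),
          omega_grid = seq(20, 32, by = 0.5), mu_grid = 5, pi_grid = 2)
#> Joint nonlinear PM2.5-Ox fit (profile likelihood)
#>   eta = 0.12327, lambda = 0.01827, omega = 26.50 ppb
#>   transform: 1+z, mu = 5.00, pi = 2.00, logistic weight: TRUE
#>   -2 log L = 6042.180 over 25 grid points
```

The estimated threshold (26.5 ppb) and slope (0.018 per ppb) recover the
planted truth (24 ppb, 0.02) to within the precision ~1,000 deaths allow;
`theta_profile_with_uncertainty()` and `predict_risk_curve()` add
bootstrap bands and concentration–response curves at chosen Ox levels, and
`flag_above_threshold()` marks regions above a threshold (default 23 ppb).

`run_pipeline()` orchestrates all stages (simulate → assemble → fits →
report) into plain CSV/JSON artifacts with a digest manifest;
`inst/scripts/oxpipeline.R` is a command-line wrapper over it.

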