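# Small simulated datasets shared across test files. Built once per test
# run and cached, so several test files can reuse the same cohort.

small_config <- function(n_persons = 2000, n_regions = 100, seed = 42, ...) {
  sim_config(n_persons = n_persons, n_regions = n_regions, seed = seed, ...)
}

# Cohort simulated under the default (potentiating) truth, assembled into a
# person-year analysis table.
sim_analysis_table <- local({
  cache <- new.env()
  function(n_persons = 4000, seed = 42, true_params = true_hazard(),
           key = paste(n_persons, seed, format(true_params$lam))) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- sim_config(n_persons = n_persons, n_regions = 150, seed = seed,
                      true_params = true_params)
    surf <- generate_pollutant_surfaces(cfg)
    coh <- generate_cohort(cfg, surf)
    exps <- lagged_moving_average(coh, surf)
    coh <- simulate_survival(coh, exps, cfg)
    py <- assemble_person_years(coh, exps, cfg)
    cache[[key]] <- list(config = cfg, surfaces = surf, cohort = coh,
                         exposures = exps, py = py)
    cache[[key]]
  }
})

# Adjustment covariates used throughout the analysis tests.
adj_covariates <- c("education", "income_quintile", "labour_force", "marital")
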