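#' True hazard parameters for the synthetic cohort
#'
#' The generator simulates death times from a piecewise-constant (per
#' person-year) cause-specific hazard
#' \deqn{h(t) = \sum_c r_c(\mathrm{stratum}) \exp\{\theta(O_x) T(PM_{2.5})
#'   + x'\beta\},}
#' where \eqn{\theta(O_x) = \eta + \lambda (O_x - \omega)_+} is the hinge in
#' oxidant capacity and \eqn{T} the shape-constrained PM2.5 transform. This
#' object holds the generator-side truth: the hinge and transform parameters,
#' per-covariate-level log hazard ratios, per-age-group baseline nonaccidental
#' mortality rates, and the multinomial cause shares
#' (cardiovascular/respiratory/other, nested within nonaccidental).
#'
#' Defaults: \eqn{\eta = 0.03}, \eqn{\lambda = 0.004} per ppb, threshold
#' \eqn{\omega = 24} ppb (within the simulated Ox support), logistic location
#' \eqn{\mu = 5} µg/m³ and scale \eqn{\pi = 2} µg/m³, transform
#' \eqn{\Im(z) = 1 + z}. Baseline rates rise roughly log-linearly with age and
#' average about 1% per person-year over the default age structure; cause
#' shares follow the nested death counts of a large national cohort
#' (roughly 33% cardiovascular and 9% respiratory among nonaccidental
#' deaths).
#'
#' @param eta Log relative risk per unit `T(PM2.5)` at or below the Ox
#'   threshold.
#' @param lam Increase in theta per ppb of Ox above the threshold.
#' @param omega Ox threshold (ppb).
#' @param mu,pi_scale Location and scale (µg/m³) of the logistic weight in
#'   the PM2.5 transform; `pi_scale > 0`.
#' @param transform_variant `"1+z"` (log(1 + PM2.5), risk 1 at zero exposure)
#'   or `"exp"` (identity on the log scale).
#' @param covariate_log_hrs Named list: for each categorical covariate, a
#'   numeric vector of per-level log hazard ratios (first level = reference
#'   = 0).
#' @param baseline_rates Named numeric vector of per person-year nonaccidental
#'   event rates, one per 5-year age group.
#' @param cause_shares Named numeric vector (`cardiovascular`, `respiratory`,
#'   `other`) summing to 1; the multinomial cause distribution at event time.
#' @return An object of class `true_hazard`.
#' @export
true_hazard <- function(eta = 0.03,
                        lam = 0.004,
                        omega = 24,
                        mu = 5,
                        pi_scale = 2,
                        transform_variant = c("1+z", "exp"),
                        covariate_log_hrs = default_covariate_log_hrs(),
                        baseline_rates = default_baseline_rates(),
                        cause_shares = c(cardiovascular = 0.33,
                                         respiratory = 0.09,
                                         other = 0.58)) {
  transform_variant <- match.arg(transform_variant)
  stopifnot(pi_scale > 0, all(baseline_rates >= 0))
  cause_shares <- cause_shares / sum(cause_shares)
  if (!setequal(names(cause_shares), c("cardiovascular", "respiratory", "other"))) {
    stop("cause_shares must name cardiovascular, respiratory and other")
  }
  structure(
    list(eta = eta, lam = lam, omega = omega, mu = mu, pi_scale = pi_scale,
         transform_variant = transform_variant,
         covariate_log_hrs = covariate_log_hrs,
         baseline_rates = baseline_rates,
         cause_shares = cause_shares),
    class = "true_hazard"
  )
}

#' @rdname true_hazard
#' @export
default_baseline_rates <- function() {
  groups <- age_group_levels()
  mids <- seq(27, 87, by = 5)
  # log-linear rise with age, ~0.2%/yr in the 30s to ~11%/yr in the late
  # 80s; with the default covariate mix this gives a crude nonaccidental
  # rate near 0.8%/person-year, i.e. roughly 9% dying over 10.6 years
  rates <- exp(-6.5 + 0.072 * (mids - 27))
  names(rates) <- groups
  rates
}

#' @rdname true_hazard
#' @export
default_covariate_log_hrs <- function() {
  list(
    education = log(c(1, 0.803, 0.670, 0.551)),
    income_quintile = log(c(1, 0.816, 0.711, 0.633, 0.536)),
    labour_force = log(c(1, 1.608, 1.944)),
    marital = log(c(1, 0.788, 0.676, 0.996, 1.006, 0.898))
  )
}

age_group_levels <- function() {
  lo <- seq(25, 85, by = 5)
  sprintf("%d-%d", lo, lo + 4)
}

#' Synthetic-cohort configuration
#'
#' Fixes every knob of the synthetic study: cohort and region counts,
#' follow-up length, pollutant marginal targets, the target correlation
#' between PM2.5 and Ox, residential mobility, and the true hazard. The
#' defaults are the study conditions the package's analyses are exercised
#' under: 10.6 years of follow-up with administrative censoring, pollutant
#' marginals from [default_pollutant_marginals()], a PM2.5–Ox correlation of
#' 0.66, and a 5%/yr probability of moving region.
#'
#' The simulated calendar covers `window_years + lag_years - 1` pre-baseline
#' years (so every baseline person-year has a complete lagged averaging
#' window) plus `ceiling(follow_up_years)` follow-up years.
#'
#' @param n_persons Number of cohort members.
#' @param n_regions Number of regions with their own pollutant series.
#' @param follow_up_years Administrative censoring time (years).
#' @param seed Integer seed; every random stage derives its stream from it.
#' @param pollutant_marginals Named list of [pollutant_marginal()] targets
#'   for `pm25`, `o3` and `no2` (an `ox` entry, if present, is reference
#'   only).
#' @param target_corr_pm25_ox Target Pearson correlation between PM2.5 and
#'   derived Ox, in (-1, 1).
#' @param mobility_prob Per-year probability that a person changes region.
#' @param true_params A [true_hazard()] object.
#' @param window_years,lag_years Exposure moving-average window and lag.
#' @param oxidant_factor_loading Loading of the NO2 and O3 latents on their
#'   shared regional oxidant factor (controls the NO2–O3 dependence and
#'   hence the spread of derived Ox).
#' @param year_noise_sd Standard deviation of the within-region year-to-year
#'   latent noise (the region component has unit total variance).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 10000,
                       n_regions = 500,
                       follow_up_years = 10.6,
                       seed = 1L,
                       pollutant_marginals = default_pollutant_marginals(),
                       target_corr_pm25_ox = 0.66,
                       mobility_prob = 0.05,
                       true_params = true_hazard(),
                       window_years = 3L,
                       lag_years = 1L,
                       oxidant_factor_loading = 0.55,
                       year_noise_sd = 0.15) {
  stopifnot(
    n_persons >= 1, n_regions >= 1, follow_up_years > 0,
    mobility_prob >= 0, mobility_prob <= 1,
    abs(target_corr_pm25_ox) < 1,
    window_years >= 1, lag_years >= 0,
    year_noise_sd >= 0, year_noise_sd < 1,
    inherits(true_params, "true_hazard")
  )
  for (p in c("pm25", "o3", "no2")) {
    if (!inherits(pollutant_marginals[[p]], "pollutant_marginal")) {
      stop("pollutant_marginals must contain a pollutant_marginal for ", p)
    }
  }
  pre_years <- window_years + lag_years - 1L
  n_years <- pre_years + as.integer(ceiling(follow_up_years))
  structure(
    list(n_persons = as.integer(n_persons),
         n_regions = as.integer(n_regions),
         follow_up_years = follow_up_years,
         seed = as.integer(seed),
         pollutant_marginals = pollutant_marginals,
         target_corr_pm25_ox = target_corr_pm25_ox,
         mobility_prob = mobility_prob,
         true_params = true_params,
         window_years = as.integer(window_years),
         lag_years = as.integer(lag_years),
         pre_years = pre_years,
         n_years = n_years,
         baseline_year = pre_years + 1L,
         oxidant_factor_loading = oxidant_factor_loading,
         year_noise_sd = year_noise_sd),
    class = "sim_config"
  )
}

#' Default covariate marginals for the synthetic cohort
#'
#' Category probabilities for the baseline covariates, loosely following the
#' composition of a large Canadian census-linked cohort: age structure skewed
#' toward working ages, slight female excess, one dominant airshed, and the
#' published education/income/labour-force/marital mixes. Not authoritative —
#' they set a realistic covariate mix for simulation, nothing more.
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_marginals <- function() {
  age10 <- c(0.0907, 0.2346, 0.2593, 0.1821, 0.1171, 0.0842, 0.0319)
  age5 <- c(age10[1], rep(age10[2:7] / 2, each = 2))
  names(age5) <- age_group_levels()
  list(
    age_group = age5 / sum(age5),
    sex = c(female = 0.516, male = 0.484),
    airshed = c(western = 0.110, prairie = 0.120, west_central = 0.069,
                east_central = 0.572, south_atlantic = 0.111, northern = 0.018),
    popcentre = c(rural = 0.266, small = 0.161, medium = 0.096, large = 0.477),
    education = c(less_than_hs = 0.288, high_school = 0.362,
                  post_secondary = 0.193, university = 0.157),
    income_quintile = c(q1 = 0.153, q2 = 0.190, q3 = 0.208,
                        q4 = 0.219, q5 = 0.230),
    labour_force = c(employed = 0.646, unemployed = 0.042,
                     not_in_labour_force = 0.312),
    marital = c(single = 0.132, common_law = 0.120, married = 0.609,
                separated = 0.024, divorced = 0.058, widowed = 0.057)
  )
}
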