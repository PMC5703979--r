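#' Simulate survival outcomes for a synthetic cohort
#'
#' Draws event times from a piecewise-constant-hazard model on the
#' person-year grid (matching the annual exposure updating), with
#' administrative censoring at `config$follow_up_years`. The total hazard in
#' a person-year is
#' \deqn{h = \Big(\sum_c r_c(\mathrm{age\ group})\Big)
#'   \exp\{\theta(O_x) T(PM_{2.5}) + x'\beta\},}
#' where the cause-specific baseline rates \eqn{r_c} are the configured
#' nonaccidental rate split by the multinomial cause shares, and theta/T are
#' evaluated through [theta_of_ox()] and [transform_T()] with the
#' generator-side true parameters — the same code path the fitting side
#' uses. At an event, the cause (cardiovascular / respiratory / other, all
#' nested within nonaccidental) is drawn from the shares.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param exposures Assigned person-year exposures from
#'   [lagged_moving_average()] covering every follow-up year of every person.
#' @param truth A [true_hazard()]; defaults to `config$true_params`.
#' @param config The [sim_config()] the cohort was generated under.
#' @return The cohort with `event_time` (years since baseline) and
#'   `event_cause` (`"cardiovascular"`, `"respiratory"`, `"other"`, or
#'   `"censored"`) filled in.
#' @export
simulate_survival <- function(cohort, exposures, config,
                              truth = config$true_params) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "true_hazard"))
  n <- nrow(cohort)
  fu <- config$follow_up_years
  J <- as.integer(ceiling(fu))
  durations <- c(rep(1, J - 1L), fu - (J - 1L))
  cal_years <- config$baseline_year + seq_len(J) - 1L
  set.seed(config$seed + 2L)

  params <- schif_params(
    eta = truth$eta, lam = truth$lam, omega = truth$omega,
    mu = truth$mu, pi_scale = truth$pi_scale,
    transform_variant = truth$transform_variant
  )

  key <- paste(exposures$person_id, exposures$year)
  get_col <- function(col, year) {
    i <- match(paste(cohort$person_id, year), key)
    if (anyNA(i)) {
      miss <- which(is.na(i))[1]
      stop(sprintf("missing exposure for person %s in year %d",
                   cohort$person_id[miss], year))
    }
    exposures[[col]][i]
  }

  lp_cov <- numeric(n)
  for (cov in names(truth$covariate_log_hrs)) {
    if (!cov %in% names(cohort)) next
    lp_cov <- lp_cov + truth$covariate_log_hrs[[cov]][as.integer(cohort[[cov]])]
  }
  base_rate <- truth$baseline_rates[as.character(cohort$age_group)]
  if (anyNA(base_rate)) stop("baseline_rates missing for some age groups")

  haz <- matrix(NA_real_, n, J)
  for (j in seq_len(J)) {
    pm <- get_col("pm25", cal_years[j])
    ox <- get_col("ox", cal_years[j])
    haz[, j] <- base_rate *
      exp(lp_cov + theta_of_ox(ox, params) * transform_T(pm, params))
  }

  E <- stats::rexp(n)
  cum <- haz %*% diag(durations, J, J)
  cum <- t(apply(cum, 1, cumsum))
  if (J == 1L) cum <- matrix(cum, n, 1L)
  event_j <- apply(cum >= E, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)

  time <- rep(fu, n)
  cause <- rep("censored", n)
  has_event <- !is.na(event_j)
  if (any(has_event)) {
    j <- event_j[has_event]
    prev <- ifelse(j == 1L, 0, cum[cbind(which(has_event), pmax(j - 1L, 1L))])
    within <- (E[has_event] - prev) / haz[cbind(which(has_event), j)]
    time[has_event] <- (j - 1L) + pmin(within, durations[j])
    shares <- truth$cause_shares[c("cardiovascular", "respiratory", "other")]
    cause[has_event] <- sample(names(shares), sum(has_event),
                               replace = TRUE, prob = shares)
  }
  cohort$event_time <- time
  cohort$event_cause <- cause
  cohort
}

#' Assemble the person-year analysis table
#'
#' Expands a simulated cohort into counting-process rows (one per person
#' per follow-up year actually at risk), joins the assigned annual
#' exposures, and attaches cause-specific event indicators to each person's
#' final row. This is the table every Cox analysis in the package runs on:
#' follow-up time is the timescale (`tstart`, `tstop` in years since
#' baseline) and the stratum is the cross of age group, sex, airshed and
#' population-centre size.
#'
#' @param cohort Cohort with survival outcomes from [simulate_survival()].
#' @param exposures Assigned exposures from [lagged_moving_average()].
#' @param config The [sim_config()] (for follow-up length and calendar
#'   alignment).
#' @return Data frame with `person_id`, `tstart`, `tstop`, event indicators
#'   `event_nonaccidental` / `event_cardiovascular` / `event_respiratory`,
#'   exposure columns `pm25`, `no2`, `o3`, `ox`, the baseline covariates and
#'   a `stratum` factor.
#' @export
assemble_person_years <- function(cohort, exposures, config) {
  stopifnot(all(!is.na(cohort$event_time)))
  fu <- config$follow_up_years
  n_years_i <- pmax(ceiling(cohort$event_time), 1L)
  idx <- rep(seq_len(nrow(cohort)), times = n_years_i)
  j <- sequence(n_years_i)
  tstart <- j - 1
  tstop <- pmin(j, cohort$event_time[idx])
  last <- j == n_years_i[idx]
  cause <- cohort$event_cause[idx]
  out <- data.frame(
    person_id = cohort$person_id[idx],
    tstart = tstart,
    tstop = tstop,
    event_nonaccidental = as.integer(last & cause != "censored"),
    event_cardiovascular = as.integer(last & cause == "cardiovascular"),
    event_respiratory = as.integer(last & cause == "respiratory")
  )
  cal_year <- config$baseline_year + j - 1L
  m <- match(paste(out$person_id, cal_year),
             paste(exposures$person_id, exposures$year))
  for (col in c("pm25", "no2", "o3", "ox")) out[[col]] <- exposures[[col]][m]
  covs <- c("age_group", "sex", "airshed", "popcentre", "education",
            "income_quintile", "labour_force", "marital")
  covs <- intersect(covs, names(cohort))
  for (col in covs) out[[col]] <- cohort[[col]][idx]
  strata_vars <- intersect(c("age_group", "sex", "airshed", "popcentre"), covs)
  out$stratum <- interaction(out[strata_vars], drop = TRUE)
  # drop person-years with no assignable exposure (e.g. excluded estimates)
  out[!is.na(out$pm25) & out$tstop > out$tstart, , drop = FALSE]
}
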