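#' Generate a synthetic cohort
#'
#' Draws baseline covariates from configured category marginals and a
#' residential region trajectory for every person across the full simulated
#' calendar (pre-baseline years included, so each baseline person-year has a
#' complete lagged exposure window). Region occupancy follows a Markov move
#' process: each calendar year a person moves with probability
#' `config$mobility_prob`, to a region drawn uniformly from the remaining
#' regions. The count of move events per person is recorded in `n_moves`.
#'
#' Survival columns (`event_time`, `event_cause`) are left `NA` until
#' [simulate_survival()] fills them.
#'
#' @param config A [sim_config()].
#' @param surfaces Pollutant surfaces from [generate_pollutant_surfaces()];
#'   used only to check region/year coverage.
#' @param covariate_marginals Category probabilities, as from
#'   [default_covariate_marginals()].
#' @return A data frame with one row per person: `person_id`, baseline
#'   covariates (factors), region occupancy columns `region_y1` ...
#'   `region_y<n_years>`, `n_moves`, and empty `event_time`/`event_cause`.
#' @export
generate_cohort <- function(config, surfaces,
                            covariate_marginals = default_covariate_marginals()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_persons
  R <- config$n_regions
  Y <- config$n_years
  if (R < 1) stop("region count must be positive")
  have <- unique(surfaces$region_id)
  if (!all(seq_len(R) %in% have) || max(surfaces$year) < Y) {
    stop("surfaces do not cover all configured regions/years")
  }
  set.seed(config$seed + 1L)

  draw <- function(p) factor(
    sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  cm <- covariate_marginals
  out <- data.frame(
    person_id = seq_len(n),
    age_group = draw(cm$age_group),
    sex = draw(cm$sex),
    airshed = draw(cm$airshed),
    popcentre = draw(cm$popcentre),
    education = draw(cm$education),
    income_quintile = draw(cm$income_quintile),
    labour_force = draw(cm$labour_force),
    marital = draw(cm$marital)
  )

  # region trajectories: year-1 occupancy already reflects a possible move
  # from the drawn home region, so each of the Y years carries one move draw
  home <- sample.int(R, n, replace = TRUE)
  regions <- matrix(0L, n, Y)
  moves <- matrix(stats::runif(n * Y) < config$mobility_prob, n, Y)
  cur <- home
  for (y in seq_len(Y)) {
    mv <- moves[, y]
    if (any(mv) && R > 1L) {
      new <- sample.int(R - 1L, sum(mv), replace = TRUE)
      old <- cur[mv]
      new <- new + (new >= old) # uniform over regions != current
      cur[mv] <- new
    }
    regions[, y] <- cur
  }
  colnames(regions) <- paste0("region_y", seq_len(Y))
  out <- cbind(out, as.data.frame(regions))
  out$n_moves <- as.integer(rowSums(moves))
  out$event_time <- NA_real_
  out$event_cause <- NA_character_
  out
}

#' Baseline age (years) implied by a cohort's age-group labels
#'
#' Midpoint of each person's 5-year baseline age group; used by the
#' exclusion rules.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @return Numeric vector of ages.
#' @export
baseline_age <- function(cohort) {
  lo <- as.numeric(sub("-.*", "", as.character(cohort$age_group)))
  lo + 2
}
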