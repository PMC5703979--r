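#' Lagged moving-average exposure assignment
#'
#' Assigns each person-year the mean concentration over a trailing window of
#' calendar years, lagged so the current year is excluded, and updated for
#' residential mobility: each contributing year uses the concentration of the
#' region the person occupied *that* year. With the defaults (window 3,
#' lag 1), the exposure at calendar year `t` is the mean over years
#' `t-3, t-2, t-1`. Assignments start at the first calendar year with a
#' complete window (`window_years + lag_years`); partial windows are never
#' averaged.
#'
#' Ox is averaged on the annual Ox series (equivalently, by linearity of
#' [compute_ox()], the Ox of the averaged gases).
#'
#' @param cohort Cohort data frame from [generate_cohort()] (needs the
#'   `region_y*` occupancy columns).
#' @param surfaces Pollutant surfaces from [generate_pollutant_surfaces()].
#' @param window_years Width of the averaging window (years).
#' @param lag_years Lag between the window and the index year.
#' @return Long data frame: `person_id`, `year`, `pm25`, `no2`, `o3`, `ox`
#'   (each a lagged moving average).
#' @export
lagged_moving_average <- function(cohort, surfaces, window_years = 3L,
                                  lag_years = 1L) {
  stopifnot(window_years >= 1, lag_years >= 0)
  reg_cols <- grep("^region_y", names(cohort))
  Y <- length(reg_cols)
  first_year <- window_years + lag_years
  if (first_year > Y) stop("occupancy history too short for the window")
  regions <- as.matrix(cohort[, reg_cols])
  n <- nrow(cohort)

  # per-pollutant region x year lookup (sized to cover occupancy too, so a
  # region or year absent from the surfaces shows up as NA, not an index
  # error)
  R <- max(surfaces$region_id, regions)
  lookup <- function(col) {
    m <- matrix(NA_real_, R, max(surfaces$year, Y))
    m[cbind(surfaces$region_id, surfaces$year)] <- surfaces[[col]]
    m
  }
  mats <- lapply(c(pm25 = "pm25", no2 = "no2", o3 = "o3", ox = "ox"), lookup)

  # annual exposure by occupancy: A[i, y] = conc in region occupied in year y
  annual <- lapply(mats, function(m) {
    a <- matrix(m[cbind(as.vector(regions), rep(seq_len(Y), each = n))], n, Y)
    a
  })
  if (anyNA(annual$pm25)) {
    bad <- which(is.na(annual$pm25), arr.ind = TRUE)[1, ]
    stop(sprintf("missing region-year concentration for person %s in year %d",
                 cohort$person_id[bad[1]], bad[2]))
  }

  years <- seq.int(first_year, Y)
  ma <- function(a) {
    out <- matrix(NA_real_, n, length(years))
    for (k in seq_along(years)) {
      win <- (years[k] - lag_years - window_years + 1L):(years[k] - lag_years)
      out[, k] <- rowMeans(a[, win, drop = FALSE])
    }
    out
  }
  data.frame(
    person_id = rep(cohort$person_id, times = length(years)),
    year = rep(years, each = n),
    pm25 = as.vector(ma(annual$pm25)),
    no2 = as.vector(ma(annual$no2)),
    o3 = as.vector(ma(annual$o3)),
    ox = as.vector(ma(annual$ox))
  )
}

#' Year adjustment of an annual concentration series
#'
#' Fits a cubic smoothing spline to one region's annual concentrations and
#' returns, for each year, the ratio between the spline value at a reference
#' year and at that year. The ratios reconstruct year-specific values from a
#' single reference-year concentration surface:
#' `value(t) = reference_value / ratio(t)`.
#'
#' @param years Integer vector of calendar years (at least 4 distinct).
#' @param values Annual concentrations, same length as `years`.
#' @param reference_year Year of the reference surface; must lie within the
#'   observed range (extrapolation is refused).
#' @param reference_value Concentration at the reference year to propagate;
#'   defaults to the observed value at `reference_year` (or the spline value
#'   if that year was not observed).
#' @return Data frame with `year`, `ratio` (spline(ref)/spline(t)) and
#'   `adjusted` (the reconstructed year-t concentration).
#' @export
year_adjust <- function(years, values, reference_year, reference_value = NULL) {
  if (length(unique(years)) < 4) {
    stop("year adjustment needs at least 4 annual values (cubic spline)")
  }
  stopifnot(length(years) == length(values))
  if (reference_year < min(years) || reference_year > max(years)) {
    stop("reference year lies outside the observed range; refusing to extrapolate")
  }
  fit <- stats::smooth.spline(years, values)
  f <- function(x) stats::predict(fit, x)$y
  f_ref <- f(reference_year)
  f_t <- f(years)
  if (any(f_t <= 0) || f_ref <= 0) {
    stop("fitted spline is non-positive; year-adjustment ratios undefined")
  }
  if (is.null(reference_value)) {
    hit <- which(years == reference_year)
    reference_value <- if (length(hit)) values[hit[1]] else f_ref
  }
  ratio <- f_ref / f_t
  data.frame(year = years, ratio = ratio, adjusted = reference_value / ratio)
}

#' Apply cohort exclusion rules
#'
#' Drops persons with baseline age below 25 or above 90, drops person-years
#' whose PM2.5 exposure estimate exceeds 20 µg/m³ (such estimates likely
#' reflect inaccurate retrievals; the person's other years are kept), and
#' then drops persons left with no assignable exposure. Idempotent.
#'
#' @param cohort Cohort data frame (needs `age_group`).
#' @param exposures Assigned exposures from [lagged_moving_average()].
#' @param age_range Inclusive baseline-age bounds, default `c(25, 90)`.
#' @param pm25_max Person-year PM2.5 ceiling (µg/m³).
#' @return List with filtered `cohort`, `exposures`, and a `tally` of drops
#'   per rule (`age_persons`, `pm25_person_years`, `no_exposure_persons`).
#' @export
apply_exclusions <- function(cohort, exposures, age_range = c(25, 90),
                             pm25_max = 20) {
  stopifnot("age_group" %in% names(cohort), "pm25" %in% names(exposures))
  age <- baseline_age(cohort)
  keep_age <- age >= age_range[1] & age <= age_range[2]
  tally <- list(age_persons = sum(!keep_age))
  cohort <- cohort[keep_age, , drop = FALSE]
  exposures <- exposures[exposures$person_id %in% cohort$person_id, ,
                         drop = FALSE]
  keep_py <- exposures$pm25 <= pm25_max
  tally$pm25_person_years <- sum(!keep_py)
  exposures <- exposures[keep_py, , drop = FALSE]
  has_exp <- cohort$person_id %in% unique(exposures$person_id)
  tally$no_exposure_persons <- sum(!has_exp)
  cohort <- cohort[has_exp, , drop = FALSE]
  list(cohort = cohort, exposures = exposures, tally = tally)
}

#' Reporting increment for an exposure distribution
#'
#' The interval all pollutant hazard ratios are expressed per: the mean minus
#' the empirical 5th percentile of the person-year exposure distribution.
#' The percentile uses linear interpolation between order statistics
#' (`quantile()` type 7).
#'
#' @param x Numeric vector of person-year exposures (at least two distinct
#'   values).
#' @param pollutant Optional label.
#' @return An object of class `increment`: `pollutant`, `delta`, `mean`,
#'   `p5`.
#' @export
reporting_increment <- function(x, pollutant = "exposure") {
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2) {
    stop("reporting increment undefined for a constant exposure column")
  }
  m <- mean(x)
  p5 <- unname(stats::quantile(x, 0.05, type = 7))
  delta <- m - p5
  if (delta <= 0) stop("reporting increment must be positive")
  structure(list(pollutant = pollutant, delta = delta, mean = m, p5 = p5),
            class = "increment")
}

#' @export
print.increment <- function(x, ...) {
  cat(sprintf("Reporting increment for %s: %.4g (mean %.4g - 5th pct %.4g)\n",
              x$pollutant, x$delta, x$mean, x$p5))
  invisible(x)
}
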