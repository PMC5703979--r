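#' Pollutant marginal target
#'
#' Bundles the summary statistics a simulated pollutant marginal should
#' reproduce: the 5th/25th/50th/75th/95th percentiles plus the minimum,
#' maximum and mean of the person-year concentration distribution.
#'
#' The generator turns these into a piecewise-linear quantile function with
#' knots at probabilities 0, .05, .25, .50, .75, .95, .995 and 1. The .995
#' knot sits at `p95 + tail_damp * (max - p95)`: an undamped linear segment
#' from the 95th percentile straight to the maximum would put far too much
#' mass in the extreme tail and inflate the mean (NO2 is the worst case,
#' with a maximum more than five times its mean).
#'
#' @param p5,p25,p50,p75,p95 Target percentiles (strictly increasing).
#' @param min,max Support endpoints; `min < p5`, `max > p95`.
#' @param mean Target mean; retained for reporting/calibration checks only
#'   (the quantile knots, not the mean, drive the simulation).
#' @param tail_damp Position of the .995 knot between `p95` and `max`.
#' @return An object of class `pollutant_marginal`.
#' @export
pollutant_marginal <- function(p5, p25, p50, p75, p95, min, max, mean = NA_real_,
                               tail_damp = 0.15) {
  q <- c(p5, p25, p50, p75, p95)
  if (any(diff(q) <= 0)) stop("percentile targets must be strictly increasing")
  if (!(min < p5)) stop("`min` must lie below the 5th percentile")
  if (!(max > p95)) stop("`max` must lie above the 95th percentile")
  if (min < 0) stop("pollutant concentrations cannot be negative")
  stopifnot(tail_damp > 0, tail_damp < 1)
  structure(
    list(p5 = p5, p25 = p25, p50 = p50, p75 = p75, p95 = p95,
         min = min, max = max, mean = mean, tail_damp = tail_damp),
    class = "pollutant_marginal"
  )
}

#' Default pollutant marginal targets
#'
#' Person-year concentration summaries for the four pollutants in a large
#' Canadian census-linked cohort: PM2.5 (µg/m³), O3, NO2 and Ox (ppb).
#' Ox is included for reference (its increment and calibration checks);
#' the generator never samples Ox directly — it is always derived from the
#' simulated NO2 and O3 via [compute_ox()].
#'
#' @return Named list of [pollutant_marginal()] objects
#'   (`pm25`, `o3`, `no2`, `ox`).
#' @export
default_pollutant_marginals <- function() {
  list(
    pm25 = pollutant_marginal(3.51, 5.37, 7.12, 9.07, 11.97,
                              min = 0.5, max = 20.00, mean = 7.37),
    o3 = pollutant_marginal(27.61, 33.66, 38.11, 42.63, 50.51,
                            min = 0.5, max = 60.46, mean = 38.29),
    no2 = pollutant_marginal(3.36, 6.44, 10.31, 15.10, 24.52,
                             min = 0.5, max = 64.78, mean = 11.47),
    ox = pollutant_marginal(20.41, 25.42, 29.57, 32.98, 37.76,
                            min = 0.5, max = 49.30, mean = 29.17)
  )
}

#' Increment implied by a marginal summary
#'
#' Applies the reporting-increment rule (mean minus 5th percentile, the
#' interval all pollutant hazard ratios are expressed per) to the summary
#' statistics stored in a [pollutant_marginal()].
#'
#' @param marginal A `pollutant_marginal`.
#' @return The increment `mean - p5`, in the pollutant's units.
#' @seealso [reporting_increment()] for the same rule applied to data.
#' @export
summary_increment <- function(marginal) {
  stopifnot(inherits(marginal, "pollutant_marginal"))
  if (is.na(marginal$mean)) stop("marginal has no target mean")
  marginal$mean - marginal$p5
}

# Piecewise-linear quantile function interpolating the marginal's knots.
# Returns a function mapping probabilities in [0,1] to concentrations.
marginal_qfun <- function(m) {
  hi <- m$p95 + m$tail_damp * (m$max - m$p95)
  probs <- c(0, 0.05, 0.25, 0.50, 0.75, 0.95, 0.995, 1)
  vals <- c(m$min, m$p5, m$p25, m$p50, m$p75, m$p95, hi, m$max)
  stats::approxfun(probs, vals, rule = 2)
}
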