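#' Parameters of the joint nonlinear PM2.5-Ox risk model
#'
#' The joint relative risk surface is
#' \deqn{R(PM_{2.5}, O_x) = \exp\{\theta(O_x) \, T(PM_{2.5})\},}
#' with a hinge in oxidant capacity,
#' \deqn{\theta(O_x) = \eta + \lambda (O_x - \omega)_+,}
#' (flat below the threshold \eqn{\omega}, linear above it) and a
#' shape-constrained transform of PM2.5,
#' \deqn{T(PM_{2.5}) = \log(\Im(PM_{2.5})) \Big/
#'   \big(1 + \exp(-(PM_{2.5} - \mu)/\pi)\big),}
#' where \eqn{\Im(z) = 1 + z} or \eqn{\Im(z) = e^z}. Depending on
#' \eqn{(\Im, \mu, \pi)} the transform spans supra-linear, near-linear,
#' sub-linear and sigmoidal concentration-response shapes. The model
#' redistributes PM2.5 risk across Ox levels; it carries no Ox main effect.
#'
#' @param eta Log relative risk per unit `T` at or below the threshold.
#' @param lam Change in theta per ppb of Ox above the threshold.
#' @param omega Ox threshold (ppb).
#' @param mu Logistic weight location (µg/m³).
#' @param pi_scale Logistic weight scale (µg/m³), strictly positive.
#' @param transform_variant `"1+z"` or `"exp"`.
#' @param logistic_weight If `FALSE`, the logistic weight is fixed at 1
#'   (so `"exp"` + no weight reduces `T` to the identity and the model to
#'   the standard log-linear form).
#' @return An object of class `schif_params`.
#' @export
schif_params <- function(eta = 0, lam = 0, omega = 0, mu = 5, pi_scale = 2,
                         transform_variant = c("1+z", "exp"),
                         logistic_weight = TRUE) {
  transform_variant <- match.arg(transform_variant)
  if (!is.numeric(pi_scale) || pi_scale <= 0) {
    stop("`pi_scale` must be strictly positive")
  }
  structure(
    list(eta = eta, lam = lam, omega = omega, mu = mu, pi_scale = pi_scale,
         transform_variant = transform_variant,
         logistic_weight = isTRUE(logistic_weight)),
    class = "schif_params"
  )
}

#' Shape-constrained PM2.5 transform
#'
#' Evaluates \eqn{T(PM_{2.5}) = \log(\Im(PM_{2.5}))} times the logistic
#' weight \eqn{1/(1 + \exp(-(PM_{2.5}-\mu)/\pi))}; see [schif_params()].
#' The logistic factor is evaluated via [stats::plogis()], so extreme
#' standardized arguments are handled without overflow.
#'
#' @param pm25 Non-negative PM2.5 concentrations (µg/m³).
#' @param params A [schif_params()] (only `mu`, `pi_scale`,
#'   `transform_variant`, `logistic_weight` are used).
#' @return Numeric vector, unitless.
#' @export
transform_T <- function(pm25, params) {
  stopifnot(inherits(params, "schif_params"))
  if (any(pm25 < 0, na.rm = TRUE)) stop("`pm25` must be non-negative")
  base <- switch(params$transform_variant,
                 "1+z" = log1p(pm25),
                 "exp" = pm25)
  if (!params$logistic_weight) return(base)
  base * stats::plogis((pm25 - params$mu) / params$pi_scale)
}

#' Hinge effect of oxidant capacity on the PM2.5 risk coefficient
#'
#' \eqn{\theta(O_x) = \eta + \lambda (O_x - \omega)_+}: below the threshold
#' Ox does not modify PM2.5 risk; above it, theta rises linearly. Continuous
#' at the threshold.
#'
#' @param ox Ox concentrations (ppb).
#' @param params A [schif_params()].
#' @return Numeric vector: the log relative risk per unit `T(PM2.5)`.
#' @export
theta_of_ox <- function(ox, params) {
  stopifnot(inherits(params, "schif_params"))
  params$eta + params$lam * pmax(ox - params$omega, 0)
}

#' Joint relative risk of PM2.5 at a given Ox concentration
#'
#' \eqn{R(PM_{2.5}, O_x) = \exp\{\theta(O_x) T(PM_{2.5})\}}. With the
#' `"1+z"` transform this is \eqn{(1 + PM_{2.5})^{\theta(O_x) w(PM_{2.5})}}
#' with `w` the logistic weight, so the risk is exactly 1 at zero exposure.
#'
#' @param pm25 Non-negative PM2.5 concentrations (µg/m³).
#' @param ox Ox concentrations (ppb); recycled against `pm25`.
#' @param params A [schif_params()].
#' @return Numeric vector of relative risks.
#' @export
relative_risk <- function(pm25, ox, params) {
  exp(theta_of_ox(ox, params) * transform_T(pm25, params))
}
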