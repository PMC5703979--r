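#' Fit the joint nonlinear PM2.5-Ox model by profile likelihood
#'
#' Estimates the joint risk model \eqn{R = \exp\{\theta(O_x) T(PM_{2.5})\}}
#' (see [schif_params()]) by exhaustive profiling over the non-linear
#' parameters: for each grid point \eqn{(\omega, \mu, \pi)} the model is
#' *linear* in \eqn{(\eta, \lambda)} given the two constructed covariates
#' \eqn{T(PM_{2.5})} and \eqn{(O_x - \omega)_+ T(PM_{2.5})}, so the inner
#' problem is an ordinary 2-coefficient stratified Cox fit (same code path
#' as [fit_cox()], hence the exact construction identity between the two
#' engines). The reported parameters attain the grid-minimum
#' `-2 log partial likelihood`; the full profile table is retained.
#'
#' Profiling makes the hinge non-smoothness harmless and is reproducible;
#' grid points whose inner fit fails are flagged in the profile table and
#' skipped, not fatal.
#'
#' @param data Person-year analysis table from [assemble_person_years()].
#' @param spec A [model_spec()] providing cause, covariates, strata and
#'   ties (its `terms`/`products` are ignored; the constructed covariates
#'   are the terms).
#' @param omega_grid Threshold grid (ppb); default: 5th to 95th percentile
#'   of the modifier in 0.25-ppb steps.
#' @param mu_grid,pi_grid Grids for the logistic location and scale
#'   (µg/m³); small documented defaults.
#' @param transform_variant,logistic_weight Passed to [schif_params()].
#' @param exposure,modifier Pollutant columns (defaults PM2.5, Ox).
#' @param include_hinge If `FALSE`, fixes `lambda = 0` (no Ox modification)
#'   and profiles over `(mu, pi)` only — the null/reduction model.
#' @return An object of class `joint_fit`: `params` (the grid-minimum
#'   [schif_params()]), `se` for `(eta, lam)`, `cov`, `neg2ll`, `profile`
#'   (data frame over the grid), `cox_fit` (the inner fit at the optimum),
#'   and the settings needed to re-fit on resampled data.
#' @export
fit_joint <- function(data, spec,
                      omega_grid = NULL,
                      mu_grid = c(2.5, 5, 10),
                      pi_grid = c(1, 2, 4),
                      transform_variant = c("1+z", "exp"),
                      logistic_weight = TRUE,
                      exposure = "pm25", modifier = "ox",
                      include_hinge = TRUE) {
  transform_variant <- match.arg(transform_variant)
  stopifnot(exposure %in% names(data), modifier %in% names(data))
  ox <- data[[modifier]]
  if (is.null(omega_grid)) {
    q <- stats::quantile(ox, c(0.05, 0.95), type = 7, names = FALSE)
    omega_grid <- seq(q[1], q[2], by = 0.25)
  }
  if (include_hinge) {
    if (!length(omega_grid)) stop("empty omega grid")
    if (all(omega_grid < min(ox)) || all(omega_grid > max(ox))) {
      stop("omega grid lies entirely outside the modifier support")
    }
  } else {
    omega_grid <- NA_real_
  }
  if (!length(mu_grid) || !length(pi_grid)) stop("empty mu/pi grid")

  # stratum computed once; the inner fits reuse it
  data$.joint_stratum <- if (length(spec$strata)) {
    interaction(data[spec$strata], drop = TRUE)
  } else factor(rep(1L, nrow(data)))
  inner_spec <- spec
  inner_spec$strata <- ".joint_stratum"
  inner_spec$products <- list()
  inner_spec$terms <- if (include_hinge) c(".T", ".hingeT") else ".T"

  grid <- expand.grid(omega = omega_grid, mu = mu_grid, pi_scale = pi_grid,
                      KEEP.OUT.ATTRS = FALSE)
  prof <- grid
  prof$neg2ll <- NA_real_
  prof$eta <- NA_real_
  prof$lam <- NA_real_
  prof$converged <- FALSE
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- schif_params(mu = grid$mu[i], pi_scale = grid$pi_scale[i],
                      transform_variant = transform_variant,
                      logistic_weight = logistic_weight)
    data$.T <- transform_T(data[[exposure]], p)
    if (include_hinge) {
      data$.hingeT <- pmax(ox - grid$omega[i], 0) * data$.T
    }
    fit <- tryCatch(fit_cox(data, inner_spec), error = function(e) NULL)
    if (is.null(fit)) next
    prof$neg2ll[i] <- fit$neg2ll
    prof$eta[i] <- fit$beta[[".T"]]
    prof$lam[i] <- if (include_hinge) fit$beta[[".hingeT"]] else 0
    prof$converged[i] <- fit$converged
    ok <- isTRUE(fit$converged) && is.finite(fit$neg2ll)
    if (ok && (is.null(best) || fit$neg2ll < best$fit$neg2ll)) {
      best <- list(fit = fit, i = i)
    }
  }
  if (is.null(best)) stop("no grid point produced a converged inner fit")
  i <- best$i
  fit <- best$fit
  params <- schif_params(
    eta = prof$eta[i], lam = prof$lam[i],
    omega = if (include_hinge) prof$omega[i] else -Inf,
    mu = prof$mu[i], pi_scale = prof$pi_scale[i],
    transform_variant = transform_variant, logistic_weight = logistic_weight
  )
  structure(
    list(params = params,
         se = fit$se[inner_spec$terms],
         cov = fit$cov[inner_spec$terms, inner_spec$terms, drop = FALSE],
         covariate_beta = fit$beta[setdiff(names(fit$beta), inner_spec$terms)],
         neg2ll = fit$neg2ll,
         profile = prof,
         cox_fit = fit,
         settings = list(spec = spec, omega_grid = omega_grid,
                         mu_grid = mu_grid, pi_grid = pi_grid,
                         transform_variant = transform_variant,
                         logistic_weight = logistic_weight,
                         exposure = exposure, modifier = modifier,
                         include_hinge = include_hinge),
         modifier_range = range(ox)),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  p <- x$params
  cat("Joint nonlinear PM2.5-Ox fit (profile likelihood)\n")
  cat(sprintf("  eta = %.5f, lambda = %.5f, omega = %.2f ppb\n",
              p$eta, p$lam, p$omega))
  cat(sprintf("  transform: %s, mu = %.2f, pi = %.2f, logistic weight: %s\n",
              p$transform_variant, p$mu, p$pi_scale, p$logistic_weight))
  cat(sprintf("  -2 log L = %.3f over %d grid points\n",
              x$neg2ll, nrow(x$profile)))
  invisible(x)
}

#' Nonparametric person-level bootstrap of a joint fit
#'
#' Resamples persons (whole follow-up histories) with replacement and
#' re-runs [fit_joint()] on each replicate with the original grids (grid
#' reuse), giving replicate draws of the full parameter vector including
#' the threshold — uncertainty that Wald intervals at a fixed threshold
#' would miss.
#'
#' @param fit A [fit_joint()] result.
#' @param data The person-year table the fit was run on (needs
#'   `person_id`).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return An object of class `joint_boot`: list of replicate
#'   [schif_params()] (failed replicates dropped), `B`, `n_failed`.
#' @export
joint_bootstrap <- function(fit, data, B = 200, seed = 1L) {
  stopifnot(inherits(fit, "joint_fit"), B >= 1, "person_id" %in% names(data))
  set.seed(seed)
  ids <- unique(data$person_id)
  rows_of <- split(seq_len(nrow(data)), data$person_id)
  s <- fit$settings
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    take <- sample(length(ids), replace = TRUE)
    idx <- unlist(rows_of[take], use.names = FALSE)
    d <- data[idx, , drop = FALSE]
    # resampled persons must stay distinct clusters
    d$person_id <- rep(seq_along(take),
                       times = lengths(rows_of[take]))
    rfit <- tryCatch(
      fit_joint(d, s$spec, omega_grid = s$omega_grid, mu_grid = s$mu_grid,
                pi_grid = s$pi_grid, transform_variant = s$transform_variant,
                logistic_weight = s$logistic_weight, exposure = s$exposure,
                modifier = s$modifier, include_hinge = s$include_hinge),
      error = function(e) NULL
    )
    reps[[b]] <- if (!is.null(rfit)) rfit$params
  }
  ok <- !vapply(reps, is.null, TRUE)
  structure(list(params = reps[ok], B = B, n_failed = sum(!ok)),
            class = "joint_boot")
}

check_boot_B <- function(B, level) {
  min_B <- ceiling(2 / (1 - level))
  if (B > 1 && B < min_B) {
    stop(sprintf(
      "B = %d replicates cannot support a %.0f%% percentile interval (need >= %d)",
      B, 100 * level, min_B))
  }
}

#' Theta profile across Ox with bootstrap uncertainty
#'
#' Evaluates the fitted hinge \eqn{\hat\theta(O_x) = \hat\eta +
#' \hat\lambda (O_x - \hat\omega)_+} over a grid of Ox values, with
#' pointwise percentile bounds from a person-level bootstrap. With a single
#' replicate the bounds degenerate to that replicate's curve. Bounds are
#' widened, where necessary, to bracket the central curve.
#'
#' @param fit A [fit_joint()] result.
#' @param ox_grid Ox values (ppb); default: 40 points across the modifier's
#'   observed range.
#' @param boot A [joint_bootstrap()] result; if `NULL`, one is computed
#'   (requires `data`).
#' @param data Person-year table (only needed when `boot` is `NULL`).
#' @param B,seed Bootstrap size and seed when `boot` is computed here.
#' @param level Interval level (default 0.95).
#' @return A data frame `ox`, `theta`, `lower`, `upper`, with the boot
#'   object attached as attribute `"boot"`.
#' @export
theta_profile_with_uncertainty <- function(fit, ox_grid = NULL, boot = NULL,
                                           data = NULL, B = 200, seed = 1L,
                                           level = 0.95) {
  stopifnot(inherits(fit, "joint_fit"))
  if (is.null(ox_grid)) {
    ox_grid <- seq(fit$modifier_range[1], fit$modifier_range[2],
                   length.out = 40)
  }
  if (is.null(boot)) {
    if (is.null(data)) stop("need `data` to run the bootstrap")
    check_boot_B(B, level)
    boot <- joint_bootstrap(fit, data, B = B, seed = seed)
  } else {
    check_boot_B(length(boot$params), level)
  }
  central <- theta_of_ox(ox_grid, fit$params)
  mat <- vapply(boot$params, function(p) theta_of_ox(ox_grid, p),
                numeric(length(ox_grid)))
  mat <- matrix(mat, nrow = length(ox_grid))
  alpha <- (1 - level) / 2
  lower <- apply(mat, 1, stats::quantile, probs = alpha, type = 7)
  upper <- apply(mat, 1, stats::quantile, probs = 1 - alpha, type = 7)
  out <- data.frame(ox = ox_grid, theta = central,
                    lower = pmin(lower, central),
                    upper = pmax(upper, central))
  attr(out, "boot") <- boot
  attr(out, "level") <- level
  out
}

#' Mean Ox in the first and tenth deciles of the person-year distribution
#'
#' The two Ox values the predicted risk curves are drawn at by default:
#' the mean within the lowest and highest deciles of the analysis-table Ox
#' distribution.
#'
#' @param data Person-year analysis table.
#' @param modifier Modifier column (default `"ox"`).
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @export
default_ox_values <- function(data, modifier = "ox") {
  x <- data[[modifier]]
  q <- stats::quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
  c(low = mean(x[x <= q[1]]), high = mean(x[x >= q[2]]))
}

#' Predicted PM2.5 risk curve at a fixed Ox concentration
#'
#' Evaluates the fitted joint relative risk \eqn{R(PM_{2.5}, O_x)} along a
#' PM2.5 grid at one Ox value, with pointwise bootstrap percentile bounds
#' when a [joint_bootstrap()] is supplied. An Ox value far outside the
#' modifier's observed support is allowed but noted in the result.
#'
#' @param fit A [fit_joint()] result.
#' @param ox_value Ox concentration (ppb); see [default_ox_values()] for
#'   the conventional choices.
#' @param pm25_grid PM2.5 grid (µg/m³); default: 60 points from 0 to 20.
#' @param boot Optional [joint_bootstrap()] for uncertainty bounds.
#' @param level Interval level.
#' @return A data frame `pm25`, `rr`, `lower`, `upper` with attributes
#'   `ox_value` and (possibly) `note`.
#' @export
predict_risk_curve <- function(fit, ox_value, pm25_grid = NULL, boot = NULL,
                               level = 0.95) {
  stopifnot(inherits(fit, "joint_fit"), length(ox_value) == 1L)
  if (is.null(pm25_grid)) pm25_grid <- seq(0, 20, length.out = 60)
  central <- relative_risk(pm25_grid, ox_value, fit$params)
  lower <- upper <- central
  if (!is.null(boot)) {
    check_boot_B(length(boot$params), level)
    mat <- vapply(boot$params, function(p) relative_risk(pm25_grid, ox_value, p),
                  numeric(length(pm25_grid)))
    mat <- matrix(mat, nrow = length(pm25_grid))
    alpha <- (1 - level) / 2
    lower <- pmin(apply(mat, 1, stats::quantile, probs = alpha, type = 7),
                  central)
    upper <- pmax(apply(mat, 1, stats::quantile, probs = 1 - alpha, type = 7),
                  central)
  }
  out <- data.frame(pm25 = pm25_grid, rr = central, lower = lower,
                    upper = upper)
  attr(out, "ox_value") <- ox_value
  r <- fit$modifier_range
  if (ox_value < r[1] - diff(r) * 0.25 || ox_value > r[2] + diff(r) * 0.25) {
    attr(out, "note") <- sprintf(
      "ox_value %.2f lies far outside the modifier support [%.2f, %.2f]",
      ox_value, r[1], r[2])
  }
  out
}
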