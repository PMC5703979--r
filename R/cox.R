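#' Specify a stratified proportional-hazards model
#'
#' Describes one Cox analysis of the person-year table: the cause of death,
#' the exposure terms (numeric columns, optionally products of two columns),
#' the categorical adjustment covariates, the stratification (separate
#' baseline hazards, shared coefficients) and the tie-handling convention.
#'
#' @param cause `"nonaccidental"`, `"cardiovascular"` or `"respiratory"`;
#'   selects the event indicator column.
#' @param terms Character vector of numeric exposure columns.
#' @param products List of length-2 character vectors; each adds a product
#'   term named `"<a>_x_<b>"`.
#' @param covariates Character vector of categorical adjustment columns.
#' @param strata Character vector of columns whose cross defines the strata
#'   (default: age group, sex, airshed, population-centre size). Empty for an
#'   unstratified fit.
#' @param ties `"breslow"` (default, matching the package's partial-likelihood
#'   oracle) or `"efron"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(cause = c("nonaccidental", "cardiovascular", "respiratory"),
                       terms = "pm25",
                       products = list(),
                       covariates = character(),
                       strata = c("age_group", "sex", "airshed", "popcentre"),
                       ties = c("breslow", "efron")) {
  cause <- match.arg(cause)
  ties <- match.arg(ties)
  prod_names <- vapply(products, function(p) paste(p, collapse = "_x_"), "")
  all_terms <- c(terms, prod_names)
  if (anyDuplicated(all_terms)) stop("model terms must be unique")
  structure(
    list(cause = cause, terms = terms, products = products,
         covariates = covariates, strata = strata, ties = ties),
    class = "model_spec"
  )
}

# Materialize product columns and the stratum factor; returns the augmented
# data and the vector of coefficient-bearing term names.
prepare_model_frame <- function(data, spec) {
  term_cols <- spec$terms
  for (p in spec$products) {
    nm <- paste(p, collapse = "_x_")
    missing_in <- setdiff(p, names(data))
    if (length(missing_in)) stop("missing product component: ", missing_in[1])
    data[[nm]] <- data[[p[1]]] * data[[p[2]]]
    term_cols <- c(term_cols, nm)
  }
  need <- c(term_cols, spec$covariates, spec$strata)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("columns absent from analysis table: ",
         paste(missing_cols, collapse = ", "))
  }
  for (v in term_cols) {
    if (stats::var(data[[v]], na.rm = TRUE) == 0) {
      stop("term `", v, "` is degenerate (zero variance)")
    }
  }
  X <- as.matrix(data[term_cols])
  if (qr(X)$rank < ncol(X)) {
    stop("collinear exposure terms: ", paste(term_cols, collapse = ", "))
  }
  data$.stratum <- if (length(spec$strata)) {
    interaction(data[spec$strata], drop = TRUE)
  } else {
    factor(rep(1L, nrow(data)))
  }
  list(data = data, term_cols = term_cols)
}

#' Fit a stratified Cox proportional-hazards model
#'
#' Maximizes the stratified partial likelihood on the counting-process
#' person-year table (follow-up time is the timescale; each stratum
#' contributes an independent set of risk sets), with Breslow tie handling
#' by default. Estimation is delegated to [survival::coxph()]; this wrapper
#' owns the model-frame construction, degeneracy/collinearity guards, the
#' convergence report and the extraction of the `-2 log L` statistic the
#' model-sequence tables report.
#'
#' Strata without events contribute nothing to the partial likelihood and
#' are retained harmlessly. A monotone likelihood (risk-set separation)
#' is reported through `converged = FALSE` and a `diverged` flag rather
#' than an error.
#'
#' @param data Person-year analysis table from [assemble_person_years()]
#'   (needs `tstart`, `tstop` and the relevant `event_*` column).
#' @param spec A [model_spec()].
#' @return An object of class `cox_fit`: `beta`, `se`, `cov`, `neg2ll`,
#'   `n_events`, `n_persons`, `n_rows`, `converged`, `diverged`,
#'   `term_cols`, `spec`.
#' @export
fit_cox <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  ev_col <- paste0("event_", spec$cause)
  if (!ev_col %in% names(data)) stop("no event column `", ev_col, "`")
  if (sum(data[[ev_col]]) < 1) stop("no events for cause ", spec$cause)
  pf <- prepare_model_frame(data, spec)
  d <- pf$data
  d$.event <- d[[ev_col]]

  rhs <- c(pf$term_cols, spec$covariates, "survival::strata(.stratum)")
  fml <- stats::as.formula(
    paste("survival::Surv(tstart, tstop, .event) ~", paste(rhs, collapse = " + "))
  )
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = spec$ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    aliased <- names(beta)[is.na(beta)]
    if (any(aliased %in% pf$term_cols)) {
      stop("collinear model terms (aliased coefficients): ",
           paste(intersect(aliased, pf$term_cols), collapse = ", "))
    }
    # sparse-data aliasing of adjustment-covariate levels: drop and record
    warns <- c(warns, paste("aliased covariate levels dropped:",
                            paste(aliased, collapse = ", ")))
    beta <- beta[!is.na(beta)]
  }
  # divergence is judged on the exposure terms: a monotone likelihood in a
  # sparse covariate level is routine and does not invalidate the fit
  term_beta <- beta[intersect(names(beta), pf$term_cols)]
  diverged <- any(abs(term_beta) > 12)
  V <- as.matrix(stats::vcov(fit))[names(beta), names(beta), drop = FALSE]
  structure(
    list(beta = beta,
         se = sqrt(diag(V)),
         cov = V,
         neg2ll = -2 * fit$loglik[length(fit$loglik)],
         neg2ll_null = -2 * fit$loglik[1],
         n_events = sum(d$.event),
         n_persons = length(unique(d$person_id %||% seq_len(nrow(d)))),
         n_rows = nrow(d),
         iterations = fit$iter,
         converged = !diverged && fit$iter < 50 &&
           is.finite(fit$loglik[length(fit$loglik)]),
         diverged = diverged,
         warnings = warns,
         term_cols = pf$term_cols,
         spec = spec),
    class = "cox_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox fit (%s, ties = %s): %d events / %d rows\n",
              x$spec$cause, x$spec$ties, x$n_events, x$n_rows))
  tab <- data.frame(beta = x$beta, se = x$se, hr = exp(x$beta))
  print(round(tab, 5))
  cat(sprintf("-2 log L = %.3f%s\n", x$neg2ll,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Hazard ratio over a reporting increment
#'
#' Scales a fitted log-hazard coefficient to the reporting increment:
#' `HR = exp(beta * delta)`, with a 95% normal-approximation confidence
#' interval on the log scale, `exp((beta +/- 1.96 se) * delta)`.
#'
#' @param fit A [fit_cox()] result.
#' @param term Name of the coefficient.
#' @param delta The increment, either a number or a [reporting_increment()]
#'   object.
#' @param level Confidence level (default 0.95).
#' @return A one-row data frame: `term`, `delta`, `hr`, `ci_low`, `ci_high`.
#' @export
hr_for_increment <- function(fit, term, delta, level = 0.95) {
  stopifnot(inherits(fit, "cox_fit"))
  if (inherits(delta, "increment")) delta <- delta$delta
  if (!term %in% names(fit$beta)) {
    stop("term `", term, "` not in the fitted model")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$beta[[term]]
  s <- fit$se[[term]]
  lo <- exp((b - z * s) * delta)
  hi <- exp((b + z * s) * delta)
  data.frame(term = term, delta = delta, hr = exp(b * delta),
             ci_low = min(lo, hi), ci_high = max(lo, hi))
}

# Tertile assignment with boundary values going to the lower tertile.
tertile_of <- function(x) {
  if (length(unique(x)) < 3) stop("modifier needs at least 3 distinct values")
  q <- stats::quantile(x, c(1, 2) / 3, type = 7, names = FALSE)
  1L + (x > q[1]) + (x > q[2])
}

#' Per-tertile hazard ratios of an exposure across a modifier
#'
#' Splits the person-year table by tertiles of a modifier (cut points from
#' the person-year distribution; boundary values fall to the lower tertile),
#' refits the exposure model within each disjoint subset, and reports the
#' exposure hazard ratio per tertile, all scaled to the same increment
#' computed from the full table (so the three HRs are directly comparable).
#'
#' @param data Person-year analysis table.
#' @param spec A [model_spec()] whose first term is the exposure of interest.
#' @param modifier Column to form tertiles of (default `"ox"`).
#' @return A list: `hr_table` (tertile, n rows, events, mean modifier, HR
#'   with CI), `fits`, `cutpoints`, `increment`.
#' @export
fit_tertile_series <- function(data, spec, modifier = "ox") {
  stopifnot(modifier %in% names(data))
  tert <- tertile_of(data[[modifier]])
  inc <- reporting_increment(data[[spec$terms[1]]], spec$terms[1])
  fits <- vector("list", 3)
  rows <- vector("list", 3)
  for (k in 1:3) {
    sub <- data[tert == k, , drop = FALSE]
    if (!nrow(sub)) stop("empty tertile ", k, " of ", modifier)
    fits[[k]] <- fit_cox(sub, spec)
    hr <- hr_for_increment(fits[[k]], spec$terms[1], inc)
    rows[[k]] <- data.frame(
      tertile = k,
      n = nrow(sub),
      events = fits[[k]]$n_events,
      modifier_mean = mean(sub[[modifier]]),
      hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high
    )
  }
  list(hr_table = do.call(rbind, rows), fits = fits,
       cutpoints = stats::quantile(data[[modifier]], c(1, 2) / 3, type = 7),
       increment = inc)
}

#' Joint-tertile hazard-ratio surface
#'
#' One model with indicator terms for the 3 x 3 cross of exposure and
#' modifier tertiles, reference cell (lowest exposure, lowest modifier);
#' the fitted surface is `exp(beta)` per cell, 1 at the reference.
#'
#' @param data Person-year analysis table.
#' @param spec A [model_spec()] providing cause, covariates, strata and ties
#'   (its `terms` are ignored; the indicators are the terms).
#' @param exposure,modifier Columns to form tertiles of.
#' @return A list: `hr` (3 x 3 matrix, rows = exposure tertile, cols =
#'   modifier tertile), `fit`, `counts`.
#' @export
fit_joint_tertile_grid <- function(data, spec, exposure = "pm25",
                                   modifier = "ox") {
  te <- tertile_of(data[[exposure]])
  tm <- tertile_of(data[[modifier]])
  counts <- table(factor(te, 1:3), factor(tm, 1:3))
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty tertile cell (%s tertile %d, %s tertile %d)",
                 exposure, empty[1], modifier, empty[2]))
  }
  cells <- expand.grid(e = 1:3, m = 1:3)[-1, ] # all but reference (1,1)
  nms <- sprintf("cell_%d_%d", cells$e, cells$m)
  for (i in seq_len(nrow(cells))) {
    data[[nms[i]]] <- as.integer(te == cells$e[i] & tm == cells$m[i])
  }
  spec2 <- spec
  spec2$terms <- nms
  spec2$products <- list()
  fit <- fit_cox(data, spec2)
  hr <- matrix(1, 3, 3, dimnames = list(exposure = 1:3, modifier = 1:3))
  hr[cbind(cells$e, cells$m)] <- exp(fit$beta[nms])
  list(hr = hr, fit = fit, counts = counts)
}

#' The potentiation model sequence
#'
#' Fits, on the same table and under the same adjustment and stratification,
#' the five-model sequence used to examine whether the modifier potentiates
#' the exposure effect: exposure alone; exposure + modifier; product alone;
#' exposure + product; exposure + modifier + product. Reports each model's
#' `-2 log L` and its hazard ratios, pollutant terms scaled to their
#' mean-minus-5th-percentile increments and the product term per
#' `product_scale` (default 100 ppb*µg/m³).
#'
#' @param data Person-year analysis table.
#' @param spec A [model_spec()] providing cause, covariates, strata, ties.
#' @param exposure,modifier Pollutant columns (defaults PM2.5 and Ox).
#' @param product_scale Increment for the product term.
#' @return A list: `table` (one row per model term with scaled HR, CI and
#'   the model's `-2 log L`), `fits` (named list of five [fit_cox()]
#'   results), `increments`.
#' @export
model_sequence <- function(data, spec, exposure = "pm25", modifier = "ox",
                           product_scale = 100) {
  incs <- list(
    reporting_increment(data[[exposure]], exposure),
    reporting_increment(data[[modifier]], modifier)
  )
  names(incs) <- c(exposure, modifier)
  prod_nm <- paste(exposure, modifier, sep = "_x_")
  deltas <- c(incs[[exposure]]$delta, incs[[modifier]]$delta, product_scale)
  names(deltas) <- c(exposure, modifier, prod_nm)

  defs <- list(
    list(label = exposure, terms = exposure, products = list()),
    list(label = paste(exposure, "+", modifier),
         terms = c(exposure, modifier), products = list()),
    list(label = paste0(exposure, "*", modifier),
         terms = character(), products = list(c(exposure, modifier))),
    list(label = paste(exposure, "+", paste0(exposure, "*", modifier)),
         terms = exposure, products = list(c(exposure, modifier))),
    list(label = paste(exposure, "+", modifier, "+",
                       paste0(exposure, "*", modifier)),
         terms = c(exposure, modifier), products = list(c(exposure, modifier)))
  )
  fits <- list()
  rows <- list()
  for (i in seq_along(defs)) {
    s <- spec
    s$terms <- defs[[i]]$terms
    s$products <- defs[[i]]$products
    fit <- fit_cox(data, s)
    fits[[defs[[i]]$label]] <- fit
    for (tc in fit$term_cols) {
      hr <- hr_for_increment(fit, tc, deltas[[tc]])
      rows[[length(rows) + 1L]] <- data.frame(
        model = defs[[i]]$label, term = tc, delta = deltas[[tc]],
        hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high,
        neg2ll = fit$neg2ll
      )
    }
  }
  list(table = do.call(rbind, rows), fits = fits, increments = incs)
}
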