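# From-scratch Breslow partial likelihood for small right-censored tables,
# written directly from the definition (risk sets enumerated row by row).
# Independent of the fitting code: used as the oracle for the Cox engine.
#
# data: data.frame with columns time, event (0/1), stratum (optional),
#       and the covariate columns named in `terms`.
breslow_loglik <- function(beta, data, terms) {
  if (is.null(data$stratum)) data$stratum <- 1L
  X <- as.matrix(data[terms])
  eta <- drop(X %*% beta)
  ll <- 0
  for (s in unique(data$stratum)) {
    rows <- which(data$stratum == s)
    for (i in rows[data$event[rows] == 1]) {
      at_risk <- rows[data$time[rows] >= data$time[i]]
      ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
    }
  }
  ll
}

# Grid-search maximizer of the oracle likelihood (1 or 2 coefficients).
breslow_grid_mle <- function(data, terms, lower = -3, upper = 3, n = 241) {
  grid <- seq(lower, upper, length.out = n)
  if (length(terms) == 1) {
    ll <- vapply(grid, function(b) breslow_loglik(b, data, terms), 0)
    best <- grid[which.max(ll)]
    # refine around the best point
    fine <- seq(best - 0.1, best + 0.1, length.out = 2001)
    llf <- vapply(fine, function(b) breslow_loglik(b, data, terms), 0)
    list(beta = fine[which.max(llf)], loglik = max(llf))
  } else {
    stop("grid oracle implemented for a single coefficient")
  }
}

# Counting-process wrapper: turn a simple (time, event) toy into the
# analysis-table layout fit_cox() expects.
toy_analysis_table <- function(time, event, ..., stratum = NULL) {
  covs <- list(...)
  d <- data.frame(person_id = seq_along(time), tstart = 0, tstop = time,
                  event_nonaccidental = event)
  for (nm in names(covs)) d[[nm]] <- covs[[nm]]
  d$stratum_var <- if (is.null(stratum)) factor(rep(1, length(time))) else factor(stratum)
  d
}

toy_spec <- function(terms, ...) {
  model_spec(cause = "nonaccidental", terms = terms, covariates = character(),
             strata = "stratum_var", ...)
}
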