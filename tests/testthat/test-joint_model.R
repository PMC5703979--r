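test_that("the PM2.5 transform evaluates its closed forms", {
  p <- schif_params(mu = 10, pi_scale = 2)
  # log(1) = 0 at zero exposure regardless of the weight
  expect_equal(transform_T(0, p), 0)
  expect_equal(transform_T(0, schif_params(mu = -3, pi_scale = 1)), 0)
  # direct arithmetic at the logistic midpoint: log(11)/2
  expect_equal(transform_T(10, p), log(11) / 2, tolerance = 1e-10)
  expect_equal(round(transform_T(10, p), 5), 1.19895)
  # saturated weight recovers log(1 + pm)
  sat <- schif_params(mu = -1000, pi_scale = 2)
  expect_equal(transform_T(c(1, 5, 15), sat), log1p(c(1, 5, 15)),
               tolerance = 1e-8)
  # numerically stable far from the location
  expect_true(all(is.finite(transform_T(c(0, 1e4), schif_params(mu = 5000,
                                                                pi_scale = 0.01)))))
  expect_error(schif_params(pi_scale = 0), "positive")
  expect_error(transform_T(-1, p), "non-negative")
})

test_that("T is monotone non-decreasing on the 1+z branch", {
  for (mu in c(0, 5, 12)) {
    p <- schif_params(mu = mu, pi_scale = 2)
    grid <- seq(0, 20, by = 0.05)
    expect_true(all(diff(transform_T(grid, p)) >= -1e-12))
  }
})

test_that("the hinge in Ox is continuous, flat below and linear above", {
  p <- schif_params(eta = 0.02, lam = 0.003, omega = 23.71)
  expect_equal(theta_of_ox(23.71, p), 0.02)                # exactly eta at omega
  expect_equal(theta_of_ox(33.71, p), 0.05)                # eta + lam * 10
  expect_equal(theta_of_ox(c(5, 15, 23.70), p), rep(0.02, 3)) # flat below
  # continuity at the threshold
  expect_equal(theta_of_ox(23.71 + 1e-10, p), theta_of_ox(23.71 - 1e-10, p),
               tolerance = 1e-9)
  # no modification when lambda is zero
  p0 <- schif_params(eta = 0.04, lam = 0, omega = 25)
  expect_equal(theta_of_ox(c(10, 25, 40), p0), rep(0.04, 3))
})

test_that("the joint relative risk matches its closed form", {
  p <- schif_params(eta = 0.05, lam = 0, omega = 0, logistic_weight = FALSE)
  # weight = 1: (1 + pm)^theta
  expect_equal(relative_risk(9, 30, p), 10^0.05, tolerance = 1e-12)
  expect_equal(relative_risk(0, 30, p), 1)
  # theta = 0 gives unit risk everywhere
  null <- schif_params(eta = 0, lam = 0)
  expect_equal(relative_risk(c(0, 5, 20), 35, null), rep(1, 3))
  # continuity in ox across the threshold
  ph <- schif_params(eta = 0.03, lam = 0.01, omega = 24)
  expect_equal(relative_risk(10, 24 + 1e-9, ph), relative_risk(10, 24, ph),
               tolerance = 1e-7)
})

test_that("a single grid point reduces fit_joint to fit_cox on the
           constructed covariates", {
  dat <- sim_analysis_table()
  py <- dat$py
  spec <- model_spec(cause = "nonaccidental", covariates = adj_covariates)
  jf <- fit_joint(py, spec, omega_grid = 26, mu_grid = 5, pi_grid = 2)
  # hand-constructed covariates through the public transform
  p <- schif_params(mu = 5, pi_scale = 2)
  py$.T <- transform_T(py$pm25, p)
  py$.hingeT <- pmax(py$ox - 26, 0) * py$.T
  spec2 <- spec
  spec2$terms <- c(".T", ".hingeT")
  ref <- fit_cox(py, spec2)
  expect_equal(jf$neg2ll, ref$neg2ll, tolerance = 1e-10)
  expect_equal(jf$params$eta, ref$beta[[".T"]], tolerance = 1e-10)
  expect_equal(jf$params$lam, ref$beta[[".hingeT"]], tolerance = 1e-10)
  expect_equal(jf$params$omega, 26)
})

test_that("with unit weight, exponential transform and no hinge the joint
           model is the log-linear Cox model", {
  dat <- sim_analysis_table()
  py <- dat$py
  spec <- model_spec(cause = "nonaccidental", covariates = adj_covariates)
  jf <- fit_joint(py, spec, mu_grid = 1, pi_grid = 1,
                  transform_variant = "exp", logistic_weight = FALSE,
                  include_hinge = FALSE)
  ref <- fit_cox(py, model_spec(cause = "nonaccidental", terms = "pm25",
                                covariates = adj_covariates))
  expect_equal(jf$params$eta, ref$beta[["pm25"]], tolerance = 1e-8)
  expect_equal(jf$params$lam, 0)
  expect_equal(jf$neg2ll, ref$neg2ll, tolerance = 1e-8)
})

test_that("grid profiling recovers a strong planted threshold", {
  strong <- true_hazard(lam = 0.04, covariate_log_hrs = list())
  dat <- sim_analysis_table(n_persons = 10000, seed = 13, true_params = strong)
  spec <- model_spec(cause = "nonaccidental")
  jf <- fit_joint(dat$py, spec, omega_grid = seq(20, 32, by = 0.5),
                  mu_grid = 5, pi_grid = 2)
  # single-cohort smoke bound; the 20-seed recovery study asserts the
  # tight median error
  expect_lt(abs(jf$params$omega - 24), 6)
  expect_gt(jf$params$lam, 0)
  expect_gt(jf$params$lam / jf$se[[".hingeT"]], 2)
  # profile covers the full grid and the reported minimum is the grid minimum
  expect_equal(nrow(jf$profile), length(seq(20, 32, by = 0.5)))
  expect_equal(jf$neg2ll, min(jf$profile$neg2ll[jf$profile$converged]))
  # an off-support grid is refused
  expect_error(fit_joint(dat$py, spec, omega_grid = c(200, 300)),
               "outside the modifier support")
})

test_that("theta profile has a single knee at the estimated threshold and
           degenerate bootstraps behave as documented", {
  strong <- true_hazard(lam = 0.04, covariate_log_hrs = list())
  dat <- sim_analysis_table(n_persons = 10000, seed = 13, true_params = strong)
  spec <- model_spec(cause = "nonaccidental")
  jf <- fit_joint(dat$py, spec, omega_grid = seq(21, 29, by = 1),
                  mu_grid = 5, pi_grid = 2)
  ox <- seq(18, 40, by = 0.5)
  th <- theta_of_ox(ox, jf$params)
  # piecewise linear: curvature only where the grid straddles omega-hat
  curv <- abs(diff(diff(th)))
  knee <- which(curv > 1e-12)
  expect_lte(length(knee), 1)
  if (length(knee)) {
    expect_lt(abs(ox[knee + 1] - jf$params$omega), 0.5 + 1e-9)
  }
  # too few replicates for the requested interval fails loudly
  expect_error(
    theta_profile_with_uncertainty(jf, ox, data = dat$py, B = 5),
    "replicates"
  )
  # B = 1: bounds collapse onto the single replicate curve
  b1 <- joint_bootstrap(jf, dat$py, B = 1, seed = 4)
  pr <- theta_profile_with_uncertainty(jf, ox, boot = b1)
  rep_curve <- theta_of_ox(ox, b1$params[[1]])
  expect_equal(pr$lower, pmin(rep_curve, pr$theta))
  expect_equal(pr$upper, pmax(rep_curve, pr$theta))
  # bounds always bracket the central curve
  expect_true(all(pr$lower <= pr$theta & pr$theta <= pr$upper))
})

test_that("risk curves are anchored at 1, flat in ox below the threshold and
           ordered under potentiation", {
  strong <- true_hazard(lam = 0.04, covariate_log_hrs = list())
  dat <- sim_analysis_table(n_persons = 10000, seed = 13, true_params = strong)
  spec <- model_spec(cause = "nonaccidental")
  jf <- fit_joint(dat$py, spec, omega_grid = seq(21, 29, by = 1),
                  mu_grid = 5, pi_grid = 2)
  om <- jf$params$omega
  below <- predict_risk_curve(jf, om - 3)
  at <- predict_risk_curve(jf, om)
  expect_equal(below$rr, at$rr) # hinge is flat below the threshold
  expect_equal(below$rr[below$pm25 == 0], 1)
  high <- predict_risk_curve(jf, om + 10)
  expect_true(all(high$rr[-1] > at$rr[-1])) # potentiated curve dominates
  expect_equal(high$rr[1], 1)               # but both start at RR = 1
  # far-out-of-support ox values are noted
  far <- predict_risk_curve(jf, 120)
  expect_match(attr(far, "note"), "outside")
  # decile-mean defaults straddle the bulk of the Ox distribution
  oxv <- default_ox_values(dat$py)
  expect_lt(oxv[["low"]], quantile(dat$py$ox, 0.2))
  expect_gt(oxv[["high"]], quantile(dat$py$ox, 0.8))
})

test_that("bootstrap intervals widen around the central theta curve", {
  # small table, coarse grid: keeps the refits cheap
  dat <- sim_analysis_table(n_persons = 2500, seed = 23)
  spec <- model_spec(cause = "nonaccidental")
  jf <- fit_joint(dat$py, spec, omega_grid = seq(22, 30, by = 2),
                  mu_grid = 5, pi_grid = 2)
  boot <- joint_bootstrap(jf, dat$py, B = 12, seed = 6)
  expect_lte(boot$n_failed, 2)
  pr <- theta_profile_with_uncertainty(jf, seq(20, 38, by = 2), boot = boot,
                                       level = 0.8)
  expect_true(all(pr$lower <= pr$theta & pr$theta <= pr$upper))
  expect_gt(mean(pr$upper - pr$lower), 0)
})
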