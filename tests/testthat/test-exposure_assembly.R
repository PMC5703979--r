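test_that("compute_ox reproduces the redox-weighted average", {
  # mean NO2 and O3 of the reference cohort give the reference mean Ox
  expect_equal(round(compute_ox(11.47, 38.29), 2), 29.17)
  # weights sum to the denominator, so equal inputs are a fixed point
  for (c in c(0, 1, 17.3, 100)) expect_equal(compute_ox(c, c), c)
  # direct arithmetic with one gas absent
  expect_equal(round(compute_ox(64.78, 0), 2), round(1.07 * 64.78 / 3.145, 2))
  expect_equal(round(compute_ox(64.78, 0), 2), 22.04)
})

test_that("compute_ox rejects bad input", {
  expect_error(compute_ox(-1, 10), "negative")
  expect_error(compute_ox(10, -1), "negative")
  expect_error(compute_ox(c(1, 2), c(1, 2, 3)), "length")
  expect_error(compute_ox(NA, 3), "missing")
})

test_that("compute_ox is a linear convex combination", {
  set.seed(1)
  no2 <- runif(50, 0, 60)
  o3 <- runif(50, 0, 60)
  ox <- compute_ox(no2, o3)
  # convexity: bounded by the two inputs
  expect_true(all(ox >= pmin(no2, o3) - 1e-12))
  expect_true(all(ox <= pmax(no2, o3) + 1e-12))
  # linearity: Ox of the mean equals the mean of Ox
  expect_equal(compute_ox(mean(no2), mean(o3)), mean(ox))
})

test_that("lagged moving average uses the region occupied in each window year", {
  # 2 regions, 5 years; person in region 1 for years 1-2, region 2 after
  surf <- data.frame(
    region_id = rep(1:2, times = 5),
    year = rep(1:5, each = 2),
    pm25 = rep(c(10, 16), times = 5),
    no2 = 8, o3 = 30
  )
  surf$ox <- compute_ox(surf$no2, surf$o3)
  coh <- data.frame(person_id = 1L,
                    region_y1 = 1L, region_y2 = 1L, region_y3 = 2L,
                    region_y4 = 2L, region_y5 = 2L)
  out <- lagged_moving_average(coh, surf, window_years = 3, lag_years = 1)
  # year 4 window = years 1..3: regions 1,1,2 -> (10+10+16)/3
  expect_equal(out$pm25[out$year == 4], (10 + 10 + 16) / 3)
  # year 5 window = years 2..4: regions 1,2,2 -> (10+16+16)/3
  expect_equal(out$pm25[out$year == 5], (10 + 16 + 16) / 3)
  # assignments only where the full window exists
  expect_equal(sort(unique(out$year)), 4:5)
})

test_that("window 1 / lag 0 reduces to the same-year concentration and a
           constant field averages to itself", {
  surf <- expand.grid(region_id = 1:3, year = 1:4)
  surf$pm25 <- ifelse(surf$region_id == 2, 7, 3)
  surf$no2 <- 5; surf$o3 <- 5
  surf$ox <- compute_ox(surf$no2, surf$o3)
  coh <- data.frame(person_id = 1:2,
                    region_y1 = c(1L, 2L), region_y2 = c(2L, 2L),
                    region_y3 = c(1L, 2L), region_y4 = c(3L, 2L))
  ident <- lagged_moving_average(coh, surf, window_years = 1, lag_years = 0)
  expect_equal(ident$pm25[ident$person_id == 1], c(3, 7, 3, 3))
  # ox is constant everywhere -> every assignment equals that constant
  ma <- lagged_moving_average(coh, surf, window_years = 3, lag_years = 1)
  expect_true(all(ma$ox == 5))
})

test_that("moving average commutes with a constant concentration shift", {
  set.seed(11)
  surf <- expand.grid(region_id = 1:4, year = 1:6)
  surf$pm25 <- runif(nrow(surf), 2, 12)
  surf$no2 <- runif(nrow(surf), 2, 20)
  surf$o3 <- runif(nrow(surf), 20, 50)
  surf$ox <- compute_ox(surf$no2, surf$o3)
  coh <- data.frame(person_id = 1:3)
  for (y in 1:6) coh[[paste0("region_y", y)]] <- sample(1:4, 3, replace = TRUE)
  base <- lagged_moving_average(coh, surf)
  shifted <- surf
  shifted$pm25 <- shifted$pm25 + 2.5
  out <- lagged_moving_average(coh, shifted)
  expect_equal(out$pm25, base$pm25 + 2.5)
})

test_that("missing region-year concentrations are reported with person and year", {
  surf <- expand.grid(region_id = 1:2, year = 1:4)
  surf$pm25 <- 5; surf$no2 <- 5; surf$o3 <- 5; surf$ox <- 5
  coh <- data.frame(person_id = 9L, region_y1 = 1L, region_y2 = 3L,
                    region_y3 = 1L, region_y4 = 1L)
  expect_error(lagged_moving_average(coh, surf), "person 9")
})

test_that("year adjustment is the identity for a flat series", {
  out <- year_adjust(2000:2010, rep(8.2, 11), reference_year = 2006)
  expect_equal(out$ratio, rep(1, 11), tolerance = 1e-8)
  expect_equal(out$adjusted, rep(8.2, 11), tolerance = 1e-8)
})

test_that("year adjustment reproduces an exactly linear decline", {
  years <- 2000:2011
  f <- 30 - 0.8 * (years - 2000) # linear trend, known closed form
  out <- year_adjust(years, f, reference_year = 2006)
  f_ref <- 30 - 0.8 * 6
  expect_equal(out$ratio, f_ref / f, tolerance = 1e-4)
  expect_equal(out$adjusted, f, tolerance = 1e-3)
})

test_that("year adjustment refuses short series and extrapolation", {
  expect_error(year_adjust(2001:2003, c(1, 2, 3), 2002), "at least 4")
  expect_error(year_adjust(2000:2010, runif(11, 5, 6), 2012), "outside")
})

test_that("exclusion rules drop the right persons and person-years", {
  coh <- data.frame(
    person_id = 1:5,
    age_group = c("20-24", "25-29", "60-64", "85-89", "90-94")
  )
  # ages 22, 27, 62, 87, 92 -> the 22 and 92 year olds leave (2 drops)
  exps <- data.frame(person_id = rep(1:5, each = 3),
                     year = rep(4:6, 5),
                     pm25 = c(rep(5, 9), 25, 5, 5, rep(5, 3)))
  out <- apply_exclusions(coh, exps)
  expect_equal(out$tally$age_persons, 2)
  expect_equal(out$tally$pm25_person_years, 1)
  expect_setequal(out$cohort$person_id, 2:4)
  # the person-year above 20 is gone but the person remains
  expect_equal(sum(out$exposures$person_id == 5), 0) # age-excluded anyway
  expect_equal(sum(out$exposures$person_id == 4), 2)

  # idempotence
  again <- apply_exclusions(out$cohort, out$exposures)
  expect_equal(again$cohort, out$cohort)
  expect_equal(again$exposures, out$exposures)
  expect_equal(again$tally$age_persons + again$tally$pm25_person_years +
                 again$tally$no_exposure_persons, 0)

  # all estimates below the ceiling: no exposure-rule drops
  ok <- apply_exclusions(coh[2:3, ], exps[exps$person_id %in% 2:3, ])
  expect_equal(ok$tally$pm25_person_years, 0)
})

test_that("a person with no assignable exposure is dropped and tallied", {
  coh <- data.frame(person_id = 1:2, age_group = c("40-44", "40-44"))
  exps <- data.frame(person_id = c(1, 2, 2), year = c(4, 4, 5),
                     pm25 = c(30, 5, 6))
  out <- apply_exclusions(coh, exps)
  expect_equal(out$tally$no_exposure_persons, 1)
  expect_equal(out$cohort$person_id, 2)
})

test_that("empty input passes through exclusions with zero tallies", {
  coh <- data.frame(person_id = integer(), age_group = character())
  exps <- data.frame(person_id = integer(), year = integer(), pm25 = numeric())
  out <- apply_exclusions(coh, exps)
  expect_equal(nrow(out$cohort), 0)
  expect_equal(unlist(out$tally), c(age_persons = 0, pm25_person_years = 0,
                                    no_exposure_persons = 0))
})

test_that("reporting increment is mean minus interpolated 5th percentile", {
  set.seed(3)
  x <- rlnorm(5000, 2, 0.4)
  inc <- reporting_increment(x, "test")
  expect_equal(inc$delta, mean(x) - unname(quantile(x, 0.05, type = 7)))
  expect_gt(inc$delta, 0)
  # two-value column under the documented linear-interpolation convention
  two <- reporting_increment(c(0, 100))
  expect_equal(two$delta, 50 - unname(quantile(c(0, 100), 0.05, type = 7)))
  # constant column refused
  expect_error(reporting_increment(rep(4, 10)), "constant")
})

test_that("summary increments from the default marginal targets match the rule", {
  m <- default_pollutant_marginals()
  expect_equal(summary_increment(m$ox), m$ox$mean - m$ox$p5)
  expect_equal(summary_increment(m$pm25), 7.37 - 3.51)
})

test_that("threshold flagging uses a strict inequality", {
  fl <- flag_above_threshold(c(20, 23, 26))
  expect_equal(fl$n_flagged, 1)
  expect_equal(fl$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(fl$fraction, 1 / 3)
  none <- flag_above_threshold(c(10, 15), threshold = 23)
  expect_equal(none$n_flagged, 0)
  # default threshold is 23 ppb
  expect_equal(formals(flag_above_threshold)$threshold, 23.0)
})
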