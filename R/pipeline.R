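write_csv_plain <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

write_json_plain <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Re-attach factor levels lost on CSV round-trips.
refactor_cohort_columns <- function(df) {
  cm <- default_covariate_marginals()
  for (v in intersect(names(cm), names(df))) {
    df[[v]] <- factor(df[[v]], levels = names(cm[[v]]))
  }
  df
}

config_snapshot <- function(config) {
  list(
    n_persons = config$n_persons, n_regions = config$n_regions,
    follow_up_years = config$follow_up_years, seed = config$seed,
    target_corr_pm25_ox = config$target_corr_pm25_ox,
    mobility_prob = config$mobility_prob,
    window_years = config$window_years, lag_years = config$lag_years,
    oxidant_factor_loading = config$oxidant_factor_loading,
    year_noise_sd = config$year_noise_sd,
    pollutant_marginals = lapply(config$pollutant_marginals, unclass),
    true_params = unclass(config$true_params)
  )
}

#' Run the simulate-assemble-fit-report pipeline
#'
#' Orchestrates the full analysis on a synthetic cohort: pollutant surfaces
#' and cohort generation (`simulate`), exposure assignment, exclusions,
#' survival simulation and person-year assembly (`assemble`), then the
#' analysis stages: single-pollutant hazard ratios (`fit_linear`), PM2.5
#' hazard ratios across Ox tertiles and the joint-tertile surface
#' (`fit_tertiles`), the five-model potentiation sequence (`fit_sequence`),
#' the joint nonlinear threshold model with theta profile and risk curves
#' (`fit_joint`), region flagging above the Ox threshold (`flag_regions`)
#' and a human-readable summary (`report`). Every artifact is a plain CSV
#' or JSON file; a manifest with content digests makes re-runs verifiable
#' (deterministic stages reproduce identical digests under the same
#' config and seed).
#'
#' Stages not requested are skipped; a downstream stage re-reads its inputs
#' from `outdir` if the upstream stage ran in an earlier call.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "assemble", "fit_linear", "fit_tertiles",
#'   "fit_sequence", "fit_joint", "flag_regions", "report")`.
#' @param causes Causes of death to analyse.
#' @param joint_omega_step,joint_mu_grid,joint_pi_grid Joint-model grids
#'   (coarser defaults than [fit_joint()]'s, sized for pipeline runs).
#' @param boot_B Bootstrap replicates for the joint-model uncertainty bands;
#'   `0` writes central curves only.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "assemble", "fit_linear",
                                    "fit_tertiles", "fit_sequence",
                                    "fit_joint", "flag_regions", "report"),
                         causes = "nonaccidental",
                         joint_omega_step = 0.5,
                         joint_mu_grid = 5, joint_pi_grid = 2,
                         boot_B = 0) {
  stopifnot(inherits(config, "sim_config"))
  all_stages <- c("simulate", "assemble", "fit_linear", "fit_tertiles",
                  "fit_sequence", "fit_joint", "flag_regions", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  need <- function(f, stage) {
    if (!file.exists(path(f))) {
      stop(sprintf("stage `%s` needs missing upstream artifact `%s`", stage, f))
    }
    utils::read.csv(path(f))
  }

  surfaces <- cohort <- py <- NULL
  if ("simulate" %in% stages) {
    surfaces <- generate_pollutant_surfaces(config)
    cohort <- generate_cohort(config, surfaces)
    write_csv_plain(surfaces, path("surfaces.csv"))
    write_csv_plain(cohort, path("cohort.csv"))
    write_json_plain(config_snapshot(config), path("config.json"))
  }

  if ("assemble" %in% stages) {
    if (is.null(surfaces)) surfaces <- need("surfaces.csv", "assemble")
    if (is.null(cohort)) {
      cohort <- refactor_cohort_columns(need("cohort.csv", "assemble"))
    }
    exposures <- lagged_moving_average(cohort, surfaces,
                                       config$window_years, config$lag_years)
    excl <- apply_exclusions(cohort, exposures)
    cohort <- simulate_survival(excl$cohort, excl$exposures, config)
    py <- assemble_person_years(cohort, excl$exposures, config)
    write_csv_plain(excl$exposures, path("exposures.csv"))
    write_csv_plain(cohort, path("cohort.csv"))
    write_csv_plain(py, path("person_years.csv"))
    write_json_plain(excl$tally, path("exclusions.json"))
  }

  # analysis stages always read the written artifact, never the in-memory
  # table: a resumed run then reproduces a fresh run's outputs bit for bit
  fit_stages <- intersect(stages, c("fit_linear", "fit_tertiles",
                                    "fit_sequence", "fit_joint"))
  if (length(fit_stages)) {
    py <- need("person_years.csv", fit_stages[1])
    py <- refactor_cohort_columns(py)
    py$stratum <- factor(py$stratum)
  }
  adj <- intersect(c("education", "income_quintile", "labour_force", "marital"),
                   names(py))

  if ("fit_linear" %in% stages) {
    rows <- list()
    for (cause in causes) {
      for (pol in c("pm25", "no2", "o3", "ox")) {
        spec <- model_spec(cause = cause, terms = pol, covariates = adj)
        fit <- fit_cox(py, spec)
        inc <- reporting_increment(py[[pol]], pol)
        hr <- hr_for_increment(fit, pol, inc)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(cause = cause, pollutant = pol, increment = inc$delta,
                     events = fit$n_events, neg2ll = fit$neg2ll),
          hr[c("hr", "ci_low", "ci_high")]
        )
      }
    }
    write_csv_plain(do.call(rbind, rows), path("table3_single_pollutant.csv"))
  }

  if ("fit_tertiles" %in% stages) {
    rows <- list(); grids <- list()
    for (cause in causes) {
      spec <- model_spec(cause = cause, terms = "pm25", covariates = adj)
      ts <- fit_tertile_series(py, spec, modifier = "ox")
      rows[[cause]] <- cbind(cause = cause, ts$hr_table)
      g <- fit_joint_tertile_grid(py, spec, "pm25", "ox")
      grids[[cause]] <- data.frame(
        cause = cause,
        pm25_tertile = rep(1:3, 3), ox_tertile = rep(1:3, each = 3),
        hr = as.vector(g$hr)
      )
    }
    write_csv_plain(do.call(rbind, rows), path("fig1_tertiles.csv"))
    write_csv_plain(do.call(rbind, grids), path("fig2_joint_tertiles.csv"))
  }

  if ("fit_sequence" %in% stages) {
    tabs <- list()
    for (cause in causes) {
      spec <- model_spec(cause = cause, covariates = adj)
      ms <- model_sequence(py, spec)
      tabs[[cause]] <- cbind(cause = cause, ms$table)
    }
    write_csv_plain(do.call(rbind, tabs), path("table4_model_sequence.csv"))
  }

  if ("fit_joint" %in% stages) {
    theta_rows <- list(); risk_rows <- list(); summaries <- list()
    for (cause in causes) {
      spec <- model_spec(cause = cause, covariates = adj)
      q <- stats::quantile(py$ox, c(0.05, 0.95), type = 7, names = FALSE)
      jf <- fit_joint(py, spec,
                      omega_grid = seq(q[1], q[2], by = joint_omega_step),
                      mu_grid = joint_mu_grid, pi_grid = joint_pi_grid)
      boot <- if (boot_B > 0) {
        joint_bootstrap(jf, py, B = boot_B, seed = config$seed + 10L)
      }
      ox_grid <- seq(jf$modifier_range[1], jf$modifier_range[2],
                     length.out = 40)
      theta <- if (!is.null(boot)) {
        theta_profile_with_uncertainty(jf, ox_grid, boot = boot)
      } else {
        data.frame(ox = ox_grid, theta = theta_of_ox(ox_grid, jf$params),
                   lower = NA_real_, upper = NA_real_)
      }
      theta_rows[[cause]] <- cbind(cause = cause, theta)
      oxv <- default_ox_values(py)
      for (nm in names(oxv)) {
        rc <- predict_risk_curve(jf, oxv[[nm]], boot = boot)
        risk_rows[[paste(cause, nm)]] <- cbind(
          cause = cause, ox_decile = nm, ox_value = oxv[[nm]], rc)
      }
      summaries[[cause]] <- list(
        eta = jf$params$eta, lambda = jf$params$lam, omega = jf$params$omega,
        mu = jf$params$mu, pi = jf$params$pi_scale,
        neg2ll = jf$neg2ll,
        ox_decile_means = as.list(oxv)
      )
    }
    write_csv_plain(do.call(rbind, theta_rows), path("fig4_theta_profile.csv"))
    write_csv_plain(do.call(rbind, risk_rows), path("fig4_risk_curves.csv"))
    write_json_plain(summaries, path("joint_summary.json"))
  }

  if ("flag_regions" %in% stages) {
    surfaces <- need("surfaces.csv", "flag_regions")
    region_ox <- tapply(surfaces$ox, surfaces$region_id, mean)
    fl <- flag_above_threshold(as.numeric(region_ox))
    write_csv_plain(
      data.frame(region_id = as.integer(names(region_ox)),
                 ox = as.numeric(region_ox), flagged = fl$flagged),
      path("flagged_regions.csv"))
    write_json_plain(fl[c("n_flagged", "n", "fraction", "threshold")],
                     path("flagged_regions.json"))
  }

  if ("report" %in% stages) make_report(outdir)

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("oxmod")),
    seed = config$seed,
    stages = stages,
    config = config_snapshot(config),
    artifacts = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$artifacts) <- files
  write_json_plain(manifest, path("manifest.json"))
  invisible(manifest)
}

#' Summarize a pipeline artifact directory
#'
#' Writes (and returns) a short markdown summary of whatever fit artifacts
#' are present: the reporting increments used, per-model hazard ratios with
#' confidence intervals, the estimated Ox threshold per cause, and the
#' fraction of regions flagged above the Ox threshold. An empty directory
#' yields an explicit "nothing to report".
#'
#' @param outdir A directory written by [run_pipeline()].
#' @return The summary, invisibly, as a character vector of lines.
#' @export
make_report <- function(outdir) {
  path <- function(f) file.path(outdir, f)
  lines <- c("# Analysis summary", "")
  have <- function(f) file.exists(path(f))
  any_artifact <- FALSE

  if (have("table3_single_pollutant.csv")) {
    any_artifact <- TRUE
    t3 <- utils::read.csv(path("table3_single_pollutant.csv"))
    lines <- c(lines, "## Single-pollutant hazard ratios",
               paste0("Hazard ratios are expressed per the reporting ",
                      "increment of each pollutant: the mean minus the 5th ",
                      "percentile of its person-year distribution."), "")
    lines <- c(lines, sprintf(
      "- %s / %s: HR %.3f (%.3f-%.3f) per %.3f units",
      t3$cause, t3$pollutant, t3$hr, t3$ci_low, t3$ci_high, t3$increment))
    lines <- c(lines, "")
  }
  if (have("fig1_tertiles.csv")) {
    any_artifact <- TRUE
    t1 <- utils::read.csv(path("fig1_tertiles.csv"))
    lines <- c(lines, "## PM2.5 hazard ratios across Ox tertiles",
               sprintf("- %s, tertile %d (mean Ox %.1f ppb): HR %.3f (%.3f-%.3f)",
                       t1$cause, t1$tertile, t1$modifier_mean,
                       t1$hr, t1$ci_low, t1$ci_high), "")
  }
  if (have("table4_model_sequence.csv")) {
    any_artifact <- TRUE
    t4 <- utils::read.csv(path("table4_model_sequence.csv"))
    lines <- c(lines, "## Potentiation model sequence",
               sprintf("- %s | %s | %s: HR %.3f (%.3f-%.3f), -2logL %.1f",
                       t4$cause, t4$model, t4$term, t4$hr, t4$ci_low,
                       t4$ci_high, t4$neg2ll), "")
  }
  if (have("joint_summary.json")) {
    any_artifact <- TRUE
    js <- jsonlite::read_json(path("joint_summary.json"))
    lines <- c(lines, "## Joint nonlinear threshold model")
    for (cause in names(js)) {
      lines <- c(lines, sprintf(
        "- %s: omega-hat = %.2f ppb, eta = %.4f, lambda = %.4f per ppb",
        cause, js[[cause]]$omega, js[[cause]]$eta, js[[cause]]$lambda))
    }
    lines <- c(lines, "")
  }
  if (have("flagged_regions.json")) {
    any_artifact <- TRUE
    fl <- jsonlite::read_json(path("flagged_regions.json"))
    lines <- c(lines, sprintf(
      "%.1f%% of regions (%d of %d) have mean Ox above %.1f ppb.",
      100 * fl$fraction, fl$n_flagged, fl$n, fl$threshold), "")
  }
  if (!any_artifact) lines <- c(lines, "Nothing to report: no fit artifacts found.")
  writeLines(lines, path("report.md"))
  invisible(lines)
}
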