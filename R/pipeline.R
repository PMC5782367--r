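# Pipeline orchestration: per-occasion kinetics -> amino-acid fluxes ->
# longitudinal statistics, with CSV reports and a run log.

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    lt_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            c("lt_stage_error", class(e)[1]))
  })
}

#' Per-occasion kinetic analysis of a cohort
#'
#' For every study occasion: plasma flow from the occlusion readings,
#' timepoint averaging, steady-state QC, the two-pool and three-pool
#' phenylalanine models, 3-MH kinetics, and the amino-acid flux panel.
#' Occasions without a biopsy (or with an enrichment ordering the
#' three-pool model cannot accommodate) keep their two-pool results and
#' carry `NA` three-pool fluxes with `three_pool_ok = FALSE`.
#'
#' @param cohort An `lt_cohort`.
#' @param config An [lt_config()].
#' @param panel Amino-acid panel (default [aa_panel_default()]).
#' @return List of class `lt_analysis`: `kinetics` (one row per occasion),
#'   `aaflux` (long, one row per occasion x amino acid plus total rows).
#' @export
analyze_cohort <- function(cohort, config = lt_config(),
                           panel = aa_panel_default()) {
  stopifnot(inherits(cohort, "lt_cohort"))
  occ <- cohort$occasions
  kin_rows <- list(); aa_rows <- list()
  for (k in seq_len(nrow(occ))) {
    pid <- occ$patient_id[k]; day <- occ$icu_day[k]
    sam <- cohort$samples[cohort$samples$patient_id == pid &
                          cohort$samples$icu_day == day, , drop = FALSE]
    bio <- cohort$biopsies[cohort$biopsies$patient_id == pid &
                           cohort$biopsies$icu_day == day, , drop = FALSE]
    ple <- cohort$plethysmography[
      cohort$plethysmography$patient_id == pid &
      cohort$plethysmography$icu_day == day, , drop = FALSE]

    flow <- occasion_flow(ple$slope_pct_per_min[ple$phase == "pre"],
                          ple$slope_pct_per_min[ple$phase == "post"],
                          occ$hematocrit[k],
                          min_readings = config$kinetics$min_readings,
                          trim = config$kinetics$trim_readings)
    av <- average_occasion(sam, if (nrow(bio)) bio else NULL, flow, config)
    qc <- steady_state_qc(sam, config$qc$cv_threshold)

    inverted <- FALSE
    withCallingHandlers(
      two <- two_pool(av),
      warning = function(w) {
        inverted <<- TRUE
        invokeRestart("muffleWarning")
      })
    three <- tryCatch(three_pool(av, config$kinetics$ordering_tolerance),
                      lt_error = function(e) NULL)
    m3 <- suppressWarnings(mh3_two_pool(av))
    aa <- aa_fluxes(av, panel)

    kin_rows[[k]] <- data.frame(
      patient_id = pid, icu_day = day,
      blood_flow = flow$blood_flow, PF = flow$plasma_flow,
      NB = two$NB, Rd = two$Rd, Ra = two$Ra,
      F_MA = if (is.null(three)) NA_real_ else three$F_MA,
      F_VM = if (is.null(three)) NA_real_ else three$F_VM,
      F_VA = if (is.null(three)) NA_real_ else three$F_VA,
      F_M0 = if (is.null(three)) NA_real_ else three$F_M0,
      F_0M = if (is.null(three)) NA_real_ else three$F_0M,
      NB3 = m3$NB3, Rd3 = m3$Rd3, Ra3 = m3$Ra3,
      total_aa_flux = aa$total_flux, total_aa_arterial = aa$total_arterial,
      three_pool_ok = !is.null(three),
      shunt_negative = if (is.null(three)) NA else three$shunt_negative,
      inverted_gradient = inverted,
      qc_flagged = any(qc$flag),
      stringsAsFactors = FALSE)

    aa_rows[[k]] <- rbind(
      data.frame(patient_id = pid, icu_day = day, aa = aa$panel_used,
                 flux = unname(aa$flux),
                 arterial_conc = unname(aa$arterial_conc),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = pid, icu_day = day, aa = "total",
                 flux = aa$total_flux, arterial_conc = aa$total_arterial,
                 stringsAsFactors = FALSE))
  }
  structure(list(kinetics = do.call(rbind, kin_rows),
                 aaflux = do.call(rbind, aa_rows)),
            class = "lt_analysis")
}

#' Longitudinal statistics over every kinetic outcome
#'
#' Fits the random-intercept model over ICU day and runs the early/late
#' period comparison for each outcome column, plus the sensitivity refit
#' and zero-crossing-day estimate.
#'
#' @param kinetics The `kinetics` table from [analyze_cohort()].
#' @param outcomes Outcome columns to analyze.
#' @param config An [lt_config()]; `stats$holm = TRUE` adds
#'   Holm-adjusted p columns across the outcomes.
#' @return List of class `lt_stats`: `trend_report` and
#'   `comparison_report` data frames, and per-outcome `fits`.
#' @export
cohort_statistics <- function(kinetics,
                              outcomes = c("NB", "Rd", "Ra", "F_0M", "F_M0",
                                           "Ra3", "total_aa_flux",
                                           "total_aa_arterial"),
                              config = lt_config()) {
  trend <- list(); comp <- list(); fits <- list()
  for (outc in outcomes) {
    y <- kinetics[[outc]]
    ok <- !is.na(y)
    fit <- fit_random_intercept(y[ok], kinetics$icu_day[ok],
                                kinetics$patient_id[ok],
                                df_method = config$stats$df_method)
    sens <- tryCatch(sensitivity_refit(fit), lt_error = function(e) NULL)
    zc <- zero_crossing_day(fit)
    fits[[outc]] <- fit
    trend[[outc]] <- data.frame(
      outcome = outc, beta0 = fit$beta0, beta1 = fit$beta1,
      se_beta1 = fit$se_beta1, p_slope = fit$p_slope,
      sigma_b = fit$sigma_b, sigma_e = fit$sigma_e,
      n_obs = fit$n_obs, n_patients = fit$n_patients,
      crossing_day = zc$day, crossing_se = zc$se,
      n_removed_sensitivity =
        if (is.null(sens)) NA_integer_ else length(sens$removed_patient_ids),
      conclusion_changed =
        if (is.null(sens)) NA else sens$conclusion_changed,
      stringsAsFactors = FALSE)
    pc <- tryCatch(
      period_comparison(kinetics[ok, c("patient_id", "icu_day")] |>
                          cbind(value = y[ok]), "value",
                        exact_max_n = config$stats$mw_exact_max_n),
      lt_error = function(e) NULL)
    comp[[outc]] <- if (is.null(pc)) {
      data.frame(outcome = outc, n_early = NA, median_early = NA,
                 q1_early = NA, q3_early = NA, n_late = NA,
                 median_late = NA, q1_late = NA, q3_late = NA,
                 U = NA, p_value = NA, stringsAsFactors = FALSE)
    } else {
      data.frame(outcome = outc,
                 n_early = pc$early$n, median_early = pc$early$median,
                 q1_early = pc$early$q1, q3_early = pc$early$q3,
                 n_late = pc$late$n, median_late = pc$late$median,
                 q1_late = pc$late$q1, q3_late = pc$late$q3,
                 U = pc$U, p_value = pc$p_value, stringsAsFactors = FALSE)
    }
  }
  trend_report <- do.call(rbind, trend)
  comparison_report <- do.call(rbind, comp)
  if (isTRUE(config$stats$holm)) {
    trend_report$p_slope_holm <- stats::p.adjust(trend_report$p_slope, "holm")
    comparison_report$p_value_holm <-
      stats::p.adjust(comparison_report$p_value, "holm")
  }
  rownames(trend_report) <- rownames(comparison_report) <- NULL
  structure(list(trend_report = trend_report,
                 comparison_report = comparison_report, fits = fits),
            class = "lt_stats")
}

#' Run the full pipeline
#'
#' Either loads a cohort from `input_dir` or simulates one, then runs
#' the kinetic analysis and the longitudinal statistics, writing
#' `kinetics.csv`, `aaflux.csv`, `stats_report.csv`,
#' `comparison_report.csv` and `run_log.txt` to `out_dir`. Reruns with
#' the same inputs and seed reproduce the outputs numerically.
#'
#' @param out_dir Output directory (created if needed).
#' @param input_dir Directory with cohort CSVs; `NULL` to simulate.
#' @param config An [lt_config()]; its `simulate` section parameterizes
#'   the generator when simulating.
#' @param seed Seed for simulation (required when `input_dir` is NULL).
#' @return List of class `lt_pipeline` with the analysis, statistics and
#'   output paths, invisibly.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL, config = lt_config(),
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("legturnover %s", as.character(packageVersion("legturnover"))),
           sprintf("started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  if (is.null(input_dir)) {
    sim <- stage_wrap("simulate", {
      generate_cohort(do.call(sim_config, config$simulate), seed = seed)
    })
    cohort <- sim$cohort
    write_simulation(sim, file.path(out_dir, "simulated_cohort"))
    log <- c(log, sprintf("stage simulate: ok (seed %s, %d occasions)",
                          format(seed), nrow(cohort$occasions)))
  } else {
    cohort <- stage_wrap("datamodel", load_cohort(input_dir, config))
    log <- c(log, sprintf("stage datamodel: ok (%d occasions from %s)",
                          nrow(cohort$occasions), input_dir))
  }

  analysis <- stage_wrap("kinetics", analyze_cohort(cohort, config))
  log <- c(log, sprintf("stage kinetics: ok (%d occasions, %d three-pool)",
                        nrow(analysis$kinetics),
                        sum(analysis$kinetics$three_pool_ok)))

  stats <- stage_wrap("stats", cohort_statistics(analysis$kinetics,
                                                 config = config))
  log <- c(log, "stage stats: ok")

  write_csv_full(analysis$kinetics, file.path(out_dir, "kinetics.csv"))
  write_csv_full(analysis$aaflux, file.path(out_dir, "aaflux.csv"))
  write_csv_full(stats$trend_report, file.path(out_dir, "stats_report.csv"))
  write_csv_full(stats$comparison_report,
                 file.path(out_dir, "comparison_report.csv"))
  cfg_path <- file.path(out_dir, "config_echo.yml")
  yaml::write_yaml(unclass(config), cfg_path)
  log <- c(log, sprintf("config md5 %s; seed %s",
                        unname(tools::md5sum(cfg_path)), format(seed)))
  writeLines(log, file.path(out_dir, "run_log.txt"))

  invisible(structure(list(cohort = cohort, analysis = analysis,
                           stats = stats, out_dir = out_dir, log = log),
                      class = "lt_pipeline"))
}

#' Spaghetti plot of per-patient trajectories with the fitted trend
#'
#' @param kinetics The `kinetics` table from [analyze_cohort()].
#' @param outcome Outcome column to plot.
#' @param fit Optional [fit_random_intercept()] result; its fixed line
#'   is overlaid.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_trajectories <- function(kinetics, outcome, fit = NULL, ...) {
  x <- kinetics$icu_day; y <- kinetics[[outcome]]
  plot(x, y, xlab = "ICU day", ylab = outcome, pch = 19, ...)
  for (pid in unique(kinetics$patient_id)) {
    idx <- which(kinetics$patient_id == pid)
    idx <- idx[order(x[idx])]
    if (length(idx) > 1) graphics::lines(x[idx], y[idx], col = "grey60")
  }
  if (!is.null(fit)) graphics::abline(fit$beta0, fit$beta1, col = "red3", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(NULL)
}
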