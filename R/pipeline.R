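# Moderators (Table-style sets) and trend covariates fitted per treatment.
default_moderators <- function(treatment) {
  switch(treatment,
    interplant = c("prev_land_use", "tree_genus", "soil_moisture_regime",
                   "intercrop_genus", "wood_type", "experimental_design"),
    npk = c("prev_land_use", "tree_genus", "soil_moisture_regime",
            "wood_type", "application_method"),
    thin = c("prev_land_use", "tree_genus", "soil_moisture_regime",
             "wood_type"))
}

default_trend_covariates <- function(treatment) {
  switch(treatment,
    interplant = c("stand_age", "map_mm"),
    npk = c("stand_age", "time_since_treatment", "map_mm"),
    thin = c("time_since_treatment", "map_mm", "basal_area_removed"))
}

#' Run the full meta-analytic pipeline for one treatment
#'
#' Orchestrates every stage of the analysis on a compilation of paired
#' treatment-control comparisons: SD imputation, lnRR effect sizes, the
#' overall publication-level random-effects model, one single-moderator
#' model per moderator, covariate-trimmed time/continuous trend regressions
#' with zero crossings, fertilizer greenhouse-gas accounting (NPK only), and
#' a sensitivity reanalysis excluding imputed SDs. A moderator whose model
#' cannot be fitted (for example, every category has a single observation)
#' is skipped with a warning rather than aborting the run.
#'
#' @param input A compilation tibble, a path to a compilation CSV, or a
#'   [synthetic_config()] to simulate from.
#' @param treatment Treatment to analyze (`"interplant"`, `"npk"`,
#'   `"thin"`); inferred when the input holds a single treatment.
#' @param moderators Character vector of moderator columns; defaults to the
#'   treatment's standard set.
#' @param trend_covariates Continuous covariates for trend regressions;
#'   defaults to the treatment's standard set, with the treatment's trimming
#'   rule (interplanting: stand age <= 20 yr; NPK: time since treatment <=
#'   5 yr; thinning: untrimmed) applied to its time variable.
#' @param exclude_imputed If `TRUE`, comparisons whose SDs were imputed are
#'   excluded from every model (the sensitivity configuration).
#' @param constants [ghg_constants()] for the NPK emission accounting.
#' @param out Optional output directory; when given, stage tables are
#'   written as CSV (`effects.csv`, `overall.csv`, `moderators/<name>.csv`,
#'   `trend.csv`, `ghg.csv`), a `report.json` summary and a `run.log`.
#' @return A `silvicarb_report` list: `treatment`, `effects`, `overall`,
#'   `moderators` (named list of `meta_fit`), `moderator_table`, `trends`
#'   (named list of `trend_fit`), `trend_table`, `ghg`, `ghg_data`,
#'   `sensitivity`, and the run `log`.
#' @export
run_analysis <- function(input, treatment = NULL, moderators = NULL,
                         trend_covariates = NULL, exclude_imputed = FALSE,
                         constants = ghg_constants(), out = NULL) {
  log_lines <- character()
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  }

  records <- if (inherits(input, "synthetic_config")) {
    note("input", sprintf("generated synthetic compilation (seed %d)",
                          input$seed))
    generate_compilation(input)$records
  } else if (is.character(input)) {
    note("input", sprintf("read compilation from %s", input))
    read_compilation(input)
  } else {
    validate_compilation(input)
  }

  if (is.null(treatment)) {
    present <- unique(records$treatment)
    if (length(present) != 1) {
      abort(c("`treatment` must be given when the input mixes treatments.",
              i = paste("Present:", paste(present, collapse = ", "))))
    }
    treatment <- present
  }
  records <- records[records$treatment == treatment, , drop = FALSE]
  if (nrow(records) == 0) {
    abort(sprintf("No comparisons for treatment '%s'.", treatment))
  }
  note("input", sprintf("%d comparisons, %d publications, treatment '%s'",
                        nrow(records), length(unique(records$study_id)),
                        treatment))

  imputed <- impute_missing_sd(records)
  n_imp <- sum(imputed$sd_imputed_treat | imputed$sd_imputed_ctrl)
  note("impute", sprintf("imputed SDs for %d of %d comparisons", n_imp,
                         nrow(imputed)))
  if (exclude_imputed) {
    imputed <- imputed[!(imputed$sd_imputed_treat | imputed$sd_imputed_ctrl), ,
                       drop = FALSE]
    note("impute", sprintf("excluded imputed comparisons; %d remain",
                           nrow(imputed)))
  }

  effects <- add_effect_sizes(imputed)
  note("effects", sprintf("computed %d lnRR effect sizes", nrow(effects)))

  overall <- fit_random_effects(effects)
  note("overall", sprintf("pooled percent change %.1f%% [%.1f, %.1f], tau2 %.4f",
                          overall$coefficients$percent[1],
                          overall$coefficients$percent_lb[1],
                          overall$coefficients$percent_ub[1], overall$tau2))

  moderators <- moderators %||% default_moderators(treatment)
  moderator_fits <- list()
  for (mod in moderators) {
    fit <- tryCatch(fit_moderator_model(effects, mod), error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("Moderator '%s' skipped: %s", mod, conditionMessage(fit)))
      note("moderators", sprintf("'%s' skipped: %s", mod,
                                 conditionMessage(fit)))
    } else {
      if (length(fit$dropped_categories) > 0) {
        note("moderators", sprintf("'%s': dropped single-observation %s", mod,
                                   paste(fit$dropped_categories,
                                         collapse = ", ")))
      }
      moderator_fits[[mod]] <- fit
    }
  }
  moderator_table <- purrr::imap(moderator_fits, function(f, nm) {
    dplyr::mutate(tidy(f), moderator = nm,
                  omnibus_p = f$omnibus$p_value, .before = 1)
  }) |> dplyr::bind_rows()

  trend_covariates <- trend_covariates %||% default_trend_covariates(treatment)
  rule <- trim_rules()[[treatment]]
  trend_fits <- list()
  for (cov in trend_covariates) {
    eff_cov <- effects
    if (!is.null(rule) && identical(rule$covariate, cov)) {
      eff_cov <- trim_by_covariate(effects, cov, rule$max_value)
      note("trend", sprintf("'%s': trimmed %d comparisons above %s", cov,
                            attr(eff_cov, "n_dropped"), rule$max_value))
    }
    fit <- tryCatch(fit_time_meta_regression(eff_cov, cov),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warn(sprintf("Trend '%s' skipped: %s", cov, conditionMessage(fit)))
      note("trend", sprintf("'%s' skipped: %s", cov, conditionMessage(fit)))
    } else {
      trend_fits[[cov]] <- fit
    }
  }
  trend_table <- purrr::map(trend_fits, glance) |> dplyr::bind_rows()

  ghg_fit_obj <- NULL
  ghg_data <- NULL
  if (treatment == "npk") {
    ghg_data <- tryCatch(ghg_table(effects, constants), error = function(e) e)
    if (inherits(ghg_data, "error")) {
      note("ghg", paste("skipped:", conditionMessage(ghg_data)))
      ghg_data <- NULL
    } else {
      note("ghg", sprintf("%d fertilized comparisons, median net balance %.2f",
                          nrow(ghg_data), median(ghg_data$net_balance)))
      ghg_fit_obj <- tryCatch(fit_net_balance_regression(ghg_data),
                              error = function(e) {
                                note("ghg", paste("regression skipped:",
                                                  conditionMessage(e)))
                                NULL
                              })
    }
  } else {
    note("ghg", "not an NPK analysis; stage skipped")
  }

  sensitivity <- if (exclude_imputed) NULL else sensitivity_reanalysis(records)
  if (!is.null(sensitivity)) {
    note("sensitivity", sprintf(
      "refit on %d complete-SD comparisons (%d excluded); max |difference| %.2f%%",
      sensitivity$n_complete, sensitivity$n_excluded,
      max(abs(sensitivity$difference$difference))))
  }

  report <- structure(
    list(treatment = treatment, effects = effects, overall = overall,
         moderators = moderator_fits, moderator_table = moderator_table,
         trends = trend_fits, trend_table = trend_table,
         ghg = ghg_fit_obj, ghg_data = ghg_data,
         sensitivity = sensitivity, log = log_lines),
    class = "silvicarb_report"
  )
  if (!is.null(out)) {
    write_report(report, out)
  }
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report A `silvicarb_report` from [run_analysis()].
#' @param out Output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$effects, file.path(out, "effects.csv"), na = "")
  readr::write_csv(dplyr::bind_cols(tidy(report$overall),
                                    glance(report$overall)[c("tau2", "m")]),
                   file.path(out, "overall.csv"))
  if (length(report$moderators) > 0) {
    dir.create(file.path(out, "moderators"), showWarnings = FALSE)
    for (nm in names(report$moderators)) {
      readr::write_csv(tidy(report$moderators[[nm]]),
                       file.path(out, "moderators", paste0(nm, ".csv")))
    }
  }
  if (nrow(report$trend_table %||% tibble::tibble()) > 0) {
    readr::write_csv(report$trend_table, file.path(out, "trend.csv"))
  }
  if (!is.null(report$ghg_data)) {
    readr::write_csv(report$ghg_data, file.path(out, "ghg.csv"))
  }
  summary <- list(
    treatment = report$treatment,
    k = report$overall$k,
    m = report$overall$m,
    tau2 = report$overall$tau2,
    percent_change = report$overall$coefficients$percent[1],
    percent_ci = c(report$overall$coefficients$percent_lb[1],
                   report$overall$coefficients$percent_ub[1]),
    moderator_omnibus_p = purrr::map_dbl(report$moderators,
                                         ~ .x$omnibus$p_value),
    trend = if (nrow(report$trend_table %||% tibble::tibble()) > 0)
      report$trend_table else NULL,
    ghg = if (!is.null(report$ghg)) glance(report$ghg) else NULL
  )
  jsonlite::write_json(summary, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.silvicarb_report <- function(x, ...) {
  cat(sprintf("silvicarb analysis: treatment '%s'\n", x$treatment))
  cat(sprintf("  overall: %.1f%% [%.1f, %.1f], k = %d, m = %d, tau2 = %.4f\n",
              x$overall$coefficients$percent[1],
              x$overall$coefficients$percent_lb[1],
              x$overall$coefficients$percent_ub[1],
              x$overall$k, x$overall$m, x$overall$tau2))
  if (length(x$moderators) > 0) {
    cat("  moderators:",
        paste(sprintf("%s (p=%.3g)", names(x$moderators),
                      purrr::map_dbl(x$moderators, ~ .x$omnibus$p_value)),
              collapse = ", "), "\n")
  }
  if (length(x$trends) > 0) {
    cat("  trends:",
        paste(sprintf("%s (%.2f%%/unit)", names(x$trends),
                      purrr::map_dbl(x$trends, "percent_per_unit")),
              collapse = ", "), "\n")
  }
  if (!is.null(x$ghg)) {
    cat(sprintf("  ghg: median net balance %.2f Mg CO2e/ha, break-even %.3f Mg N/ha\n",
                x$ghg$median_net_balance, x$ghg$break_even_n))
  }
  invisible(x)
}
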