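#' Specify a synthetic study compilation with known ground truth
#'
#' Defines the generative model for a synthetic compilation of paired
#' treatment-control comparisons, mirroring the structure of real
#' silvicultural meta-analytic databases: comparisons nested in
#' publications (some sharing a control plot), between-publication
#' heterogeneity, moderator- and covariate-dependent true effects, and
#' missing-completely-at-random standard deviations.
#'
#' The true effect of comparison i in publication j is
#' `lnRR_ij = mu_true + u_j + sum(offsets) + sum(slope * (x - midrange))`,
#' with `u_j ~ N(0, tau2_true)`. Continuous covariates are drawn uniformly
#' over their stated range and their contribution is centred on the range
#' midpoint, so `mu_true` remains the marginal mean effect whatever slopes
#' are present.
#'
#' @param treatment One of `"interplant"`, `"npk"`, `"thin"`.
#' @param n_publications Number of publications.
#' @param comparisons_rate Poisson rate; each publication contributes
#'   `1 + rpois(rate)` comparisons.
#' @param mu_true Marginal mean lnRR.
#' @param tau2_true Between-publication variance of true effects (>= 0).
#' @param moderator_spec Named list of categorical moderators; each element
#'   is `list(levels =, probs =, offsets =)` (probs default uniform,
#'   offsets default 0).
#' @param slope_spec Named numeric vector of lnRR slopes per unit of the
#'   covariates named in `covariate_ranges`.
#' @param covariate_ranges Named list of `c(min, max)` ranges for the
#'   continuous covariates to generate.
#' @param ctrl_meanlog,ctrl_sdlog Log-normal parameters of the control-arm
#'   aboveground carbon (Mg C ha^-1).
#' @param cv_range Range of arm coefficients of variation.
#' @param n_reps_range Integer range of replicate counts per arm.
#' @param missing_sd_fraction Probability that a comparison's SDs are
#'   blanked (both arms, MCAR).
#' @param shared_control_prob Probability that a comparison after the first
#'   in a publication reuses the publication's control plot.
#' @param per_tree_fraction For NPK only: fraction of comparisons reporting
#'   N application per tree rather than per hectare.
#' @param n_applied_meanlog,n_applied_sdlog For NPK only: log-normal
#'   parameters of the N applied (kg N ha^-1).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   the configuration.
#' @return A `synthetic_config` list.
#' @seealso [default_config()] for treatment-specific defaults emulating the
#'   compiled database; [generate_compilation()].
#' @export
synthetic_config <- function(treatment = "interplant",
                             n_publications = 40,
                             comparisons_rate = 3.6,
                             mu_true = 0.2,
                             tau2_true = 0.05,
                             moderator_spec = list(),
                             slope_spec = NULL,
                             covariate_ranges = list(stand_age = c(1, 20),
                                                     map_mm = c(600, 2500)),
                             ctrl_meanlog = log(60),
                             ctrl_sdlog = 0.6,
                             cv_range = c(0.10, 0.30),
                             n_reps_range = c(3L, 5L),
                             missing_sd_fraction = 0.30,
                             shared_control_prob = 0.30,
                             per_tree_fraction = 0.15,
                             n_applied_meanlog = log(200),
                             n_applied_sdlog = 0.8,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    abort("A `seed` is mandatory: the generator is a pure function of its config.")
  }
  if (!treatment %in% treatment_levels) {
    abort(sprintf("Unknown treatment '%s'.", treatment))
  }
  stopifnot(n_publications >= 1, comparisons_rate >= 0, tau2_true >= 0,
            missing_sd_fraction >= 0, missing_sd_fraction <= 1,
            shared_control_prob >= 0, shared_control_prob <= 1,
            cv_range[1] >= 0, diff(cv_range) >= 0,
            n_reps_range[1] >= 1, diff(n_reps_range) >= 0)
  for (nm in names(moderator_spec)) {
    ms <- moderator_spec[[nm]]
    if (is.null(ms$levels)) {
      abort(sprintf("moderator_spec[['%s']] needs a `levels` element.", nm))
    }
    if (!is.null(ms$probs) &&
        (length(ms$probs) != length(ms$levels) || any(ms$probs < 0))) {
      abort(sprintf("moderator_spec[['%s']]: bad `probs`.", nm))
    }
    if (!is.null(ms$offsets) && length(ms$offsets) != length(ms$levels)) {
      abort(sprintf("moderator_spec[['%s']]: offsets must match levels.", nm))
    }
  }
  if (!is.null(slope_spec)) {
    bad <- setdiff(names(slope_spec), names(covariate_ranges))
    if (length(bad) > 0) {
      abort(paste0("slope_spec names without a covariate range: ",
                   paste(bad, collapse = ", "), "."))
    }
  }
  structure(
    list(treatment = treatment, n_publications = n_publications,
         comparisons_rate = comparisons_rate, mu_true = mu_true,
         tau2_true = tau2_true, moderator_spec = moderator_spec,
         slope_spec = slope_spec, covariate_ranges = covariate_ranges,
         ctrl_meanlog = ctrl_meanlog, ctrl_sdlog = ctrl_sdlog,
         cv_range = cv_range, n_reps_range = as.integer(n_reps_range),
         missing_sd_fraction = missing_sd_fraction,
         shared_control_prob = shared_control_prob,
         per_tree_fraction = per_tree_fraction,
         n_applied_meanlog = n_applied_meanlog,
         n_applied_sdlog = n_applied_sdlog,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Treatment-specific default synthetic configurations
#'
#' Defaults emulate the scale and true-effect structure of the compiled
#' silvicultural database: 43 publications / ~197 comparisons with a +20%
#' mean effect growing with stand age for interplanting; 17 publications /
#' ~164 comparisons with a +44.5% mean effect declining with time since
#' treatment for NPK fertilization; 8 publications / ~62 comparisons with a
#' -34% mean effect that lessens with time since thinning and deepens with
#' the percent of basal area removed. Between-publication heterogeneity
#' defaults to tau2 = 0.05 in every case.
#'
#' @param treatment One of `"interplant"`, `"npk"`, `"thin"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
default_config <- function(treatment = c("interplant", "npk", "thin"), seed,
                           ...) {
  treatment <- match.arg(treatment)
  shared <- list(
    prev_land_use = list(levels = c("cropland", "natural_forest", "plantation")),
    soil_moisture_regime = list(levels = soil_moisture_levels),
    wood_type = list(levels = c("hardwood", "softwood"))
  )
  base <- switch(treatment,
    interplant = list(
      treatment = "interplant", n_publications = 43, comparisons_rate = 3.6,
      mu_true = log(1.20), slope_spec = c(stand_age = 0.036),
      covariate_ranges = list(stand_age = c(1, 20), map_mm = c(600, 2500)),
      moderator_spec = c(shared, list(
        tree_genus = list(levels = c("Alnus", "Anacardium", "Casuarina",
                                     "Eucalyptus", "Hymeronima", "Pachira",
                                     "Pinus", "Populus", "Pseudotsuga")),
        intercrop_genus = list(levels = c("Acacia", "Albizia", "Alnus",
                                          "Dalbergia", "Enterolobium",
                                          "Hippophae", "Leucaena", "Lupinus",
                                          "Paraserianthes", "Robinia",
                                          "Salix")),
        experimental_design = list(levels = c("additive", "replacement"))))),
    npk = list(
      treatment = "npk", n_publications = 17, comparisons_rate = 8.6,
      mu_true = log(1.445), slope_spec = c(time_since_treatment = -0.0666),
      covariate_ranges = list(stand_age = c(1, 25),
                              time_since_treatment = c(0.5, 5),
                              map_mm = c(600, 2500)),
      ctrl_meanlog = log(8), ctrl_sdlog = 0.5,
      moderator_spec = c(shared, list(
        tree_genus = list(levels = c("Ailanthus", "Eucalyptus", "Macaranga",
                                     "Picea", "Pinus")),
        application_method = list(levels = c("continuous", "pulse"))))),
    thin = list(
      treatment = "thin", n_publications = 8, comparisons_rate = 6.75,
      mu_true = log(0.66),
      slope_spec = c(time_since_treatment = 0.046, basal_area_removed = -0.013),
      covariate_ranges = list(stand_age = c(5, 40),
                              time_since_treatment = c(1, 14),
                              basal_area_removed = c(15, 70),
                              map_mm = c(600, 2500)),
      moderator_spec = c(shared, list(
        tree_genus = list(levels = c("Acacia", "Cunninghamia", "Eucalyptus",
                                     "Pinus")))))
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(synthetic_config, args)
}

#' Generate a synthetic compilation and its ground-truth ledger
#'
#' Draws a full compilation from a [synthetic_config()]: publication random
#' effects, moderators and covariates, true per-comparison lnRRs, log-normal
#' latent control means, latent treatment means `ctrl * exp(lnRR)`, arm SDs
#' from the CV range, and replicate counts. Reported arm means are sample
#' means, so they scatter around the latent means with standard error
#' `sd / sqrt(n)` - which is exactly the noise the delta-method lnRR
#' variance of [lnrr_variance()] describes. Comparisons sharing a control
#' plot share its observed value, and SDs are blanked MCAR at the configured
#' fraction. The output always passes [validate_compilation()].
#'
#' @param config A `synthetic_config`.
#' @return A list with `records` (a compilation tibble in the interchange
#'   schema) and `truth` (a list: `comparisons` tibble of latent true lnRRs,
#'   `publications` tibble of random effects, and the `config`).
#' @export
generate_compilation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_compilation_impl(config))
}

# Uniform draw from an inclusive integer range (safe when min == max).
sample_range <- function(range, n) {
  pool <- seq(range[1], range[2])
  pool[sample.int(length(pool), n, replace = TRUE)]
}

generate_compilation_impl <- function(config) {
  J <- config$n_publications
  study_ids <- sprintf("S%03d", seq_len(J))
  u <- rnorm(J, 0, sqrt(config$tau2_true))
  n_comp <- 1L + rpois(J, config$comparisons_rate)
  N <- sum(n_comp)
  pub <- rep(seq_len(J), n_comp)
  within <- sequence(n_comp)

  records <- tibble::tibble(
    study_id = study_ids[pub],
    site_id = sprintf("%s_site%02d", study_ids[pub], within),
    treatment = config$treatment,
    unit = "carbon"
  )
  true_lnrr <- config$mu_true + u[pub]

  for (cov in names(config$covariate_ranges)) {
    rng <- config$covariate_ranges[[cov]]
    x <- runif(N, rng[1], rng[2])
    records[[cov]] <- x
    sl <- config$slope_spec[cov]
    if (!is.null(config$slope_spec) && !is.na(sl)) {
      true_lnrr <- true_lnrr + sl * (x - mean(rng))
    }
  }

  for (mod in names(config$moderator_spec)) {
    ms <- config$moderator_spec[[mod]]
    probs <- ms$probs %||% rep(1 / length(ms$levels), length(ms$levels))
    idx <- sample.int(length(ms$levels), N, replace = TRUE, prob = probs)
    records[[mod]] <- ms$levels[idx]
    if (!is.null(ms$offsets)) {
      true_lnrr <- true_lnrr + ms$offsets[idx]
    }
  }

  # Control plots: the first comparison in a publication defines one; each
  # later comparison reuses a uniformly chosen existing plot with probability
  # shared_control_prob, else opens a new one.
  reuse_u <- runif(N)
  new_plot <- within == 1L | reuse_u > config$shared_control_prob
  plot_of_row <- integer(N)
  n_plots_pub <- integer(J)
  for (i in seq_len(N)) {
    j <- pub[i]
    if (new_plot[i]) {
      n_plots_pub[j] <- n_plots_pub[j] + 1L
      plot_of_row[i] <- n_plots_pub[j]
    } else {
      plot_of_row[i] <- sample.int(n_plots_pub[j], 1)
    }
  }
  total_plots <- sum(n_plots_pub)
  plot_mean <- rlnorm(total_plots, config$ctrl_meanlog, config$ctrl_sdlog)
  plot_sd <- plot_mean * runif(total_plots, config$cv_range[1],
                               config$cv_range[2])
  plot_n <- sample_range(config$n_reps_range, total_plots)
  # Reported arm means are sample means of plot_n replicates, so they carry
  # sampling error sd / sqrt(n) around the latent plot mean; the error is
  # drawn once per control plot, so comparisons sharing a control share the
  # same observed value.  (Floored at 1% of the latent mean - relevant only
  # for CVs far beyond the default range.)
  plot_mean_obs <- pmax(plot_mean + rnorm(total_plots, 0,
                                          plot_sd / sqrt(plot_n)),
                        0.01 * plot_mean)
  # global plot index: plots are numbered within publications
  plot_base <- c(0L, cumsum(n_plots_pub))[seq_len(J)]
  plot_global <- plot_base[pub] + plot_of_row

  records$control_id <- sprintf("%s_ctrl%02d", study_ids[pub], plot_of_row)
  records$mean_ctrl <- plot_mean_obs[plot_global]
  records$sd_ctrl <- plot_sd[plot_global]
  records$n_ctrl <- plot_n[plot_global]

  treat_mean_true <- plot_mean[plot_global] * exp(true_lnrr)
  records$sd_treat <- treat_mean_true *
    runif(N, config$cv_range[1], config$cv_range[2])
  records$n_treat <- sample_range(config$n_reps_range, N)
  records$mean_treat <- pmax(treat_mean_true +
                               rnorm(N, 0, records$sd_treat /
                                       sqrt(records$n_treat)),
                             0.01 * treat_mean_true)
  records$u_j <- u[pub]
  records$true_lnrr <- true_lnrr

  if (config$treatment == "npk") {
    n <- nrow(records)
    kg_ha <- rlnorm(n, config$n_applied_meanlog, config$n_applied_sdlog)
    per_tree <- runif(n) < config$per_tree_fraction
    records$stand_density <- round(runif(n, 800, 2500))
    records$n_applied <- ifelse(per_tree, kg_ha / records$stand_density, kg_ha)
    records$n_applied_unit <- ifelse(per_tree, "kg_per_tree", "kg_per_ha")
  }

  # Blank SDs completely at random, but keep at least one complete record so
  # that CV-based imputation stays well defined.
  blank <- runif(nrow(records)) < config$missing_sd_fraction
  if (all(blank)) {
    blank[1] <- FALSE
  }
  records$sd_treat[blank] <- NA_real_
  records$sd_ctrl[blank] <- NA_real_

  truth_comparisons <- records |>
    dplyr::select("study_id", "site_id", "u_j", "true_lnrr")
  records$u_j <- NULL
  records$true_lnrr <- NULL

  missing_cols <- setdiff(compilation_columns, names(records))
  for (col in missing_cols) {
    records[[col]] <- if (col %in% c("stand_age", "time_since_treatment",
                                     "map_mm", "basal_area_removed",
                                     "n_applied", "stand_density")) {
      NA_real_
    } else {
      NA_character_
    }
  }
  records <- records[compilation_columns]
  validate_compilation(records)

  list(
    records = records,
    truth = list(
      comparisons = truth_comparisons,
      publications = tibble::tibble(study_id = study_ids, u_j = u,
                                    n_comparisons = n_comp),
      config = config
    )
  )
}

#' Parameter-recovery experiment over repeated synthetic compilations
#'
#' Repeatedly generates a compilation (replicate r uses `seed + r`), runs
#' the imputation / effect-size / overall-model pipeline, and summarizes how
#' well the pooled mean and heterogeneity are recovered: mean bias of the
#' estimated marginal lnRR, mean bias of tau^2-hat, and 95% CI coverage of
#' the true marginal mean, each with Monte-Carlo standard errors. When
#' `null_moderator` names a categorical moderator with no true offsets, the
#' omnibus rejection rate at alpha = 0.05 is also reported - the empirical
#' type-I error of the moderator test.
#'
#' @param config A `synthetic_config`; for coverage to be meaningful the
#'   config's slopes are centred (as [synthetic_config()] enforces) and
#'   moderator offsets are zero, so the true marginal mean is `mu_true`.
#' @param n_replicates Number of generate-fit cycles (>= 100 recommended for
#'   coverage claims).
#' @param null_moderator Optional name of a categorical moderator to test
#'   for omnibus type-I error.
#' @return A one-row tibble of summary statistics, with the per-replicate
#'   results in attribute `"replicates"`.
#' @export
recovery_experiment <- function(config, n_replicates = 100,
                                null_moderator = NULL) {
  stopifnot(inherits(config, "synthetic_config"), n_replicates >= 1)
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- generate_compilation(cfg)
    eff <- add_effect_sizes(impute_missing_sd(sim$records))
    fit <- fit_random_effects(eff)
    est <- fit$coefficients
    out <- tibble::tibble(
      replicate = r,
      mu_hat = est$estimate[1],
      se = est$se[1],
      tau2_hat = fit$tau2,
      covered = est$ci_lb[1] <= config$mu_true &
        config$mu_true <= est$ci_ub[1]
    )
    if (!is.null(null_moderator)) {
      mfit <- fit_moderator_model(eff, null_moderator)
      out$omnibus_p <- mfit$omnibus$p_value
    }
    out
  })
  reps <- dplyr::bind_rows(reps)
  n <- nrow(reps)
  summary <- tibble::tibble(
    n_replicates = n,
    mu_true = config$mu_true,
    tau2_true = config$tau2_true,
    mu_bias = mean(reps$mu_hat) - config$mu_true,
    mu_bias_mc_se = stats::sd(reps$mu_hat) / sqrt(n),
    tau2_bias = mean(reps$tau2_hat) - config$tau2_true,
    coverage = mean(reps$covered),
    coverage_mc_se = sqrt(mean(reps$covered) * (1 - mean(reps$covered)) / n)
  )
  if (!is.null(null_moderator)) {
    rej <- mean(reps$omnibus_p < 0.05)
    summary$rejection_rate <- rej
    summary$rejection_mc_se <- sqrt(rej * (1 - rej) / n)
  }
  attr(summary, "replicates") <- reps
  summary
}
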