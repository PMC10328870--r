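#' Log response ratio of a treatment-control pair
#'
#' The effect size used throughout the pipeline is the natural log of the
#' response ratio, `lnRR = ln(mean_treat / mean_ctrl)`. A value of 0 means
#' the treatment induced no change in aboveground carbon; positive values are
#' gains relative to the control and negative values losses.
#'
#' @param mean_treat,mean_ctrl Arm means (Mg C ha^-1), strictly positive.
#' @return Numeric vector of lnRR values.
#' @examples
#' compute_lnrr(120, 100) # log(1.2)
#' @export
compute_lnrr <- function(mean_treat, mean_ctrl) {
  if (any(!is.finite(mean_treat) | mean_treat <= 0) ||
      any(!is.finite(mean_ctrl) | mean_ctrl <= 0)) {
    abort("Arm means must be finite and strictly positive to form a log ratio.")
  }
  log(mean_treat) - log(mean_ctrl)
}

#' Sampling variance of a log response ratio
#'
#' Delta-method variance of lnRR from the arm standard deviations, replicate
#' counts and means:
#' `sd_treat^2 / (n_treat * mean_treat^2) + sd_ctrl^2 / (n_ctrl * mean_ctrl^2)`.
#' Effect sizes are weighted by the inverse of this variance in every model.
#'
#' @param sd_treat,sd_ctrl Arm standard deviations (Mg C ha^-1); must be
#'   present - impute first with [impute_missing_sd()] if any are missing.
#' @param n_treat,n_ctrl Replicate counts (>= 1).
#' @param mean_treat,mean_ctrl Arm means (> 0).
#' @return Numeric vector of sampling variances.
#' @export
lnrr_variance <- function(sd_treat, n_treat, mean_treat,
                          sd_ctrl, n_ctrl, mean_ctrl) {
  if (any(is.na(sd_treat)) || any(is.na(sd_ctrl))) {
    abort(c("Missing standard deviations.",
            i = "Run `impute_missing_sd()` before computing variances."))
  }
  if (any(sd_treat < 0) || any(sd_ctrl < 0)) {
    abort("Standard deviations must be non-negative.")
  }
  if (any(n_treat < 1) || any(n_ctrl < 1)) {
    abort("Replicate counts must be >= 1.")
  }
  sd_treat^2 / (n_treat * mean_treat^2) + sd_ctrl^2 / (n_ctrl * mean_ctrl^2)
}

#' Back-transform a log response ratio to percent change
#'
#' `(exp(lnrr) - 1) * 100`, the percent change in aboveground carbon relative
#' to the control. Applied to model estimates and to both ends of their 95%
#' confidence intervals (the transform is monotone, so interval order is
#' preserved).
#'
#' @param lnrr Numeric vector of log response ratios.
#' @return Percent change relative to control; always > -100.
#' @examples
#' percent_change(log(1.2)) # 20
#' @export
percent_change <- function(lnrr) {
  (exp(lnrr) - 1) * 100
}

#' Impute missing arm standard deviations from median coefficients of variation
#'
#' For each treatment analysis (interplant / npk / thin) and each arm
#' (treatment, control), the coefficient of variation (CV = SD / mean) is
#' computed across all comparisons of that analysis that report the arm's SD.
#' Each missing SD is then replaced by `median(CV) * reported mean` for its
#' arm. Complete records are untouched, and the provenance columns
#' `sd_imputed_treat` / `sd_imputed_ctrl` record which values were filled, so
#' a sensitivity reanalysis can exclude them.
#'
#' The operation is idempotent: once all SDs are present, re-running it
#' changes nothing.
#'
#' @param data A compilation tibble (see [read_compilation()]).
#' @return The tibble with all SDs present and imputation flags added.
#' @export
impute_missing_sd <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"sd_imputed_treat" %in% names(data)) {
    data$sd_imputed_treat <- FALSE
  }
  if (!"sd_imputed_ctrl" %in% names(data)) {
    data$sd_imputed_ctrl <- FALSE
  }
  for (arm in c("treat", "ctrl")) {
    sd_col <- paste0("sd_", arm)
    mean_col <- paste0("mean_", arm)
    flag_col <- paste0("sd_imputed_", arm)
    miss <- is.na(data[[sd_col]])
    if (!any(miss)) next
    for (trt in unique(data$treatment[miss])) {
      in_group <- data$treatment == trt
      complete <- in_group & !is.na(data[[sd_col]])
      if (!any(complete)) {
        abort(sprintf(
          "No comparison of treatment '%s' reports a %s-arm SD; cannot impute.",
          trt, if (arm == "treat") "treatment" else "control"))
      }
      med_cv <- median(data[[sd_col]][complete] / data[[mean_col]][complete])
      fill <- in_group & miss
      data[[sd_col]][fill] <- med_cv * data[[mean_col]][fill]
      data[[flag_col]][fill] <- TRUE
    }
  }
  data
}

#' Add lnRR effect sizes and sampling variances to a compilation
#'
#' Computes, for every comparison, the log response ratio, its delta-method
#' sampling variance, and the inverse-variance weight. Standard deviations
#' must all be present; run [impute_missing_sd()] first when some are
#' missing.
#'
#' @param data A compilation tibble with complete SDs.
#' @return The tibble with `lnrr`, `variance`, and `weight` columns appended
#'   (plus `sd_imputed_*` flags set to `FALSE` if absent).
#' @export
add_effect_sizes <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"sd_imputed_treat" %in% names(data)) {
    data$sd_imputed_treat <- FALSE
  }
  if (!"sd_imputed_ctrl" %in% names(data)) {
    data$sd_imputed_ctrl <- FALSE
  }
  data |>
    dplyr::mutate(
      lnrr = compute_lnrr(.data$mean_treat, .data$mean_ctrl),
      variance = lnrr_variance(.data$sd_treat, .data$n_treat, .data$mean_treat,
                               .data$sd_ctrl, .data$n_ctrl, .data$mean_ctrl),
      weight = ifelse(.data$variance > 0, 1 / .data$variance, NA_real_)
    )
}
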