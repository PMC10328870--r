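#' Trim comparisons above a covariate ceiling
#'
#' Time-trend regressions are sensitive to sparse data at the old end of the
#' record, so each treatment carries a trimming rule applied before fitting:
#' interplanting drops stands older than 20 years, NPK fertilization drops
#' comparisons more than 5 years after treatment, and thinning keeps all
#' time-since-thinning data (`max_value = Inf`). Rows with the covariate
#' missing are kept (they are excluded later by the model itself).
#'
#' @param data A compilation or effect-size tibble.
#' @param covariate Name (string) of the covariate column.
#' @param max_value Ceiling; rows with covariate strictly greater are
#'   removed.
#' @return The filtered tibble with attribute `n_dropped` recording how many
#'   rows were removed.
#' @export
trim_by_covariate <- function(data, covariate, max_value) {
  if (!covariate %in% names(data)) {
    abort(sprintf("Covariate column '%s' not found.", covariate))
  }
  drop <- !is.na(data[[covariate]]) & data[[covariate]] > max_value
  out <- data[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  out
}

# Default trimming ceilings per treatment analysis.
trim_rules <- function() {
  list(interplant = list(covariate = "stand_age", max_value = 20),
       npk = list(covariate = "time_since_treatment", max_value = 5),
       thin = NULL)
}

#' Fit a time or continuous-covariate meta-regression
#'
#' Same mixed-effects machinery as [fit_moderator_model()] with a continuous
#' covariate (intercept + slope on the lnRR scale), publication-level random
#' effects and REML. The slope is tested by Wald z. The slope is also
#' expressed as percent change per covariate unit, `100 * slope` - the
#' small-effect approximation under which a slope of 0.036 per year reads as
#' "+3.6% per year"; the exact alternative `100 * (exp(slope) - 1)` is
#' reported alongside.
#'
#' @inheritParams fit_random_effects
#' @param covariate Name (string) of the continuous covariate column.
#' @return A `trend_fit` object (a `meta_fit` with trend accessors):
#'   intercept, slope, their 95% CIs, `percent_per_unit`, and drop
#'   bookkeeping.
#' @export
fit_time_meta_regression <- function(data, covariate) {
  n_input <- nrow(data)
  fit <- fit_moderator_model(data, covariate)
  class(fit) <- c("trend_fit", class(fit))
  fit$covariate <- covariate
  fit$intercept <- unname(fit$beta[1])
  fit$slope <- unname(fit$beta[2])
  fit$p_slope <- fit$omnibus$p_value
  fit$percent_per_unit <- 100 * fit$slope
  fit$percent_per_unit_exact <- percent_change(fit$slope)
  fit$n_used <- fit$k
  fit$n_dropped <- n_input - fit$k
  fit
}

#' Covariate value where a fitted trend crosses zero effect
#'
#' For a fitted linear trend on the lnRR scale the effect vanishes at
#' `-intercept / slope`. The crossing is only meaningful at a positive
#' covariate value (an age or a time since treatment), so `NA` is returned
#' when the slope is zero or when intercept and slope share a sign.
#'
#' @param fit A `trend_fit` object, or anything with `intercept` and `slope`
#'   elements.
#' @return The covariate value of the zero crossing, or `NA_real_`.
#' @examples
#' zero_crossing(list(intercept = -0.2, slope = 0.05)) # 4
#' @export
zero_crossing <- function(fit) {
  if (fit$slope == 0) {
    return(NA_real_)
  }
  x0 <- -fit$intercept / fit$slope
  if (x0 <= 0) NA_real_ else x0
}

#' Predicted trend line with a 95% confidence band
#'
#' @param fit A `trend_fit` object.
#' @param grid Covariate values at which to predict; defaults to 100 points
#'   spanning the fitted range.
#' @return A tibble `covariate`, `fit` (lnRR scale), `ci_lb`, `ci_ub`,
#'   `percent`, `percent_lb`, `percent_ub`.
#' @export
trend_line <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  if (is.null(grid)) {
    rng <- fit$covariate_range %||% c(0, 2 * abs(zero_crossing(fit) %||% 10))
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  X <- cbind(1, grid)
  pred <- drop(X %*% fit$beta)
  se <- sqrt(rowSums((X %*% fit$vb) * X))
  z <- qnorm(0.975)
  tibble::tibble(
    covariate = grid,
    fit = pred,
    ci_lb = pred - z * se,
    ci_ub = pred + z * se,
    percent = percent_change(pred),
    percent_lb = percent_change(pred - z * se),
    percent_ub = percent_change(pred + z * se)
  )
}

#' Choose the NPK time variable per application method
#'
#' Fertilization studies that applied NPK continuously over the study period
#' are followed on stand age; studies with pulse applications are followed
#' on time since treatment. This helper adds a `time_var` column holding the
#' appropriate value for each comparison.
#'
#' @param data An NPK compilation tibble with `application_method`,
#'   `stand_age`, and `time_since_treatment` columns.
#' @return The tibble with a `time_var` column appended.
#' @export
npk_time_variable <- function(data) {
  needed <- c("application_method", "stand_age", "time_since_treatment")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    time_var = dplyr::if_else(.data$application_method == "continuous",
                              .data$stand_age, .data$time_since_treatment)
  )
}
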