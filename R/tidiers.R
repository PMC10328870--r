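#' Tidy a fitted meta-analytic model
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `k` (observations behind the
#'   term), `estimate`, `se`, `ci_lb`, `ci_ub` on the lnRR scale, and
#'   `percent`, `percent_lb`, `percent_ub` back-transformed to percent
#'   change relative to the control.
#' @method tidy meta_fit
#' @export
tidy.meta_fit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a fitted meta-analytic model
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return A tibble with `moderator`, `model`, `k` (comparisons), `m`
#'   (publications), `tau2`, `QM`, `df`, `p_value`.
#' @method glance meta_fit
#' @export
glance.meta_fit <- function(x, ...) {
  tibble::tibble(
    moderator = x$moderator,
    model = x$model,
    k = x$k,
    m = x$m,
    tau2 = x$tau2,
    QM = x$omnibus$QM,
    df = x$omnibus$df,
    p_value = x$omnibus$p_value
  )
}

#' @rdname glance.meta_fit
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  out <- NextMethod()
  out$intercept <- x$intercept
  out$slope <- x$slope
  out$percent_per_unit <- x$percent_per_unit
  out$percent_per_unit_exact <- x$percent_per_unit_exact
  out$zero_crossing <- zero_crossing(x)
  out
}

#' Tidy the net-balance regression
#'
#' @param x A `ghg_fit` object.
#' @param ... Unused.
#' @return A two-row tibble of the OLS terms (intercept, slope) with
#'   estimates, standard errors and p-values.
#' @method tidy ghg_fit
#' @export
tidy.ghg_fit <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    se = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p_value = unname(s[, 4])
  )
}

#' @rdname tidy.ghg_fit
#' @method glance ghg_fit
#' @export
glance.ghg_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    intercept = x$intercept,
    slope = x$slope,
    r_squared = x$r_squared,
    p_value = x$p_value,
    break_even_n = x$break_even_n,
    median_net_balance = x$median_net_balance
  )
}

#' Forest-style coefficient plot of a fitted meta-analytic model
#'
#' @param object A `meta_fit` object.
#' @param ... Unused.
#' @return A ggplot of back-transformed percent changes with 95% CIs.
#' @method autoplot meta_fit
#' @export
autoplot.meta_fit <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::mutate(label = sprintf("%s (%d)", .data$term, .data$k))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$percent, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$percent_lb,
                                          xmax = .data$percent_ub)) +
    ggplot2::labs(
      x = "Change in aboveground carbon relative to control (%)",
      y = NULL,
      title = if (is.na(object$moderator)) "Pooled effect"
              else paste("Moderator:", object$moderator)
    ) +
    ggplot2::theme_minimal()
}

#' Fitted trend with its 95% confidence band
#'
#' @param object A `trend_fit` object.
#' @param data Optional effect-size tibble to overlay the raw comparisons.
#' @param ... Unused.
#' @return A ggplot on the lnRR scale.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, data = NULL, ...) {
  grid <- NULL
  if (!is.null(data) && object$covariate %in% names(data)) {
    rng <- range(data[[object$covariate]], na.rm = TRUE)
    grid <- seq(rng[1], rng[2], length.out = 100)
  }
  line <- trend_line(object, grid = grid)
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$covariate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lb, ymax = .data$ci_ub),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = object$covariate, y = "lnRR") +
    ggplot2::theme_minimal()
  if (!is.null(data) && object$covariate %in% names(data)) {
    p <- p + ggplot2::geom_point(
      data = data, alpha = 0.5,
      ggplot2::aes(x = .data[[object$covariate]], y = .data$lnrr))
  }
  p
}

#' Scatter of net carbon balance against N applied with the fitted line
#'
#' @param object A `ghg_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ghg_fit
#' @export
autoplot.ghg_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$n_applied_mg, y = .data$net_balance)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "N applied (Mg N ha⁻¹)",
                  y = "Net balance (Mg CO₂e ha⁻¹)") +
    ggplot2::theme_minimal()
}

#' Funnel plot of effect sizes against standard errors
#'
#' @param data A tibble with `lnrr` and `variance` columns.
#' @param center Vertical reference (defaults to the inverse-variance mean).
#' @return A ggplot with the conventional inverted SE axis.
#' @export
plot_funnel <- function(data, center = NULL) {
  tab <- funnel_data(data)
  if (is.null(center)) {
    w <- 1 / pmax(data$variance, VARIANCE_FLOOR)
    center <- sum(w * data$lnrr) / sum(w)
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lnrr, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = center, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "lnRR", y = "Standard error") +
    ggplot2::theme_minimal()
}
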