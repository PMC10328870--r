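#' Greenhouse-gas accounting constants for nitrogen fertilization
#'
#' Bundles the constants of the fertilizer carbon-cost calculation:
#'
#' * `n2o_fraction` - fraction of applied N emitted in-field as N2O-N
#'   (default 0.0254, i.e. a 2.54% emission factor);
#' * `gwp_n2o` - 100-year global warming potential of N2O (default 298);
#' * `infield_ef` - in-field emission factor in Mg CO2e per Mg N applied,
#'   derived as `n2o_fraction * (44/28) * gwp_n2o` (44/28 converts N2O-N
#'   mass to N2O mass) and reported to one decimal: 11.9 at the defaults;
#' * `upstream_ef` - manufacturing emissions, 4.0 Mg CO2e per Mg N produced;
#' * `c_to_co2e` - 44/12, converting a carbon mass to CO2 equivalents.
#'
#' @param n2o_fraction,gwp_n2o,upstream_ef Override any constant.
#' @return A `ghg_constants` list.
#' @examples
#' ghg_constants()$infield_ef # 11.9
#' @export
ghg_constants <- function(n2o_fraction = 0.0254, gwp_n2o = 298,
                          upstream_ef = 4.0) {
  stopifnot(n2o_fraction > 0, gwp_n2o > 0, upstream_ef > 0)
  structure(
    list(
      n2o_fraction = n2o_fraction,
      gwp_n2o = gwp_n2o,
      infield_ef = derive_infield_ef(n2o_fraction, gwp_n2o),
      upstream_ef = upstream_ef,
      c_to_co2e = 44 / 12
    ),
    class = "ghg_constants"
  )
}

#' Derive the in-field emission factor from the N2O fraction and GWP
#'
#' The mass of N emitted as N2O-N per Mg of N applied (`n2o_fraction`) is
#' converted to N2O mass by the molar ratio 44/28 and to CO2 equivalents by
#' the 100-year GWP. At the defaults (2.54%, GWP 298) this gives 11.9 Mg
#' CO2e per Mg N.
#'
#' @param n2o_fraction Fraction of applied N emitted as N2O-N (> 0 allowed
#'   to be 0 for a no-emission scenario).
#' @param gwp_n2o 100-year global warming potential of N2O.
#' @param digits Decimal places for reporting (default 1, matching how the
#'   factor is conventionally quoted).
#' @return In-field emission factor, Mg CO2e per Mg N applied.
#' @examples
#' derive_infield_ef(0.0254, 298) # 11.9
#' @export
derive_infield_ef <- function(n2o_fraction, gwp_n2o, digits = 1) {
  if (n2o_fraction < 0 || gwp_n2o < 0) {
    abort("Emission inputs must be non-negative.")
  }
  round(n2o_fraction * (44 / 28) * gwp_n2o, digits)
}

#' Convert per-tree nitrogen applications to per-hectare
#'
#' @param kg_per_tree Nitrogen applied per tree (kg N tree^-1).
#' @param stems_per_ha Stand density (stems ha^-1); required and positive.
#' @return Nitrogen applied per hectare (kg N ha^-1).
#' @export
per_tree_to_per_ha <- function(kg_per_tree, stems_per_ha) {
  if (any(is.na(stems_per_ha)) || any(stems_per_ha <= 0)) {
    abort("Per-tree N applications need a positive stand density to convert.")
  }
  kg_per_tree * stems_per_ha
}

#' Net carbon balance of a fertilized comparison
#'
#' The additional aboveground carbon gained under fertilization
#' (`delta_c`, treated minus control, Mg C ha^-1) is converted to CO2
#' equivalents by 44/12 and offset against the in-field and upstream
#' emissions of the N applied:
#' `net = delta_c * 44/12 - n_applied * (infield_ef + upstream_ef)`.
#'
#' @param delta_c Carbon gain, Mg C ha^-1 (may be negative).
#' @param n_applied Nitrogen applied, Mg N ha^-1 (>= 0).
#' @param constants A [ghg_constants()] list.
#' @return Net balance, Mg CO2e ha^-1; positive means a net climate benefit.
#' @export
net_balance <- function(delta_c, n_applied, constants = ghg_constants()) {
  if (any(n_applied < 0, na.rm = TRUE)) {
    abort("`n_applied` must be non-negative.")
  }
  delta_c * constants$c_to_co2e -
    n_applied * (constants$infield_ef + constants$upstream_ef)
}

#' Per-comparison greenhouse-gas table for fertilized stands
#'
#' For every NPK comparison, computes the raw carbon gain (treated minus
#' control arm means), the N applied in Mg ha^-1 (per-tree applications are
#' converted with the reported stand density), the fertilizer emissions, and
#' the net CO2e balance.
#'
#' @param data A compilation tibble of NPK comparisons, with `n_applied`
#'   (kg), `n_applied_unit` (`kg_per_ha` or `kg_per_tree`) and, where
#'   needed, `stand_density`.
#' @param constants A [ghg_constants()] list.
#' @return A tibble with `study_id`, `delta_c` (Mg C ha^-1), `n_applied_mg`
#'   (Mg N ha^-1), `emissions`, and `net_balance` (both Mg CO2e ha^-1).
#' @export
ghg_table <- function(data, constants = ghg_constants()) {
  needed <- c("mean_treat", "mean_ctrl", "n_applied", "n_applied_unit")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  data <- data[!is.na(data$n_applied), , drop = FALSE]
  per_tree <- data$n_applied_unit == "kg_per_tree"
  kg_ha <- data$n_applied
  if (any(per_tree)) {
    if (!"stand_density" %in% names(data)) {
      abort("Per-tree N applications present but no `stand_density` column.")
    }
    kg_ha[per_tree] <- per_tree_to_per_ha(data$n_applied[per_tree],
                                          data$stand_density[per_tree])
  }
  n_mg <- kg_ha / 1000
  delta_c <- data$mean_treat - data$mean_ctrl
  tibble::tibble(
    study_id = data$study_id,
    delta_c = delta_c,
    n_applied_mg = n_mg,
    emissions = n_mg * (constants$infield_ef + constants$upstream_ef),
    net_balance = net_balance(delta_c, n_mg, constants)
  )
}

#' Regression of net carbon balance on nitrogen applied
#'
#' Ordinary least squares of the per-comparison net CO2e balance on the
#' amount of N applied (Mg N ha^-1). When the fitted slope is negative the
#' break-even application rate `-intercept / slope` - the N rate at which
#' the climate benefit of fertilization becomes null - is reported, along
#' with the median net balance across comparisons.
#'
#' @param ghg A tibble from [ghg_table()] (columns `n_applied_mg`,
#'   `net_balance`), with at least 3 rows and a non-constant predictor.
#' @return A `ghg_fit` object: `intercept`, `slope`, `r_squared`, `p_value`,
#'   `break_even_n` (Mg N ha^-1, or `NA`), `median_net_balance`, `n`.
#' @export
fit_net_balance_regression <- function(ghg) {
  if (nrow(ghg) < 3) {
    abort("Net-balance regression needs at least 3 comparisons.")
  }
  if (length(unique(ghg$n_applied_mg)) < 2) {
    abort("`n_applied_mg` is constant; slope is unidentifiable.")
  }
  fit <- lm(net_balance ~ n_applied_mg, data = ghg)
  # a noiseless collinear input is legitimate (and handled below), so the
  # perfect-fit warning from summary.lm is not informative here
  s <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  p_value <- if (s$sigma == 0) {
    if (slope == 0) 1 else 0  # noiseless collinear input
  } else {
    unname(s$coefficients[2, 4])
  }
  structure(
    list(
      intercept = intercept,
      slope = slope,
      r_squared = s$r.squared,
      p_value = p_value,
      break_even_n = if (slope < 0 && intercept > 0) -intercept / slope
                     else NA_real_,
      median_net_balance = median(ghg$net_balance),
      n = nrow(ghg),
      data = tibble::as_tibble(ghg),
      lm = fit
    ),
    class = "ghg_fit"
  )
}

#' @export
print.ghg_fit <- function(x, ...) {
  cat("Net carbon balance vs N applied (OLS)\n")
  cat(sprintf("  n = %d, intercept = %.3f, slope = %.3f Mg CO2e per Mg N, R^2 = %.3f, p = %.4g\n",
              x$n, x$intercept, x$slope, x$r_squared, x$p_value))
  cat(sprintf("  median net balance = %.2f Mg CO2e ha^-1\n", x$median_net_balance))
  if (!is.na(x$break_even_n)) {
    cat(sprintf("  break-even N rate = %.3f Mg N ha^-1\n", x$break_even_n))
  }
  invisible(x)
}
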