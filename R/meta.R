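#' @title Publication-level random-effects meta-analysis engine
#'
#' @description
#' All models in the package share one marginal structure: for comparison i
#' in publication j,
#'
#'   y_ij = x_ij' beta + u_j + e_ij,   u_j ~ N(0, tau2),  e_ij ~ N(0, v_ij),
#'
#' where y is the lnRR, v its known sampling variance, and u_j a
#' publication-level random effect that absorbs the non-independence of
#' multiple comparisons reported by the same study. tau2 is estimated by
#' restricted maximum likelihood: the restricted log-likelihood is profiled
#' over tau2 >= 0 with a deterministic 1-D bounded search, and beta is the
#' GLS estimate under the fitted marginal covariance. Inference is Wald-z.
#'
#' The marginal covariance is block-diagonal by publication, so the
#' likelihood is evaluated with grouped sums via the Woodbury identity
#' rather than dense matrix inversion; fits scale linearly in the number of
#' comparisons.
#'
#' @name meta-engine
#' @keywords internal
NULL

# Variance floor keeping inverse-variance weights finite when an arm SD is 0.
VARIANCE_FLOOR <- 1e-12

# V^-1 A for V = diag(v) + tau2 * Z Z' (Z = publication indicator), via
# Woodbury: V^-1 = W - W Z diag(tau2 / (1 + tau2 s_j)) Z' W, with W = diag(1/v)
# and s_j the within-publication sum of weights.
vinv_mult <- function(A, w, g, cj) {
  A <- as.matrix(A)
  WA <- A * w
  G <- rowsum(WA, g, reorder = FALSE)
  WA - w * (G[match(g, rownames(G)), , drop = FALSE] * cj[match(g, rownames(G))])
}

# Restricted log-likelihood (up to a constant) and GLS pieces at a given tau2.
reml_pieces <- function(tau2, y, v, g, X) {
  w <- 1 / v
  s_j <- rowsum(w, g, reorder = FALSE)[, 1]
  cj <- tau2 / (1 + tau2 * s_j)
  ViX <- vinv_mult(X, w, g, cj)
  Viy <- vinv_mult(matrix(y), w, g, cj)
  XtViX <- crossprod(X, ViX)
  b <- solve(XtViX, crossprod(X, Viy))
  resid <- y - X %*% b
  Vir <- Viy - ViX %*% b
  quad <- sum(resid * Vir)
  logdetV <- sum(log(v)) + sum(log1p(tau2 * s_j))
  ll <- -0.5 * (logdetV + determinant(XtViX, logarithm = TRUE)$modulus[1] + quad)
  list(ll = ll, beta = drop(b), XtViX = XtViX)
}

# Core fitter shared by the overall, moderator, and trend models.
# `tested` indexes the coefficients entering the omnibus Wald block.
reml_fit <- function(y, v, study, X, tested = seq_len(ncol(X)),
                     terms = colnames(X), tol = 1e-8) {
  k <- length(y)
  if (k == 0) {
    abort("No effect sizes to fit.")
  }
  if (any(!is.finite(y))) {
    abort("Effect sizes must be finite.")
  }
  n_floored <- sum(v < VARIANCE_FLOOR)
  v <- pmax(v, VARIANCE_FLOOR)
  g <- as.character(study)
  m <- length(unique(g))
  p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("Design matrix is rank deficient; a moderator may be constant.")
  }

  if (k - p < 1) {
    tau2 <- 0
  } else {
    upper <- max(10 * var(y), 1e-4)
    obj <- function(t2) reml_pieces(t2, y, v, g, X)$ll
    opt <- optimize(obj, c(0, upper), maximum = TRUE, tol = tol)
    tau2 <- if (obj(0) >= opt$objective) 0 else opt$maximum
  }

  at <- reml_pieces(tau2, y, v, g, X)
  vb <- solve(at$XtViX)
  beta <- at$beta
  se <- sqrt(diag(vb))
  zcrit <- qnorm(0.975)

  bt <- beta[tested]
  QM <- drop(crossprod(bt, solve(vb[tested, tested, drop = FALSE], bt)))
  df <- length(tested)
  p_val <- pchisq(QM, df = df, lower.tail = FALSE)

  coefficients <- tibble::tibble(
    term = terms,
    estimate = unname(beta),
    se = unname(se),
    ci_lb = unname(beta - zcrit * se),
    ci_ub = unname(beta + zcrit * se)
  )

  structure(
    list(
      coefficients = coefficients,
      beta = setNames(beta, terms),
      vb = vb,
      tau2 = tau2,
      k = k,
      m = m,
      omnibus = list(QM = QM, df = df, p_value = p_val),
      tested = tested,
      n_floored = n_floored
    ),
    class = "meta_fit"
  )
}

#' Fit the overall publication-level random-effects model
#'
#' Estimates the pooled lnRR across all comparisons of a treatment, with a
#' publication-level random effect for the non-independence of multiple
#' comparisons per study, inverse-variance weighting, REML estimation of the
#' between-publication variance tau^2, and Wald-z 95% confidence intervals.
#' Point estimate and interval are also back-transformed to percent change
#' relative to the control.
#'
#' @param data A tibble with effect sizes, as produced by
#'   [add_effect_sizes()]: columns `lnrr`, `variance`, and `study_id`.
#' @return A `meta_fit` object; see [tidy.meta_fit()] and
#'   [glance.meta_fit()].
#' @examples
#' eff <- tibble::tibble(lnrr = c(0.1, 0.3, 0.2), variance = 0.02,
#'                       study_id = c("a", "a", "b"))
#' fit_random_effects(eff)
#' @export
fit_random_effects <- function(data) {
  check_effects(data)
  X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "overall"))
  fit <- reml_fit(data$lnrr, data$variance, data$study_id, X)
  fit$model <- "overall"
  fit$moderator <- NA_character_
  fit$coefficients$k <- nrow(data)
  finish_meta_fit(fit)
}

#' Fit a single-moderator mixed-effects meta-regression
#'
#' Moderators are tested one at a time in separate models, each using all
#' comparisons with that moderator recorded (rows missing it are dropped for
#' that model only). A categorical moderator is fitted as cell means (no
#' intercept), so each coefficient is that category's mean lnRR; categories
#' with a single observation are dropped before fitting. A continuous
#' moderator is fitted as intercept + slope. The publication-level random
#' effect, REML estimation and Wald inference are as in
#' [fit_random_effects()]. The omnibus Wald chi-square tests all cell means
#' for categorical moderators and the slope alone for continuous ones.
#'
#' @inheritParams fit_random_effects
#' @param moderator Name (string) of the moderator column in `data`.
#' @return A `meta_fit` object with per-category observation counts and
#'   dropped-category bookkeeping.
#' @export
fit_moderator_model <- function(data, moderator) {
  check_effects(data)
  if (!moderator %in% names(data)) {
    abort(sprintf("Moderator column '%s' not found in `data`.", moderator))
  }
  x <- data[[moderator]]
  keep <- !is.na(x)
  n_missing <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  x <- x[keep]
  if (nrow(data) == 0) {
    abort(sprintf("No rows record moderator '%s'.", moderator))
  }

  if (is.numeric(x)) {
    if (length(unique(x)) < 2) {
      abort(sprintf("Moderator '%s' is constant; slope is unidentifiable.",
                    moderator))
    }
    X <- cbind(intercept = 1, slope = x)
    fit <- reml_fit(data$lnrr, data$variance, data$study_id, X, tested = 2L)
    fit$model <- "continuous"
    fit$coefficients$k <- nrow(data)
    fit$dropped_categories <- character()
  } else {
    counts <- table(x)
    dropped <- names(counts)[counts < 2]
    keep_cat <- !x %in% dropped
    if (!any(keep_cat)) {
      abort(sprintf(
        "Every category of '%s' has fewer than 2 observations; nothing to fit.",
        moderator))
    }
    data <- data[keep_cat, , drop = FALSE]
    x <- factor(x[keep_cat])
    X <- sapply(levels(x), function(l) as.numeric(x == l))
    colnames(X) <- levels(x)
    fit <- reml_fit(data$lnrr, data$variance, data$study_id, X)
    fit$model <- "categorical"
    fit$coefficients$k <- as.integer(table(x)[fit$coefficients$term])
    fit$dropped_categories <- dropped
  }
  fit$moderator <- moderator
  fit$n_missing_moderator <- n_missing
  finish_meta_fit(fit)
}

# Back-transform coefficient estimates and CI bounds to percent change.
finish_meta_fit <- function(fit) {
  fit$coefficients <- fit$coefficients |>
    dplyr::mutate(
      percent = percent_change(.data$estimate),
      percent_lb = percent_change(.data$ci_lb),
      percent_ub = percent_change(.data$ci_ub)
    ) |>
    dplyr::relocate("k", .after = "term")
  fit
}

check_effects <- function(data) {
  missing_cols <- setdiff(c("lnrr", "variance", "study_id"), names(data))
  if (length(missing_cols) > 0) {
    abort(c(
      paste0("`data` is missing columns: ",
             paste(missing_cols, collapse = ", "), "."),
      i = "Run `add_effect_sizes()` (after `impute_missing_sd()`) first."))
  }
  if (any(is.na(data$lnrr)) || any(is.na(data$variance))) {
    abort("`lnrr` and `variance` must not contain missing values.")
  }
  invisible(data)
}

#' Omnibus Wald test of a fitted model's tested coefficients
#'
#' The joint Wald chi-square statistic QM = b' V_b^-1 b over the tested
#' coefficient block (all cell means for a categorical model, the slope for
#' a continuous model, the pooled mean for the overall model), with degrees
#' of freedom equal to the block size. A moderator is called significant
#' when p < 0.05.
#'
#' @param fit A `meta_fit` object.
#' @return A one-row tibble: `QM`, `df`, `p_value`.
#' @export
omnibus_test <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  tibble::tibble(QM = fit$omnibus$QM, df = fit$omnibus$df,
                 p_value = fit$omnibus$p_value)
}

#' Funnel-plot table of effect sizes against their standard errors
#'
#' @param data A tibble with `lnrr` and `variance` columns.
#' @return A tibble of `(lnrr, se)` pairs sorted by increasing standard
#'   error (most precise comparisons first), for funnel-plot diagnostics of
#'   publication bias.
#' @seealso [egger_regression()], [plot_funnel()]
#' @export
funnel_data <- function(data) {
  if (!all(c("lnrr", "variance") %in% names(data))) {
    abort("`data` must have `lnrr` and `variance` columns.")
  }
  tibble::tibble(lnrr = data$lnrr, se = sqrt(data$variance)) |>
    dplyr::arrange(.data$se)
}

#' Egger regression test for funnel asymmetry
#'
#' Classic Egger test: the standardized effect `lnrr / se` is regressed on
#' precision `1 / se`; a regression intercept far from zero indicates an
#' asymmetric funnel. Reported as a diagnostic only - it does not feed back
#' into the meta-analytic models.
#'
#' @inheritParams funnel_data
#' @return A one-row tibble: `intercept`, `se`, `ci_lb`, `ci_ub`,
#'   `statistic`, `df`, `p_value`. Requires at least 3 comparisons.
#' @export
egger_regression <- function(data) {
  tab <- funnel_data(data)
  if (nrow(tab) < 3) {
    abort("Egger regression needs at least 3 comparisons.")
  }
  fit <- lm(I(lnrr / se) ~ I(1 / se), data = tab)
  est <- coef(fit)[1]
  se <- sqrt(diag(vcov(fit)))[1]
  df <- fit$df.residual
  tcrit <- qt(0.975, df)
  tibble::tibble(
    intercept = unname(est),
    se = unname(se),
    ci_lb = unname(est - tcrit * se),
    ci_ub = unname(est + tcrit * se),
    statistic = unname(est / se),
    df = df,
    p_value = unname(2 * pt(abs(est / se), df, lower.tail = FALSE))
  )
}

#' Sensitivity reanalysis excluding imputed standard deviations
#'
#' Refits the overall random-effects model twice - once on all comparisons
#' (with missing SDs imputed from median coefficients of variation) and once
#' restricted to comparisons whose SDs were all reported - and tabulates the
#' difference in back-transformed percent change. Results are flagged
#' `robust` when the sign of each pooled estimate agrees between the two
#' fits.
#'
#' @param data A compilation tibble (raw arm summaries; imputation is
#'   performed internally).
#' @return A `sensitivity_result` list: `fit_all`, `fit_complete`,
#'   `difference` (tibble), `n_all`, `n_complete`, `n_excluded`.
#' @export
sensitivity_reanalysis <- function(data) {
  imputed <- impute_missing_sd(data)
  eff_all <- add_effect_sizes(imputed)
  complete <- !(eff_all$sd_imputed_treat | eff_all$sd_imputed_ctrl)
  if (!any(complete)) {
    abort("No comparison reports both SDs; sensitivity reanalysis impossible.")
  }
  fit_all <- fit_random_effects(eff_all)
  fit_complete <- fit_random_effects(eff_all[complete, , drop = FALSE])
  difference <- tibble::tibble(
    term = fit_all$coefficients$term,
    percent_all = fit_all$coefficients$percent,
    percent_complete = fit_complete$coefficients$percent,
    difference = fit_all$coefficients$percent -
      fit_complete$coefficients$percent,
    robust = sign(fit_all$coefficients$estimate) ==
      sign(fit_complete$coefficients$estimate)
  )
  structure(
    list(
      fit_all = fit_all,
      fit_complete = fit_complete,
      difference = difference,
      n_all = nrow(eff_all),
      n_complete = sum(complete),
      n_excluded = sum(!complete)
    ),
    class = "sensitivity_result"
  )
}

#' @export
print.meta_fit <- function(x, ...) {
  header <- switch(x$model,
    overall = "Random-effects meta-analysis (publication-level random effect)",
    categorical = sprintf("Mixed-effects meta-regression: moderator '%s' (cell means)",
                          x$moderator),
    continuous = sprintf("Mixed-effects meta-regression: moderator '%s' (slope)",
                         x$moderator))
  cat(header, "\n")
  cat(sprintf("k = %d comparisons, m = %d publications, tau^2 = %.5f (REML)\n",
              x$k, x$m, x$tau2))
  cat(sprintf("Omnibus: QM = %.3f, df = %d, p = %.4g\n",
              x$omnibus$QM, x$omnibus$df, x$omnibus$p_value))
  if (length(x$dropped_categories %||% character()) > 0) {
    cat("Dropped single-observation categories:",
        paste(x$dropped_categories, collapse = ", "), "\n")
  }
  print(x$coefficients)
  invisible(x)
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Sensitivity reanalysis: %d comparisons total, %d with reported SDs (%d excluded)\n",
    x$n_all, x$n_complete, x$n_excluded))
  print(x$difference)
  invisible(x)
}
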