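# Brute-force REML oracle, independent of the package's fitter: dense
# covariance matrices, explicit inversion, and a grid search over tau2
# (coarse pass at 1e-4 refined locally to 1e-5; the restricted profile is
# unimodal in tau2 so the two-stage grid finds the same optimum as a full
# 1e-5 sweep).
oracle_reml_ll <- function(tau2, y, v, study, des) {
  Z <- outer(study, unique(study), "==") * 1
  V <- diag(v, length(v)) + tau2 * Z %*% t(Z)
  Vi <- solve(V)
  XtViX <- t(des) %*% Vi %*% des
  b <- solve(XtViX, t(des) %*% Vi %*% y)
  r <- y - des %*% b
  -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

oracle_gls <- function(tau2, y, v, study, des) {
  Z <- outer(study, unique(study), "==") * 1
  V <- diag(v, length(v)) + tau2 * Z %*% t(Z)
  Vi <- solve(V)
  XtViX <- t(des) %*% Vi %*% des
  b <- drop(solve(XtViX, t(des) %*% Vi %*% y))
  list(beta = b, vb = solve(XtViX))
}

oracle_reml_fit <- function(y, v, study, des = matrix(1, length(y), 1),
                            upper = 1) {
  t0 <- upper / 2
  prev_step <- upper
  for (step in c(1e-4, 1e-5, 1e-7, 1e-9)) {
    lo <- max(0, t0 - 2 * prev_step)
    hi <- min(upper, t0 + 2 * prev_step)
    grid <- seq(lo, hi, by = step)
    prev_step <- step
    ll <- vapply(grid, oracle_reml_ll, 0, y = y, v = v, study = study,
                 des = des)
    t0 <- grid[which.max(ll)]
  }
  c(list(tau2 = t0), oracle_gls(t0, y, v, study, des))
}

# Small compilation fixture covering both units, shared controls and a
# missing-SD row; built in code so tests carry no stored data.
make_fixture_compilation <- function() {
  tibble::tibble(
    study_id = c("S1", "S1", "S1", "S2", "S3"),
    site_id = paste0("site", 1:5),
    treatment = c("thin", "thin", "thin", "interplant", "npk"),
    unit = c("carbon", "carbon", "carbon", "biomass", "carbon"),
    mean_treat = c(40, 35, 30, 100, 25),
    mean_ctrl = c(60, 60, 60, 80, 20),
    sd_treat = c(8, 7, NA, 20, 5),
    sd_ctrl = c(12, 12, NA, 16, 4),
    n_treat = c(3, 3, 3, 4, 5),
    n_ctrl = c(3, 3, 3, 4, 5),
    control_id = c("S1_c1", "S1_c1", "S1_c1", "S2_c1", "S3_c1"),
    tree_genus = c("Pinus", "Pinus", "Pinus", "Eucalyptus", "Pinus"),
    intercrop_genus = c(NA, NA, NA, "Acacia", NA),
    prev_land_use = "plantation",
    soil_moisture_regime = c("udic", "udic", "xeric", "ustic", "udic"),
    wood_type = c("softwood", "softwood", "softwood", "hardwood", "softwood"),
    experimental_design = c(NA, NA, NA, "additive", NA),
    application_method = c(NA, NA, NA, NA, "pulse"),
    stand_age = c(12, 12, 12, 8, 5),
    time_since_treatment = c(2, 2, 5, NA, 1),
    map_mm = c(900, 900, 900, 1500, 1200),
    basal_area_removed = c(30, 45, 60, NA, NA),
    n_applied = c(NA, NA, NA, NA, 150),
    n_applied_unit = c(NA, NA, NA, NA, "kg_per_ha"),
    stand_density = c(NA, NA, NA, NA, 1200)
  )
}

# Effect-size tibble straight from vectors, for model-level tests.
make_effects <- function(lnrr, variance, study_id = as.character(seq_along(lnrr)),
                         ...) {
  tibble::tibble(lnrr = lnrr, variance = variance, study_id = study_id, ...)
}
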