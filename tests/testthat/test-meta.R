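test_that("degenerate fits behave: one comparison, zero heterogeneity", {
  one <- fit_random_effects(make_effects(0.5, 0.04))
  expect_equal(one$beta[["overall"]], 0.5)
  expect_equal(one$coefficients$se, 0.2)
  expect_equal(one$tau2, 0)
  expect_equal(one$k, 1)

  five <- fit_random_effects(make_effects(rep(0.3, 5), rep(0.02, 5)))
  expect_equal(five$beta[["overall"]], 0.3)
  expect_equal(five$tau2, 0, tolerance = 1e-8)
  expect_error(fit_random_effects(make_effects(numeric(0), numeric(0))), "No effect")
})

test_that("REML matches the frozen grid-search oracle on the 3-point instance", {
  # expected values computed beforehand with a tau2 grid (step 1e-5) over the
  # restricted likelihood, and confirmed independently with metafor::rma.mv
  fit <- fit_random_effects(make_effects(c(0.1, 0.5, 0.9), rep(0.04, 3)))
  expect_equal(fit$tau2, 0.12, tolerance = 1e-4)
  expect_equal(fit$beta[["overall"]], 0.5, tolerance = 1e-6)
  expect_equal(fit$coefficients$se, 0.2309401, tolerance = 1e-6)
})

test_that("REML matches the brute-force oracle on random small instances", {
  withr::with_seed(421, {
    for (i in 1:5) {
      k <- sample(4:10, 1)
      study <- as.character(sample(ceiling(k / 2), k, replace = TRUE))
      y <- rnorm(k, 0.2, 0.25)
      v <- runif(k, 0.01, 0.08)
      fit <- fit_random_effects(make_effects(y, v, study))
      orc <- oracle_reml_fit(y, v, study)
      expect_equal(fit$tau2, orc$tau2, tolerance = 1.1e-4)
      expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-6)
    }
  })
})

test_that("with tau2 = 0 and singleton studies the fit collapses to the inverse-variance mean", {
  y <- c(0.28, 0.30, 0.31, 0.29)
  v <- c(0.05, 0.02, 0.04, 0.03)
  fit <- fit_random_effects(make_effects(y, v))
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
  w <- 1 / v
  expect_equal(fit$beta[["overall"]], sum(w * y) / sum(w), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, sqrt(1 / sum(w)), tolerance = 1e-8)
})

test_that("zero sampling variances are floored rather than fatal", {
  fit <- fit_random_effects(make_effects(c(0.2, 0.2), c(0, 0.04)))
  expect_equal(fit$n_floored, 1)
  expect_true(is.finite(fit$beta[["overall"]]))
})

test_that("categorical moderators give cell means; within-category weighted means at tau2 = 0", {
  eff <- make_effects(c(0.10, 0.12, 0.11, 0.50, 0.52),
                      rep(0.04, 5),
                      moderator = c("a", "a", "a", "b", "b"))
  fit <- fit_moderator_model(eff, "moderator")
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
  expect_equal(unname(fit$beta), c(mean(c(0.10, 0.12, 0.11)), mean(c(0.50, 0.52))),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$k, c(3L, 2L))
  expect_equal(fit$omnibus$df, 2)
})

test_that("single-observation categories are dropped before fitting", {
  eff <- make_effects(c(0.1, 0.2, 0.3, 0.9), rep(0.04, 4),
                      genus = c("Pinus", "Pinus", "Pinus", "Alnus"))
  fit <- fit_moderator_model(eff, "genus")
  expect_equal(fit$dropped_categories, "Alnus")
  expect_equal(fit$coefficients$term, "Pinus")
  expect_equal(fit$k, 3)
  expect_error(
    fit_moderator_model(make_effects(c(0.1, 0.2), rep(0.04, 2),
                                     g = c("a", "b")), "g"),
    "fewer than 2")
  expect_error(fit_moderator_model(eff, "absent_column"), "not found")
})

test_that("moderator GLS coefficients match direct linear algebra at the oracle tau2", {
  # frozen 3-category toy instance, verified against metafor::rma.mv
  eff <- make_effects(
    c(0.05, 0.15, 0.42, 0.50, -0.10, -0.30, 0.20, 0.35),
    c(0.02, 0.03, 0.04, 0.02, 0.05, 0.03, 0.02, 0.04),
    moderator = c("a", "a", "b", "b", "c", "c", "a", "b"))
  fit <- fit_moderator_model(eff, "moderator")
  expect_equal(unname(fit$beta), c(0.13125, 0.4425, -0.225), tolerance = 1e-6)
  expect_equal(fit$omnibus$QM, 24.5775, tolerance = 1e-4)

  # and a multi-comparison-per-study instance against the oracle
  withr::with_seed(77, {
    study <- as.character(rep(1:4, each = 2))
    cat <- c("a", "b", "a", "b", "a", "b", "a", "b")
    y <- rnorm(8, ifelse(cat == "a", 0.1, 0.4), 0.2)
    v <- runif(8, 0.01, 0.05)
    fit2 <- fit_moderator_model(make_effects(y, v, study, moderator = cat),
                                "moderator")
    des <- cbind(a = as.numeric(cat == "a"), b = as.numeric(cat == "b"))
    orc <- oracle_reml_fit(y, v, study, des)
    expect_equal(fit2$tau2, orc$tau2, tolerance = 1.1e-4)
    expect_equal(unname(fit2$beta), unname(orc$beta), tolerance = 1e-6)
  })
})

test_that("continuous moderators are fitted as intercept + slope with the slope tested", {
  eff <- make_effects(c(0.1, 0.2, 0.3, 0.4), rep(0.02, 4), age = c(2, 4, 6, 8))
  fit <- fit_moderator_model(eff, "age")
  expect_equal(fit$coefficients$term, c("intercept", "slope"))
  expect_equal(fit$omnibus$df, 1)
  expect_equal(unname(fit$beta[2]), 0.05, tolerance = 1e-6)
  expect_error(fit_moderator_model(
    make_effects(c(0.1, 0.2), rep(0.02, 2), age = c(3, 3)), "age"),
    "constant")
})

test_that("rows missing the moderator are dropped for that model only", {
  eff <- make_effects(c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.02, 5),
                      mod = c("a", "a", "b", "b", NA))
  fit <- fit_moderator_model(eff, "mod")
  expect_equal(fit$k, 4)
  expect_equal(fit$n_missing_moderator, 1)
})

test_that("omnibus Wald test honors its identities", {
  null_fit <- fit_moderator_model(
    make_effects(rep(0, 6), rep(0.04, 6), g = rep(c("a", "b"), 3)), "g")
  expect_equal(null_fit$omnibus$QM, 0)
  expect_equal(null_fit$omnibus$p_value, 1)

  single <- fit_random_effects(make_effects(qnorm(0.975) * 0.2, 0.04))
  expect_equal(single$omnibus$QM, qnorm(0.975)^2, tolerance = 1e-8)
  expect_equal(single$omnibus$p_value, 0.05, tolerance = 1e-8)

  tab <- omnibus_test(null_fit)
  expect_equal(tab$df, length(null_fit$tested))
})

test_that("back-transformed CI bounds are order-preserving exponentials of the lnRR bounds", {
  withr::with_seed(5, {
    eff <- make_effects(rnorm(8, 0.3, 0.3), runif(8, 0.01, 0.05))
  })
  fit <- fit_random_effects(eff)
  co <- tidy(fit)
  expect_equal(co$percent_lb, percent_change(co$ci_lb))
  expect_equal(co$percent_ub, percent_change(co$ci_ub))
  expect_true(all(co$percent_lb < co$percent) && all(co$percent < co$percent_ub))
})

test_that("REML agrees with metafor's rma.mv on a nested instance", {
  skip_if_not_installed("metafor")
  withr::with_seed(99, {
    study <- as.character(rep(1:6, times = c(3, 2, 1, 2, 3, 1)))
    y <- rnorm(12, 0.25, 0.3)
    v <- runif(12, 0.01, 0.06)
  })
  fit <- fit_random_effects(make_effects(y, v, study))
  mf <- metafor::rma.mv(y, v, random = ~ 1 | id,
                        data = data.frame(y = y, v = v, id = study),
                        method = "REML")
  expect_equal(fit$tau2, mf$sigma2, tolerance = 1e-5)
  expect_equal(fit$beta[["overall"]], as.numeric(mf$beta), tolerance = 1e-6)
  expect_equal(fit$coefficients$se, mf$se, tolerance = 1e-6)
})

test_that("funnel table pairs lnrr with sqrt(variance), sorted by precision", {
  eff <- make_effects(c(0.3, 0.1, 0.2), c(0.09, 0.01, 0.04))
  tab <- funnel_data(eff)
  expect_equal(tab$se, c(0.1, 0.2, 0.3))
  expect_equal(tab$lnrr, c(0.1, 0.2, 0.3))
  expect_equal(nrow(funnel_data(make_effects(0.5, 0.04))), 1)
  expect_error(egger_regression(make_effects(0.5, 0.04)), "at least 3")
})

test_that("Egger intercept CI covers 0 for symmetric simulated effects", {
  withr::with_seed(2024, {
    v <- runif(80, 0.005, 0.08)
    y <- rnorm(80, 0.2, sqrt(v))
  })
  eg <- egger_regression(make_effects(y, v))
  expect_true(eg$ci_lb < 0 && 0 < eg$ci_ub)
})

test_that("sensitivity reanalysis compares all-data and complete-SD fits", {
  comp <- make_fixture_compilation()
  comp$treatment <- "thin"
  comp$intercrop_genus <- NA_character_
  sens <- sensitivity_reanalysis(comp)
  expect_equal(sens$n_all, 5)
  expect_equal(sens$n_complete, 4)
  expect_equal(sens$n_excluded, 1)
  expect_s3_class(sens$fit_all, "meta_fit")
  expect_true(is.logical(sens$difference$robust))

  complete <- comp[c(1, 2, 4, 5), ]
  sens2 <- sensitivity_reanalysis(complete)
  expect_equal(sens2$n_excluded, 0)
  expect_equal(tidy(sens2$fit_all), tidy(sens2$fit_complete))
  expect_true(all(sens2$difference$difference == 0))
  expect_true(all(sens2$difference$robust))
})
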