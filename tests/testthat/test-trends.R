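test_that("covariate trimming removes rows above the ceiling and counts them", {
  dat <- tibble::tibble(stand_age = c(5, 15, 21, 28), x = 1:4)
  out <- trim_by_covariate(dat, "stand_age", 20)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_dropped"), 2)
  expect_equal(out$stand_age, c(5, 15))

  all_kept <- trim_by_covariate(dat, "stand_age", Inf)
  expect_equal(nrow(all_kept), 4)
  expect_equal(attr(all_kept, "n_dropped"), 0)

  empty <- trim_by_covariate(dat[0, ], "stand_age", 20)
  expect_equal(nrow(empty), 0)

  kept_na <- trim_by_covariate(tibble::tibble(stand_age = c(NA, 30)), "stand_age", 20)
  expect_equal(nrow(kept_na), 1)
})

test_that("a noiseless linear trend is recovered exactly", {
  eff <- make_effects(-0.2 + 0.05 * c(1, 3, 5, 8, 12), rep(0.02, 5),
                      age = c(1, 3, 5, 8, 12))
  fit <- fit_time_meta_regression(eff, "age")
  expect_equal(fit$intercept, -0.2, tolerance = 1e-6)
  expect_equal(fit$slope, 0.05, tolerance = 1e-6)
  expect_equal(fit$percent_per_unit, 5, tolerance = 1e-4)
  expect_equal(fit$n_used, 5)
  expect_equal(zero_crossing(fit), 4, tolerance = 1e-6)
})

test_that("trend slope matches the brute-force GLS oracle on the 6-point instance", {
  # frozen instance, verified against metafor::rma.mv beforehand
  eff <- make_effects(c(-0.20, -0.05, 0.10, 0.18, 0.40, 0.55),
                      c(0.030, 0.010, 0.020, 0.015, 0.040, 0.025),
                      study_id = c("1", "1", "2", "2", "3", "3"),
                      years = c(2, 4, 6, 9, 13, 18))
  fit <- fit_time_meta_regression(eff, "years")
  expect_equal(fit$intercept, -0.2263965, tolerance = 1e-6)
  expect_equal(fit$slope, 0.0450511, tolerance = 1e-6)

  orc <- oracle_reml_fit(eff$lnrr, eff$variance, eff$study_id,
                         cbind(1, eff$years))
  expect_equal(fit$tau2, orc$tau2, tolerance = 1.1e-4)
  expect_equal(unname(fit$beta), unname(orc$beta), tolerance = 1e-6)
})

test_that("a simulated age trend is recovered within its own confidence interval", {
  cfg <- default_config("interplant", seed = 314, n_publications = 50,
                        comparisons_rate = 2)
  sim <- generate_compilation(cfg)
  eff <- add_effect_sizes(impute_missing_sd(sim$records))
  fit <- fit_time_meta_regression(eff, "stand_age")
  ci <- tidy(fit)[tidy(fit)$term == "slope", ]
  expect_true(ci$ci_lb <= 0.036 && 0.036 <= ci$ci_ub)
  expect_true(fit$p_slope < 0.05)
})

test_that("zero crossings are positive-root only and scale invariant", {
  expect_equal(zero_crossing(list(intercept = -0.2, slope = 0.05)), 4)
  expect_true(is.na(zero_crossing(list(intercept = -0.2, slope = 0))))
  expect_true(is.na(zero_crossing(list(intercept = 0.2, slope = 0.05))))
  withr::with_seed(8, {
    for (i in 1:20) {
      int <- runif(1, -1, 1)
      sl <- runif(1, -0.2, 0.2)
      k <- runif(1, 0.1, 10)
      expect_equal(zero_crossing(list(intercept = int, slope = sl)),
                   zero_crossing(list(intercept = k * int, slope = k * sl)))
    }
  })
})

test_that("trimming then fitting equals fitting the pre-trimmed set", {
  withr::with_seed(11, {
    eff <- make_effects(rnorm(12, 0.1, 0.2), runif(12, 0.01, 0.05),
                        study_id = as.character(rep(1:6, 2)),
                        age = runif(12, 1, 30))
  })
  a <- fit_time_meta_regression(trim_by_covariate(eff, "age", 20), "age")
  b <- fit_time_meta_regression(eff[eff$age <= 20, ], "age")
  expect_equal(tidy(a), tidy(b))
  expect_equal(a$tau2, b$tau2)
})

test_that("the NPK time variable follows the application method", {
  dat <- tibble::tibble(application_method = c("continuous", "pulse"),
                        stand_age = c(10, 12), time_since_treatment = c(3, 2))
  out <- npk_time_variable(dat)
  expect_equal(out$time_var, c(10, 2))
})

test_that("trend_line predictions back-transform consistently", {
  eff <- make_effects(-0.2 + 0.05 * c(1, 3, 5, 8, 12), rep(0.02, 5),
                      age = c(1, 3, 5, 8, 12))
  fit <- fit_time_meta_regression(eff, "age")
  line <- trend_line(fit, grid = c(0, 4, 10))
  expect_equal(line$fit, -0.2 + 0.05 * c(0, 4, 10), tolerance = 1e-6)
  expect_equal(line$percent, percent_change(line$fit))
  expect_true(all(line$ci_lb < line$ci_ub))
  expect_equal(line$fit[2], 0, tolerance = 1e-6)  # the zero crossing at 4 yr
})
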