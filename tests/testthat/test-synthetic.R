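test_that("the generator is a pure function of its configuration", {
  cfg <- default_config("interplant", seed = 101)
  a <- generate_compilation(cfg)
  b <- generate_compilation(cfg)
  expect_equal(a$records, b$records)
  expect_equal(a$truth$comparisons, b$truth$comparisons)
  # a different seed gives different data
  c <- generate_compilation(default_config("interplant", seed = 102))
  expect_false(identical(a$records$mean_ctrl, c$records$mean_ctrl))
})

test_that("a seed is mandatory and configs are validated", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(treatment = "coppice", seed = 1), "Unknown")
  expect_error(synthetic_config(tau2_true = -1, seed = 1))
  expect_error(synthetic_config(slope_spec = c(elevation = 0.1), seed = 1),
               "covariate range")
  expect_error(synthetic_config(
    moderator_spec = list(g = list(levels = c("a", "b"), offsets = 1)),
    seed = 1), "offsets")
})

test_that("missing_sd_fraction = 0 leaves no blanks; blanks appear otherwise", {
  none <- generate_compilation(
    default_config("interplant", seed = 5, missing_sd_fraction = 0))
  expect_false(any(is.na(none$records$sd_treat)))
  expect_false(any(is.na(none$records$sd_ctrl)))

  some <- generate_compilation(default_config("interplant", seed = 5))
  expect_true(any(is.na(some$records$sd_treat)))
  # blanks are paired: a comparison loses both arm SDs or neither
  expect_equal(is.na(some$records$sd_treat), is.na(some$records$sd_ctrl))
})

test_that("the degenerate generator reproduces mu exactly", {
  cfg <- default_config("interplant", seed = 9, tau2_true = 0,
                        cv_range = c(0, 0), slope_spec = NULL,
                        missing_sd_fraction = 0)
  sim <- generate_compilation(cfg)
  lnrr <- with(sim$records, log(mean_treat / mean_ctrl))
  expect_equal(lnrr, rep(cfg$mu_true, nrow(sim$records)), tolerance = 1e-12)
  expect_equal(sim$truth$comparisons$true_lnrr,
               rep(cfg$mu_true, nrow(sim$records)))
})

test_that("generator output passes compilation validation and matches the schema", {
  for (trt in c("interplant", "npk", "thin")) {
    sim <- generate_compilation(default_config(trt, seed = 33))
    expect_silent(validate_compilation(sim$records))
    expect_equal(nrow(validation_report(sim$records)), 0)
    expect_true(all(sim$records$treatment == trt))
  }
  # the records round-trip through the interchange CSV
  sim <- generate_compilation(default_config("npk", seed = 34))
  path <- withr::local_tempfile(fileext = ".csv")
  write_compilation(sim$records, path)
  back <- read_compilation(path, convert_units = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(sim$records))
})

test_that("ground truth is internally consistent with the records", {
  cfg <- default_config("thin", seed = 55, missing_sd_fraction = 0,
                        n_publications = 60)
  sim <- generate_compilation(cfg)
  eff <- add_effect_sizes(sim$records)
  # observed lnRR scatters around the latent truth with roughly the
  # delta-method spread and no systematic shift
  resid <- eff$lnrr - sim$truth$comparisons$true_lnrr
  expect_lt(abs(mean(resid)), 4 * sd(resid) / sqrt(length(resid)))
  z <- resid / sqrt(eff$variance)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.25)
  # publication random effects are shared within publications
  by_pub <- tapply(sim$truth$comparisons$u_j, sim$truth$comparisons$study_id,
                   function(x) length(unique(x)))
  expect_true(all(by_pub == 1))
})

test_that("shared controls appear at the configured rate and duplicate arms", {
  sim <- generate_compilation(
    default_config("interplant", seed = 21, shared_control_prob = 1))
  groups <- group_shared_controls(sim$records)
  # with probability 1, each publication has exactly one control plot
  expect_equal(nrow(groups), length(unique(sim$records$study_id)))
  per_ctrl <- split(sim$records$mean_ctrl, sim$records$control_id)
  expect_true(all(vapply(per_ctrl, function(x) length(unique(x)) == 1,
                         logical(1))))

  solo <- generate_compilation(
    default_config("interplant", seed = 21, shared_control_prob = 0))
  expect_equal(nrow(group_shared_controls(solo$records)), nrow(solo$records))
})

test_that("between-publication variance of latent effects converges to tau2", {
  cfg <- default_config("interplant", seed = 71, n_publications = 10000,
                        comparisons_rate = 0, missing_sd_fraction = 0)
  sim <- generate_compilation(cfg)
  u <- sim$truth$publications$u_j
  expect_equal(var(u), cfg$tau2_true, tolerance = 0.05)
})

test_that("recovery_experiment summarizes bias and coverage with MC errors", {
  cfg <- default_config("interplant", seed = 7, n_publications = 20,
                        comparisons_rate = 1)
  out <- recovery_experiment(cfg, n_replicates = 20)
  expect_equal(out$n_replicates, 20)
  expect_true(abs(out$mu_bias) < 0.1)
  expect_true(out$coverage >= 0 && out$coverage <= 1)
  reps <- attr(out, "replicates")
  expect_equal(nrow(reps), 20)
  # reproducible: same config, same summary
  out2 <- recovery_experiment(cfg, n_replicates = 20)
  expect_equal(out$mu_bias, out2$mu_bias)
})
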