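test_that("grand-mean centering and product construction", {
  d <- data.frame(age = c(10, 12, 14), k = 1)
  out <- center_predictors(d, c("age", "k"),
                           products = list(age_c2 = c("age_c", "age_c")))
  expect_equal(out$age_c, c(-2, 0, 2))
  expect_equal(out$k_c, c(0, 0, 0)) # constant predictor centers to zero
  expect_equal(out$age_c2, c(4, 0, 4))
  expect_error(center_predictors(d[0, ], "age"), "empty")
  # quadratic built from centered age is uncorrelated with the linear term
  g <- center_predictors(make_cohort_grid(seed = 1), "age",
                         products = list(age_c2 = c("age_c", "age_c")))
  expect_lt(abs(cor(g$age_c, g$age_c2)), 0.05)
})

test_that("outcome simulation obeys the deterministic limit", {
  d <- data.frame(subject_id = 1:2, age_c = c(2, -2))
  out <- simulate_outcome(d, c(age_c = 0.3),
                          list(intercept_sd = 0, slope_sd = 0,
                               residual_sd = 0))
  expect_equal(out$y, c(0.6, -0.6))
  expect_error(simulate_outcome(d, c(nope = 1), list()), "unknown")
})

test_that("zero-noise data identify every generating effect exactly", {
  g <- make_accelerated_grid(n_subjects = 60, seed = 2)
  g <- center_predictors(g, c("age", "exposure_count"),
                         products = list(age_c2 = c("age_c", "age_c")))
  gen <- c(intercept = 0.2, age_c = 0.3, age_c2 = -0.1,
           exposure_count_c = -0.3)
  d <- simulate_outcome(g, gen, list(intercept_sd = 0, residual_sd = 0))
  ols <- lm(y ~ age_c + age_c2 + exposure_count_c, data = d)
  expect_equal(unname(coef(ols)), unname(gen), tolerance = 1e-6)
  # practice-only at zero noise: exposure regression recovers 0.3 exactly
  d2 <- simulate_outcome(g, c(exposure_count_c = 0.3),
                         list(intercept_sd = 0, residual_sd = 0))
  expect_equal(unname(coef(lm(y ~ exposure_count_c, d2))[2]), 0.3,
               tolerance = 1e-9)
})

test_that("outcome variance decomposes into intercept and residual parts", {
  g <- make_cohort_grid(n_subjects = 2000, seed = 3)
  g$age_c <- g$age - mean(g$age)
  d <- simulate_outcome(g, c(age_c = 0),
                        list(intercept_sd = 0.5, residual_sd = 1), seed = 4)
  expect_lt(abs(var(d$y) - (0.25 + 1)), 0.05)
})

test_that("stress covariate calibration and error contamination", {
  g <- center_predictors(make_school_grid(seed = 5), "age")
  d <- simulate_stress_tvc(g, seed = 6)
  expect_true(all(c("stress_true", "stress_observed") %in% names(d)))
  # no measurement error: observed equals true
  d0 <- simulate_stress_tvc(g, error_sd = 0, seed = 7)
  expect_equal(d0$stress_observed, d0$stress_true)
  # pooled age-stress correlation near the calibrated .41
  rho <- vapply(1:30, function(r) {
    gg <- center_predictors(make_school_grid(seed = child_seed(8, r)), "age")
    dd <- simulate_stress_tvc(gg, seed = child_seed(9, r))
    cor(dd$age, dd$stress_observed)
  }, numeric(1))
  expect_lt(abs(mean(rho) - 0.41), 0.04)
})

test_that("MCAR deletion is random and at the nominal rate", {
  g <- make_cohort_grid(seed = 10)
  expect_identical(inject_mcar(g, 0), g)
  expect_error(inject_mcar(g, 1), "rate")
  kept <- vapply(1:50, function(r) nrow(inject_mcar(g, 0.10,
                                                    seed = child_seed(11, r))),
                 numeric(1))
  expect_lt(abs(mean(750 - kept) - 75), 3 * sqrt(750 * .1 * .9 / 50))
  # deletion independent of the outcome
  d <- simulate_outcome(center_predictors(g, "age"), c(age_c = 0.3),
                        list(), seed = 12)
  d$q <- cut(d$y, quantile(d$y, 0:4 / 4), include.lowest = TRUE)
  del <- inject_mcar(cbind(d, row = seq_len(nrow(d))), 0.10, seed = 13)
  d$deleted <- !(seq_len(nrow(d)) %in% del$row)
  expect_gt(suppressWarnings(chisq.test(table(d$q, d$deleted)))$p.value,
            0.001)
})

test_that("scenario replicants are deterministic and carry their truth", {
  cfg <- scenario_config("puberty", variability = "low", sampling = "slow")
  a <- build_scenario(cfg, 3)
  b <- build_scenario(cfg, 3)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data$y, build_scenario(cfg, 4)$data$y))
  expect_equal(unname(a$truth$fixed), c(0, 2, -0.5))
  cfg2 <- scenario_config("intervention")
  tr <- build_scenario(cfg2, 1)$truth
  expect_equal(unname(tr$fixed), c(0.3, 0.3, -0.1))
  expect_equal(tr$random$intercept_sd, 1)
  expect_equal(tr$random$slope_sd, 0.15)
  expect_equal(tr$random$residual_sd, 0.5)
})

test_that("scenario configs round-trip through YAML", {
  cfg <- scenario_config("habituation", design = "accelerated",
                         n_replicants = 57, master_seed = 99)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  back <- load_scenario_config(path)
  expect_equal(back$fixed, cfg$fixed)
  expect_equal(back$random, cfg$random)
  expect_equal(back$n_replicants, 57)
  expect_equal(back$master_seed, 99)
  # every shipped config loads cleanly
  shipped <- list_scenario_configs()
  expect_gt(length(shipped), 20)
  cfgs <- lapply(shipped, load_scenario_config)
  expect_true(all(vapply(cfgs, inherits, logical(1), "scenario_config")))
})
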