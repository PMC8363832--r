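test_that("growth correlation: identity, affine collinearity, errors", {
  d <- data.frame(a = rnorm(50))
  d$b <- 2 * d$a + 1
  expect_equal(growth_correlation(d, "a", "a"), 1)
  expect_equal(growth_correlation(d, "a", "b"), 1)
  g <- make_cohort_grid(n_subjects = 20, jitter_sd = 0, seed = 1)
  expect_equal(growth_correlation(g, "age", "exposure_count"), 1)
  expect_error(growth_correlation(data.frame(a = rep(1, 5), b = 1:5),
                                  "a", "b"), "zero-variance")
})

test_that("VIF matches hand-computable cases and the correlation identity", {
  set.seed(2)
  n <- 4000
  a <- rnorm(n); b <- rnorm(n) # near-orthogonal
  expect_lt(variance_inflation(data.frame(a, b), "a", "b"), 1.01)
  # exact r = 0.5 pair -> VIF = 4/3
  u <- rnorm(n); v <- rnorm(n)
  u <- residuals(lm(u ~ v)) # orthogonalize exactly
  x <- scale(v)[, 1]; ypred <- 0.5 * x + sqrt(0.75) * scale(u)[, 1]
  expect_equal(variance_inflation(data.frame(x, ypred), "x", "ypred"),
               1 / (1 - 0.25), tolerance = 1e-12)
  # VIF(a|b) = VIF(b|a) = 1/(1 - rho^2) to near machine precision
  d <- data.frame(a = rnorm(200))
  d$b <- 0.7 * d$a + rnorm(200)
  rho <- growth_correlation(d, "a", "b")
  expect_equal(variance_inflation(d, "a", "b"), 1 / (1 - rho^2),
               tolerance = 1e-10)
  expect_equal(variance_inflation(d, "b", "a"), 1 / (1 - rho^2),
               tolerance = 1e-10)
  expect_error(variance_inflation(d, "a", character(0)), "other")
  d$c <- d$a
  expect_error(variance_inflation(d, "a", "c"), "collinear")
})

test_that("SE inflation is the square root of the VIF", {
  expect_equal(se_inflation(1), 1)
  expect_equal(se_inflation(1.17), sqrt(1.17))
  expect_equal(se_inflation(202), sqrt(202), tolerance = 1e-12)
  expect_gt(se_inflation(202), 14) # the ~14-fold inflation regime
  expect_error(se_inflation(0.9), ">= 1")
})

test_that("standardized bias: arithmetic, invariance, errors", {
  expect_equal(standardized_bias(c(0.4, 0.5, 0.6), 0.4), 1)
  expect_equal(standardized_bias(c(0.4, 0.5, 0.6), 0.5), 0)
  est <- rnorm(30, 0.3, 0.05)
  b0 <- standardized_bias(est, 0.28)
  expect_equal(standardized_bias(5 * est + 2, 5 * 0.28 + 2), b0) # affine
  expect_error(standardized_bias(0.3, 0.3), "two")
  expect_error(standardized_bias(rep(0.3, 5), 0.3), "identical")
})

test_that("significance proportions respect the sign filter", {
  expect_equal(proportion_significant(rnorm(10), rep(1, 10), 0.3), 0)
  est <- c(rep(1, 5), rep(-1, 5))
  expect_equal(proportion_significant(est, rep(0.001, 10), 0.3), 0.5)
  # null truth: plain rejection rate regardless of sign
  expect_equal(proportion_significant(est, rep(0.001, 10), 0), 1)
  expect_error(proportion_significant(numeric(0), numeric(0), 0), "empty")
})

test_that("replication summaries aggregate and validate ensembles", {
  cfg <- scenario_config("practice_only", design = "accelerated")
  fits <- lapply(1:6, function(r) {
    adjust_pvalues(fit_mlm(build_scenario(cfg, r)$data,
                           c("age_c", "exposure_count_c")))
  })
  truth <- c(age_c = 0, exposure_count_c = 0.3, sigma = 1, tau00 = 0.5)
  s <- summarize_replications(fits, truth, rho = runif(6, .3, .4))
  expect_s3_class(s, "replication_summary")
  r <- s[s$term == "exposure_count_c", ]
  expect_true(r$min_est <= r$mean_est && r$mean_est <= r$max_est)
  expect_true(all(s$prop_sig_adj <= s$prop_sig_raw, na.rm = TRUE))
  # permutation invariance over replicants
  s2 <- summarize_replications(fits[c(4, 2, 6, 1, 3, 5)], truth,
                               rho = runif(6, .3, .4))
  expect_equal(as.data.frame(s)[c("term", "mean_est", "sd_est", "std_bias")],
               as.data.frame(s2)[c("term", "mean_est", "sd_est", "std_bias")])
  expect_error(summarize_replications(fits[1], truth), "two replicants")
  bad <- fits
  bad[[2]]$coefficients$term[2] <- "other"
  expect_error(summarize_replications(bad, truth), "mismatched")
})
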