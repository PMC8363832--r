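test_that("cohort grids have the documented geometry", {
  g <- make_cohort_grid(seed = 1)
  expect_equal(nrow(g), 750L)
  expect_equal(g$exposure_count, g$occasion)
  expect_true(all(tapply(g$age, g$subject_id, function(a) all(diff(a) > 0))))
  # jitter-free ages are exactly baseline + wave * spacing
  g0 <- make_cohort_grid(n_subjects = 4, jitter_sd = 0, seed = 2)
  expect_equal(g0$age, 10 + g0$occasion)
})

test_that("grid generation is reproducible and validates inputs", {
  expect_identical(make_cohort_grid(seed = 7), make_cohort_grid(seed = 7))
  expect_identical(make_accelerated_grid(seed = 7),
                   make_accelerated_grid(seed = 7))
  expect_error(make_cohort_grid(spacing = 0), "spacing")
  expect_error(make_cohort_grid(n_waves = 1), "waves")
  expect_error(make_cohort_grid(jitter_sd = 2, spacing = 0.1, seed = 1),
               "monotone")
})

test_that("accelerated grids stagger baselines and degenerate to cohort", {
  g <- make_accelerated_grid(seed = 3)
  expect_equal(nrow(g), 750L)
  base <- g$age[g$occasion == 0]
  expect_gt(diff(range(base)), 3) # several entry cohorts represented
  # single entry cohort behaves as a cohort design
  g1 <- make_accelerated_grid(n_subjects = 40, entry_ages = 10, seed = 4)
  expect_lt(diff(range(g1$age[g1$occasion == 0])), 1)
})

test_that("school grids spread baseline age over a one-year band", {
  g <- make_school_grid(seed = 5)
  expect_equal(nrow(g), 750L)
  expect_lt(diff(range(g$age[g$occasion == 0])), 1 + 0.8) # band + jitter
  expect_equal(nrow(make_school_grid(n_subjects = 187, n_waves = 4,
                                     seed = 6)), 748L)
})

test_that("intervention exposure counts follow the onset definition", {
  g <- make_school_grid(n_subjects = 200, seed = 8)
  g <- assign_intervention(g, seed = 9)
  tx <- matrix(g$tx_count, ncol = 5, byrow = TRUE)
  # tx is non-decreasing and advances by exactly 1 once positive
  expect_true(all(apply(tx, 1, function(x) all(diff(x) >= 0))))
  steps <- apply(tx, 1, function(x) all(diff(x[x > 0 | c(x[-1], 0) > 0]) %in%
                                          c(0, 1)))
  expect_true(all(steps))
  # onset at occasion 0 yields 1..5; onset at the last occasion 0,0,0,0,1
  expect_true(any(apply(tx, 1, identical, y = as.integer(1:5))))
  expect_true(any(apply(tx, 1, identical, y = c(0L, 0L, 0L, 0L, 1L))))
  # some subjects are never treated during the window
  expect_gt(sum(rowSums(tx) == 0), 0)
})

test_that("puberty grids honor the observation budget and mean age", {
  slow <- make_puberty_grid("slow", "cohort", seed = 10)
  expect_equal(nrow(slow), 188L * 4L)
  expect_lt(abs(mean(slow$age) - 12), 0.1)
  fast <- make_puberty_grid("fast", "cohort", seed = 11)
  expect_equal(nrow(fast), 188L * 4L)
  expect_lt(abs(mean(fast$age) - 12), 0.1)
  # biannual visits: half the within-subject span
  expect_lt(diff(range(fast$age)), diff(range(slow$age)))
  acc <- make_puberty_grid("slow", "accelerated", seed = 12)
  expect_equal(nrow(acc), 750L)
  expect_lt(abs(mean(acc$age) - 12), 0.15)
})

test_that("exposure count is shared across subjects at each occasion", {
  g <- make_accelerated_grid(n_subjects = 30, seed = 13)
  per_occ <- tapply(g$exposure_count, g$occasion, unique)
  expect_true(all(lengths(per_occ) == 1L))
})

test_that("cohort confounds age with exposure; accelerated decouples them", {
  r_coh <- vapply(1:25, function(r) {
    g <- make_cohort_grid(seed = child_seed(99, r))
    cor(g$age, g$exposure_count)
  }, numeric(1))
  expect_true(all(r_coh > 0.99))
  r_acc <- vapply(1:25, function(r) {
    g <- make_accelerated_grid(seed = child_seed(99, r))
    cor(g$age, g$exposure_count)
  }, numeric(1))
  expect_true(mean(r_acc) > 0.30 && mean(r_acc) < 0.45)
})
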