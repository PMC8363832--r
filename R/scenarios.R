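# Scenario library: generating models layered on top of the observation
# grids. Each scenario couples a design, a set of generating fixed effects
# on grand-mean-centered predictors, and a random-effects specification.

#' Grand-mean center predictors and build product terms
#'
#' Each requested predictor is centered over all rows (grand-mean policy);
#' product columns (interactions, polynomials) are then built from the
#' centered terms, which keeps higher-order terms essentially uncorrelated
#' with the linear terms on symmetric designs.
#'
#' @param data A data frame (typically an observation grid, possibly with
#'   extra predictor columns).
#' @param vars Character vector of column names to center; each gains a
#'   `<name>_c` companion column.
#' @param products Optional named list; each element is a character vector
#'   of two (centered) column names whose rowwise product is stored under
#'   the element's name, e.g. `list(age_c2 = c("age_c", "age_c"))`.
#' @return `data` with the centered and product columns appended.
#' @export
#' @examples
#' d <- data.frame(age = c(10, 12, 14))
#' center_predictors(d, "age", products = list(age_c2 = c("age_c", "age_c")))
center_predictors <- function(data, vars, products = NULL) {
  if (nrow(data) == 0L) stop("empty dataset")
  for (v in vars) {
    if (!v %in% names(data)) stop("no column named '", v, "'")
    data[[paste0(v, "_c")]] <- data[[v]] - mean(data[[v]])
  }
  for (nm in names(products)) {
    pr <- products[[nm]]
    if (!all(pr %in% names(data))) stop("product refers to missing columns")
    data[[nm]] <- data[[pr[1]]] * data[[pr[2]]]
  }
  data
}

#' Simulate an outcome from a multi-growth mixed-effects model
#'
#' Builds `y = gamma00 + sum_j gamma_j * x_j + u0_i + u1_i * age_c + r_ti`
#' with per-subject random intercepts `u0 ~ N(0, intercept_sd^2)`, optional
#' per-subject random age slopes `u1 ~ N(0, slope_sd^2)` (independent of
#' `u0`), and occasion-level residuals `r ~ N(0, residual_sd^2)`.
#'
#' @param data Data frame holding the predictor columns named in `fixed`.
#' @param fixed Named numeric vector of generating fixed effects; names must
#'   match columns of `data`, except the optional name `"intercept"` which
#'   supplies `gamma00` (defaults to 0 when absent).
#' @param random List with elements `intercept_sd`, `slope_sd` and
#'   `residual_sd` (all >= 0; missing entries default to 0.5, 0 and 1).
#' @param seed Optional integer seed.
#' @return `data` with a simulated `y` column appended.
#' @export
#' @examples
#' g <- make_cohort_grid(n_subjects = 5, seed = 1)
#' g <- center_predictors(g, c("age", "exposure_count"))
#' d <- simulate_outcome(g, c(age_c = 0.3), list(residual_sd = 0), seed = 2)
#' head(d$y)
simulate_outcome <- function(data, fixed, random = list(), seed = NULL) {
  set_seed_if(seed)
  intercept_sd <- random$intercept_sd %||% 0.5
  slope_sd <- random$slope_sd %||% 0
  residual_sd <- random$residual_sd %||% 1
  if (any(c(intercept_sd, slope_sd, residual_sd) < 0))
    stop("random-effect SDs must be non-negative")
  gamma00 <- if ("intercept" %in% names(fixed)) fixed[["intercept"]] else 0
  terms <- setdiff(names(fixed), "intercept")
  miss <- setdiff(terms, names(data))
  if (length(miss))
    stop("fixed effects name unknown predictors: ", paste(miss, collapse = ", "))
  eta <- rep(gamma00, nrow(data))
  for (tm in terms) eta <- eta + fixed[[tm]] * data[[tm]]
  ids <- unique(data$subject_id)
  u0 <- stats::rnorm(length(ids), 0, intercept_sd)
  names(u0) <- as.character(ids)
  eta <- eta + u0[as.character(data$subject_id)]
  if (slope_sd > 0) {
    if (!"age_c" %in% names(data))
      stop("random age slope requires an age_c column")
    u1 <- stats::rnorm(length(ids), 0, slope_sd)
    names(u1) <- as.character(ids)
    eta <- eta + u1[as.character(data$subject_id)] * data$age_c
  }
  data$y <- eta + stats::rnorm(nrow(data), 0, residual_sd)
  data
}

#' Simulate an age-trending stress covariate with measurement error
#'
#' The latent stress signal rises linearly with (centered) age and carries
#' both a stable person-level component and occasion-level fluctuation; the
#' observed measurement adds independent error on top. Outcome generation
#' should use `stress_true`, model fitting `stress_observed`: feeding the
#' error-contaminated measurement to the fitted model is what lets the
#' correlated age term absorb part of the stress effect.
#'
#' @param data Data frame with `subject_id` and `age` (an `age_c` column is
#'   used when present, otherwise built internally).
#' @param signal_slope Increase in latent stress per year of age
#'   (default 0.5).
#' @param person_sd SD of the stable person-level stress component
#'   (default 1.3).
#' @param occasion_sd SD of the occasion-level latent fluctuation
#'   (default 0.75).
#' @param error_sd SD of the measurement error added to the observation
#'   (default 0.5).
#' @param seed Optional integer seed.
#' @return `data` with `stress_true` and `stress_observed` columns. The
#'   defaults give a pooled age-by-observed-stress correlation of about .41
#'   on the 5-wave school-cohort grid.
#' @export
simulate_stress_tvc <- function(data, signal_slope = 0.5, person_sd = 1.3,
                                occasion_sd = 0.75, error_sd = 0.5,
                                seed = NULL) {
  if (error_sd < 0 || person_sd < 0 || occasion_sd < 0)
    stop("SD parameters must be non-negative")
  set_seed_if(seed)
  age_c <- if ("age_c" %in% names(data)) data$age_c else
    data$age - mean(data$age)
  ids <- unique(data$subject_id)
  pe <- stats::rnorm(length(ids), 0, person_sd)
  names(pe) <- as.character(ids)
  data$stress_true <- signal_slope * age_c +
    pe[as.character(data$subject_id)] +
    stats::rnorm(nrow(data), 0, occasion_sd)
  data$stress_observed <- data$stress_true +
    stats::rnorm(nrow(data), 0, error_sd)
  data
}

#' Delete observations completely at random
#'
#' Each row is dropped independently with probability `rate`, independent of
#' all observed and unobserved quantities (MCAR).
#'
#' @param data A data frame.
#' @param rate Deletion probability in `[0, 1)` (default 0.10).
#' @param seed Optional integer seed.
#' @return `data` with roughly `rate * nrow(data)` rows removed.
#' @export
inject_mcar <- function(data, rate = 0.10, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  set_seed_if(seed)
  if (rate == 0) return(data)
  keep <- stats::runif(nrow(data)) >= rate
  data[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_names <- function() {
  c("practice_only", "age_only", "additive", "quadratic", "habituation",
    "snr_inverse", "intervention", "tvc_stress", "puberty")
}

#' Build a scenario configuration
#'
#' Bundles a named generating model with a design choice into a validated
#' configuration consumed by [build_scenario()] and [run_replications()].
#' All generating values default to the study conditions of the simulation
#' suite the package reproduces; override only for methodological
#' exploration.
#'
#' @param scenario_name One of `"practice_only"`, `"age_only"`,
#'   `"additive"`, `"quadratic"`, `"habituation"`, `"snr_inverse"`,
#'   `"intervention"`, `"tvc_stress"`, `"puberty"`.
#' @param design `"cohort"` or `"accelerated"` for the retest scenarios
#'   (ignored for `intervention`/`tvc_stress`, which use the school-cohort
#'   grid, and for `puberty`, which uses `frame`).
#' @param n_waves Waves for the school-cohort intervention design (5 or 4).
#' @param sampling,variability,frame Puberty options: `"fast"`/`"slow"`
#'   visit rate, `"high"`/`"low"` pubertal-timing variability (midpoint SD
#'   1.5 vs 0.5), and the `"cohort"`/`"accelerated"` age frame.
#' @param fixed,random Optional overrides of the generating fixed effects
#'   (named numeric) and random-effect SDs (list).
#' @param mcar_rate Fraction of rows deleted completely at random
#'   (default 0).
#' @param n_replicants Default ensemble size for [run_replications()].
#' @param master_seed Default master seed.
#' @return An object of class `scenario_config`.
#' @export
#' @examples
#' cfg <- scenario_config("practice_only", design = "accelerated")
#' cfg$fixed
scenario_config <- function(scenario_name,
                            design = c("cohort", "accelerated"),
                            n_waves = 5,
                            sampling = c("fast", "slow"),
                            variability = c("high", "low"),
                            frame = c("cohort", "accelerated"),
                            fixed = NULL, random = NULL,
                            mcar_rate = 0, n_replicants = 200,
                            master_seed = 1) {
  scenario_name <- match.arg(scenario_name, scenario_names())
  design <- match.arg(design)
  sampling <- match.arg(sampling)
  variability <- match.arg(variability)
  frame <- match.arg(frame)
  if (mcar_rate < 0 || mcar_rate >= 1) stop("mcar_rate must lie in [0, 1)")

  defaults <- switch(scenario_name,
    practice_only = list(
      fixed = c(age_c = 0, exposure_count_c = 0.3),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    age_only = list(
      fixed = c(age_c = 0.3, exposure_count_c = 0),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    additive = list(
      fixed = c(age_c = 0.3, exposure_count_c = 0.3),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    quadratic = list(
      fixed = c(age_c = 0.3, age_c2 = -0.1, exposure_count_c = 0.3),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    habituation = list(
      fixed = c(age_c = 0.3, exposure_count_c = -0.3),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    snr_inverse = list(
      fixed = c(age_c = -0.3, exposure_count_c = 0.3),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 1)),
    intervention = list(
      fixed = c(age_c = 0.3, tx_count_c = 0.3, age_x_tx = -0.1),
      random = list(intercept_sd = 1, slope_sd = 0.15, residual_sd = 0.5)),
    tvc_stress = list(
      fixed = c(age_c = 0.3, stress_true_c = 0.3, age_x_stress_true = -0.1),
      random = list(intercept_sd = 1, slope_sd = 0.15, residual_sd = 0.5)),
    puberty = list(
      fixed = c(age_c = 0, puberty_c = 2, age_x_puberty = -0.5),
      random = list(intercept_sd = 0.5, slope_sd = 0, residual_sd = 0.5))
  )
  structure(list(
    scenario_name = scenario_name,
    design = design,
    n_waves = n_waves,
    sampling = sampling,
    variability = variability,
    frame = frame,
    fixed = fixed %||% defaults$fixed,
    random = utils::modifyList(defaults$random, random %||% list()),
    mcar_rate = mcar_rate,
    n_replicants = n_replicants,
    master_seed = master_seed
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$scenario_name, "\n")
  extra <- switch(x$scenario_name,
    intervention = paste0("school cohort, ", x$n_waves, " waves"),
    tvc_stress = "school cohort, 5 waves",
    puberty = paste0(x$variability, " variability, ", x$sampling,
                     " sampling, ", x$frame, " frame"),
    paste0(x$design, " design"))
  cat("  design:", extra, "\n")
  cat("  fixed: ", paste(names(x$fixed), round(x$fixed, 3), sep = "=",
                         collapse = ", "), "\n")
  cat("  random SDs: intercept", x$random$intercept_sd,
      "| age slope", x$random$slope_sd,
      "| residual", x$random$residual_sd, "\n")
  if (x$mcar_rate > 0) cat("  MCAR rate:", x$mcar_rate, "\n")
  invisible(x)
}

# Model specifications (fitted models) attached to each scenario. Each spec
# lists the fixed terms, whether a random age slope is estimated, and the
# generating truth each fitted coefficient is evaluated against. Bias for a
# mis-specified model's age term is always judged against the generating age
# effect (the aliasing of the omitted process is the bias, not a new truth);
# the ordinal Tanner predictor spans 4 stages over the unit puberty range,
# so its effects are judged against the per-stage scaled truths.
scenario_models <- function(config) {
  nm <- config$scenario_name
  fx <- config$fixed
  rnd <- config$random
  vc_truth <- c(sigma = rnd$residual_sd, tau00 = rnd$intercept_sd,
                if (rnd$slope_sd > 0) c(tau11 = rnd$slope_sd))
  if (nm %in% c("practice_only", "age_only", "additive", "habituation",
                "snr_inverse")) {
    list(
      mis = list(fixed_terms = "age_c", random_slope = FALSE,
                 truth = c(fx["age_c"], vc_truth)),
      proper = list(fixed_terms = c("age_c", "exposure_count_c"),
                    random_slope = FALSE,
                    truth = c(fx[c("age_c", "exposure_count_c")], vc_truth))
    )
  } else if (nm == "quadratic") {
    list(
      mis = list(fixed_terms = c("age_c", "age_c2"), random_slope = FALSE,
                 truth = c(fx[c("age_c", "age_c2")], vc_truth)),
      proper = list(fixed_terms = c("age_c", "age_c2", "exposure_count_c"),
                    random_slope = FALSE,
                    truth = c(fx[c("age_c", "age_c2", "exposure_count_c")],
                              vc_truth))
    )
  } else if (nm == "intervention") {
    list(
      proper = list(fixed_terms = c("age_c", "tx_count_c", "age_x_tx"),
                    random_slope = TRUE,
                    truth = c(fx[c("age_c", "tx_count_c", "age_x_tx")],
                              vc_truth))
    )
  } else if (nm == "tvc_stress") {
    truth <- c(fx[["age_c"]], fx[["stress_true_c"]], fx[["age_x_stress_true"]])
    names(truth) <- c("age_c", "stress_c", "age_x_stress")
    list(
      proper = list(fixed_terms = c("age_c", "stress_c", "age_x_stress"),
                    random_slope = TRUE, truth = c(truth, vc_truth))
    )
  } else { # puberty
    stages_per_unit <- 4 # Tanner stages spanned across the (0, 1) range
    tanner_truth <- c(fx[["age_c"]], fx[["puberty_c"]] / stages_per_unit,
                      fx[["age_x_puberty"]] / stages_per_unit)
    names(tanner_truth) <- c("age_c", "tanner_c", "age_x_tanner")
    list(
      # the age-only quadratic proxies the omitted age-by-puberty curvature,
      # so its quadratic term is judged against that generating interaction
      mis = list(fixed_terms = c("age_c", "age_c2"), random_slope = FALSE,
                 truth = c(c(age_c = fx[["age_c"]],
                             age_c2 = fx[["age_x_puberty"]]), vc_truth)),
      proper = list(fixed_terms = c("age_c", "puberty_c", "age_x_puberty"),
                    random_slope = FALSE,
                    truth = c(fx[c("age_c", "puberty_c", "age_x_puberty")],
                              vc_truth)),
      tanner = list(fixed_terms = c("age_c", "tanner_c", "age_x_tanner"),
                    random_slope = FALSE,
                    truth = c(tanner_truth, vc_truth),
                    rho_pair = c("age", "tanner"))
    )
  }
}

# Uncentered predictor pair for the growth-correlation / VIF diagnostics.
scenario_rho_pair <- function(config) {
  switch(config$scenario_name,
    intervention = c("age", "tx_count"),
    tvc_stress = c("age", "stress_observed"),
    puberty = c("age", "puberty"),
    c("age", "exposure_count"))
}

#' Simulate one replicant of a scenario
#'
#' Deterministic function of `(config, master_seed, replicant_index)`:
#' generates the design grid, the growth predictors (including pubertal
#' trajectories or the stress covariate where applicable), centers
#' predictors, builds product terms, simulates the outcome and applies MCAR
#' deletion if configured.
#'
#' @param config A [scenario_config()].
#' @param replicant_index 1-based replicant number.
#' @param master_seed Master seed; defaults to the one in `config`.
#' @return A list with elements `data` (the simulated long-format dataset),
#'   `truth` (generating fixed effects and random-effect SDs), `models`
#'   (fitted-model specifications for this scenario) and `rho_pair` (the
#'   uncentered predictor pair used for collinearity diagnostics).
#' @export
#' @examples
#' rep1 <- build_scenario(scenario_config("additive"), 1)
#' names(rep1$data)
build_scenario <- function(config, replicant_index,
                           master_seed = config$master_seed) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- child_seed(master_seed, replicant_index)
  set.seed(seed)
  nm <- config$scenario_name

  if (nm %in% c("practice_only", "age_only", "additive", "quadratic",
                "habituation", "snr_inverse")) {
    grid <- if (config$design == "cohort") make_cohort_grid()
            else make_accelerated_grid()
    data <- center_predictors(grid, c("age", "exposure_count"),
                              products = list(age_c2 = c("age_c", "age_c")))
  } else if (nm == "intervention") {
    grid <- make_school_grid(
      n_subjects = if (config$n_waves == 4) 187L else 150L,
      n_waves = config$n_waves)
    grid <- assign_intervention(grid)
    data <- center_predictors(grid, c("age", "tx_count"),
                              products = list(age_x_tx = c("age_c", "tx_count_c")))
  } else if (nm == "tvc_stress") {
    grid <- make_school_grid(n_subjects = 150L, n_waves = 5L)
    grid <- center_predictors(grid, "age")
    grid <- simulate_stress_tvc(grid)
    data <- center_predictors(
      grid, c("stress_true", "stress_observed"),
      products = list(age_x_stress_true = c("age_c", "stress_true_c"),
                      age_x_stress = c("age_c", "stress_observed_c")))
    data$stress_c <- data$stress_observed_c
  } else { # puberty
    grid <- make_puberty_grid(sampling = config$sampling,
                              frame = config$frame)
    pp <- draw_puberty_params(
      length(unique(grid$subject_id)),
      location_sd = if (config$variability == "high") 1.5 else 0.5)
    idx <- match(grid$subject_id, unique(grid$subject_id))
    grid$z <- pp$z[idx]
    grid$k <- pp$k[idx]
    grid$puberty <- puberty_value(grid$age - 12, grid$z, grid$k)
    grid$tanner <- tanner_stage(grid$puberty)
    # the Tanner interaction is built from the raw 1-5 stage score (its
    # scale is substantively meaningful); centering the main effect alone
    # leaves the tanner coefficient unchanged while the age term absorbs
    # -gamma_int * mean(stage), the coarsening artifact under study
    data <- center_predictors(
      grid, c("age", "puberty", "tanner"),
      products = list(age_c2 = c("age_c", "age_c"),
                      age_x_puberty = c("age_c", "puberty_c"),
                      age_x_tanner = c("age_c", "tanner")))
  }

  data <- simulate_outcome(data, config$fixed, config$random)
  if (config$mcar_rate > 0) data <- inject_mcar(data, config$mcar_rate)

  list(data = data,
       truth = list(fixed = config$fixed, random = config$random),
       models = scenario_models(config),
       rho_pair = scenario_rho_pair(config),
       seed = seed)
}
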