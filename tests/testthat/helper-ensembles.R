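# Shared Monte-Carlo ensembles for the acceptance checks, computed once per
# test run and cached. All ensembles use a fixed master seed chosen before
# any result was inspected.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

ACCEPT_SEED <- 20260927L
ACCEPT_REPS <- 200L

# ensemble of design grids -> per-grid statistic
grid_stat <- function(n, make, stat) {
  vapply(seq_len(n), function(r) {
    set.seed(child_seed(ACCEPT_SEED, r))
    stat(make())
  }, numeric(1))
}

accept_run <- function(key, scenario, models, reps = ACCEPT_REPS, ...) {
  cached(key, suppressWarnings(run_replications(
    scenario_config(scenario, ..., n_replicants = reps,
                    master_seed = ACCEPT_SEED),
    models = models)))
}

# Monte-Carlo standard error of a standardized-bias statistic estimated
# from n replicants (delta method for mean/sd of a normal ensemble).
bias_mcse <- function(bias, n) sqrt((1 + bias^2 / 2) / n)

summary_row <- function(run, model, term) {
  s <- run$summaries[[model]]
  s[s$term == term, , drop = FALSE]
}
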