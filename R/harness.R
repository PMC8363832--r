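# Replication harness: simulate -> fit -> summarize loops with seed
# management and table reproduction.

#' Run a replicated simulate-fit-summarize ensemble
#'
#' For each replicant: build the scenario dataset, fit every requested
#' model, Bonferroni-adjust the p-values within each model, and record the
#' pooled growth-predictor correlation and VIF. Replicants whose fit did not
#' converge or was singular are excluded from aggregation (counted in the
#' manifest; a warning is raised when more than 2% drop).
#'
#' @param config A [scenario_config()].
#' @param n_replicants Ensemble size (default from the config).
#' @param master_seed Master seed (default from the config); replicant `r`
#'   uses the deterministic child seed `child_seed(master_seed, r)`.
#' @param models Character vector of model labels to fit (subset of the
#'   scenario's models, e.g. `c("mis", "proper")`); default all.
#' @param progress Print a dot every 25 replicants (default `FALSE`).
#' @return An object of class `mlmgm_run`: a list with `summaries` (one
#'   [summarize_replications()] result per model) and `manifest`
#'   (scenario, seeds, replicant count, per-model convergence counts).
#' @export
#' @examples
#' \donttest{
#' run <- run_replications(scenario_config("practice_only",
#'                                         design = "accelerated"),
#'                         n_replicants = 20, master_seed = 7)
#' run$summaries$proper
#' }
run_replications <- function(config, n_replicants = config$n_replicants,
                             master_seed = config$master_seed,
                             models = NULL, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  if (n_replicants < 2L) stop("n_replicants must be at least 2")
  model_specs <- scenario_models(config)
  if (is.null(models)) models <- names(model_specs)
  if (!all(models %in% names(model_specs)))
    stop("unknown model label(s): ",
         paste(setdiff(models, names(model_specs)), collapse = ", "))
  model_specs <- model_specs[models]

  fits <- stats::setNames(
    lapply(models, function(m) vector("list", n_replicants)), models)
  rho <- stats::setNames(
    lapply(models, function(m) rep(NA_real_, n_replicants)), models)
  vif <- rep(NA_real_, n_replicants)
  seeds <- integer(n_replicants)

  for (r in seq_len(n_replicants)) {
    sc <- build_scenario(config, r, master_seed = master_seed)
    seeds[r] <- sc$seed
    base_pair <- sc$rho_pair
    vif[r] <- variance_inflation(sc$data, base_pair[1], base_pair[2])
    for (m in models) {
      spec <- model_specs[[m]]
      f <- fit_mlm(sc$data, spec$fixed_terms,
                   random_slope = isTRUE(spec$random_slope), label = m)
      f <- adjust_pvalues(f)
      fits[[m]][[r]] <- f
      pair <- spec$rho_pair %||% base_pair
      rho[[m]][r] <- growth_correlation(sc$data, pair[1], pair[2])
    }
    if (progress && r %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")

  summaries <- list()
  convergence <- list()
  for (m in models) {
    ok <- vapply(fits[[m]], function(f) f$converged && !f$singular,
                 logical(1))
    convergence[[m]] <- c(n = n_replicants, converged = sum(ok))
    if (mean(!ok) > 0.02)
      warning(sprintf("model '%s': %d/%d replicants dropped (%s)", m,
                      sum(!ok), n_replicants,
                      "non-convergence or singular fit"), call. = FALSE)
    summaries[[m]] <- summarize_replications(
      fits[[m]][ok], truth = model_specs[[m]]$truth,
      rho = rho[[m]][ok], vif = vif[ok])
  }

  structure(list(
    summaries = summaries,
    manifest = list(
      scenario = config$scenario_name,
      config = config,
      master_seed = master_seed,
      n_replicants = n_replicants,
      child_seeds = seeds,
      convergence = convergence,
      package_version = as.character(utils::packageVersion("mlmgm")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "mlmgm_run")
}

#' @export
print.mlmgm_run <- function(x, ...) {
  cat("<mlmgm_run>", x$manifest$scenario, "|",
      x$manifest$n_replicants, "replicants | master seed",
      x$manifest$master_seed, "\n\n")
  for (m in names(x$summaries)) {
    cat("--", m, "model --\n")
    print(x$summaries[[m]], ...)
    cat("\n")
  }
  invisible(x)
}

# (table_id, cell) -> scenario configs; tables 1-3 pair two scenarios
# across the cohort/accelerated designs, table 4 is the school-cohort
# intervention/TVC set, tables 5-8 the puberty variability-by-sampling grid.
table_cells <- function(table_id, n_replicants, master_seed) {
  cfg <- function(...) scenario_config(..., n_replicants = n_replicants,
                                       master_seed = master_seed)
  both <- function(name) list(
    cohort = cfg(name, design = "cohort"),
    accelerated = cfg(name, design = "accelerated"))
  pub <- function(vb) list(
    cohort = cfg("puberty", variability = vb[1], sampling = vb[2],
                 frame = "cohort"),
    accelerated = cfg("puberty", variability = vb[1], sampling = vb[2],
                      frame = "accelerated"))
  switch(as.character(table_id),
    "1" = c(stats::setNames(both("practice_only"),
                            c("practice_only.cohort",
                              "practice_only.accelerated")),
            stats::setNames(both("age_only"),
                            c("age_only.cohort", "age_only.accelerated"))),
    "2" = c(stats::setNames(both("additive"),
                            c("additive.cohort", "additive.accelerated")),
            stats::setNames(both("quadratic"),
                            c("quadratic.cohort", "quadratic.accelerated"))),
    "3" = c(stats::setNames(both("habituation"),
                            c("habituation.cohort",
                              "habituation.accelerated")),
            stats::setNames(both("snr_inverse"),
                            c("snr_inverse.cohort",
                              "snr_inverse.accelerated"))),
    "4" = list(intervention.wave5 = cfg("intervention", n_waves = 5),
               intervention.wave4 = cfg("intervention", n_waves = 4),
               tvc_stress = cfg("tvc_stress")),
    "5" = stats::setNames(pub(c("high", "fast")),
                          c("puberty_hv_fast.cohort",
                            "puberty_hv_fast.accelerated")),
    "6" = stats::setNames(pub(c("low", "fast")),
                          c("puberty_lv_fast.cohort",
                            "puberty_lv_fast.accelerated")),
    "7" = stats::setNames(pub(c("high", "slow")),
                          c("puberty_hv_slow.cohort",
                            "puberty_hv_slow.accelerated")),
    "8" = stats::setNames(pub(c("low", "slow")),
                          c("puberty_lv_slow.cohort",
                            "puberty_lv_slow.accelerated")),
    stop("unknown table_id: ", table_id)
  )
}

#' Reproduce one of the simulation-suite summary tables
#'
#' Runs every scenario-by-design cell belonging to the requested table and
#' optionally writes one summary CSV per (cell, model).
#'
#' @param table_id Integer 1--8.
#' @param n_replicants Replicants per cell (the original study used 1000;
#'   200 keeps the Monte-Carlo error near the full-size ensemble SDs at a
#'   fraction of the cost).
#' @param master_seed Master seed shared by all cells.
#' @param out_dir Optional directory for the summary CSVs.
#' @return Named list of `mlmgm_run` objects, one per cell, invisibly.
#' @export
reproduce_table <- function(table_id, n_replicants = 200, master_seed = 1,
                            out_dir = NULL) {
  cells <- table_cells(table_id, n_replicants, master_seed)
  runs <- list()
  for (cell in names(cells)) {
    runs[[cell]] <- run_replications(cells[[cell]])
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (m in names(runs[[cell]]$summaries)) {
        s <- runs[[cell]]$summaries[[m]]
        df <- as.data.frame(s)
        df$rho_mean <- attr(s, "rho_mean")
        df$vif_mean <- attr(s, "vif_mean")
        utils::write.csv(df, file.path(out_dir,
          sprintf("table%s_%s_%s.csv", table_id, cell, m)),
          row.names = FALSE)
      }
    }
  }
  invisible(runs)
}
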