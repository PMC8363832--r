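# Ensemble evaluation statistics: growth-predictor correlation, variance
# inflation, standardized bias, and correct-sign significance proportions.

#' Pooled correlation between two growth predictors
#'
#' Pearson correlation over all observation rows of one replicant.
#'
#' @param data A dataset.
#' @param pred_a,pred_b Column names of the two predictors.
#' @return A correlation in `[-1, 1]`.
#' @export
growth_correlation <- function(data, pred_a, pred_b) {
  a <- data[[pred_a]]; b <- data[[pred_b]]
  if (is.null(a) || is.null(b)) stop("predictor column not found")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance predictor")
  stats::cor(a, b)
}

#' Variance inflation factor of one predictor given others
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` comes from the observation-level
#' least-squares regression (with intercept) of the target predictor on the
#' other predictors.
#'
#' @param data A dataset.
#' @param target Column name of the predictor whose VIF is wanted.
#' @param others Character vector of the remaining predictor columns.
#' @return A VIF `>= 1`.
#' @export
#' @examples
#' d <- data.frame(a = rnorm(100))
#' d$b <- d$a + rnorm(100)
#' variance_inflation(d, "a", "b")
variance_inflation <- function(data, target, others) {
  if (!length(others)) stop("need at least one other predictor")
  fml <- stats::as.formula(
    paste(target, "~", paste(others, collapse = " + ")))
  r2 <- suppressWarnings(summary(stats::lm(fml, data = data)))$r.squared
  if (r2 >= 1 - 1e-12)
    stop("perfect collinearity among predictors: degenerate design")
  1 / (1 - r2)
}

#' Standard-error inflation implied by a VIF
#'
#' Standard errors inflate by `sqrt(VIF)` relative to orthogonal
#' predictors.
#'
#' @param vif A variance inflation factor `>= 1`.
#' @return The SE inflation factor.
#' @export
se_inflation <- function(vif) {
  if (any(vif < 1)) stop("vif must be >= 1")
  sqrt(vif)
}

#' Standardized bias of an estimator across replicants
#'
#' `(mean(estimates) - truth) / sd(estimates)`: the distance between the
#' Monte-Carlo mean and the generating value in units of the empirical SD of
#' the sampling distribution. Absolute values above 0.25 are conventionally
#' flagged as poor recovery.
#'
#' @param estimates Numeric vector of per-replicant estimates (length >= 2).
#' @param truth The generating parameter value.
#' @return The standardized bias.
#' @export
#' @examples
#' standardized_bias(c(0.4, 0.5, 0.6), 0.4)  # 1
standardized_bias <- function(estimates, truth) {
  if (length(estimates) < 2L) stop("need at least two estimates")
  s <- stats::sd(estimates)
  if (s == 0) stop("all estimates identical: bias undefined on the SD scale")
  (mean(estimates) - truth) / s
}

#' Proportion of replicants with a correct-sign significant effect
#'
#' Counts fits with `p < alpha` whose estimate carries the sign of the
#' generating value; significant effects of the wrong sign are not counted
#' as successes. When the truth is 0 the proportion is the plain rejection
#' rate (a false-positive rate), regardless of sign.
#'
#' @param estimates Per-replicant estimates.
#' @param p_values Matching p-values (raw or Bonferroni-adjusted).
#' @param truth The generating value.
#' @param alpha Significance level (default 0.05).
#' @return A proportion in `[0, 1]`.
#' @export
proportion_significant <- function(estimates, p_values, truth,
                                   alpha = 0.05) {
  if (!length(estimates)) stop("empty estimate list")
  if (length(estimates) != length(p_values))
    stop("estimates and p_values differ in length")
  sig <- p_values < alpha
  if (truth != 0) sig <- sig & (sign(estimates) == sign(truth))
  mean(sig)
}

#' Aggregate an ensemble of fits into a replication summary
#'
#' Produces one row per model term with the Monte-Carlo mean, SD, range,
#' standardized bias and raw/adjusted correct-sign significance
#' proportions, plus rows for the variance components; per-replicant
#' growth-predictor correlations and VIFs are averaged alongside.
#' Non-converged or singular fits must be excluded by the caller (see
#' [run_replications()], which also counts them).
#'
#' @param fits List of converged `mlmgm_fit` objects with identical term
#'   sets.
#' @param truth Named numeric vector of generating values for (a subset of)
#'   the fitted terms and the variance components `sigma`, `tau00`,
#'   `tau11`; terms without a truth get `NA` bias.
#' @param rho,vif Optional numeric vectors of per-replicant pooled
#'   growth-predictor correlations and VIFs.
#' @return A `replication_summary`: a data frame with columns `term`,
#'   `mean_est`, `sd_est`, `min_est`, `max_est`, `std_bias`,
#'   `prop_sig_raw`, `prop_sig_adj`, with the ensemble diagnostics stored
#'   as attributes (`rho_mean`, `rho_sd`, `vif_mean`, `vif_sd`,
#'   `n_replicants`).
#' @export
summarize_replications <- function(fits, truth = numeric(), rho = NULL,
                                   vif = NULL) {
  if (length(fits) < 2L)
    stop("need at least two replicants to summarize a sampling distribution")
  terms <- fits[[1L]]$coefficients$term
  same <- vapply(fits, function(f) identical(f$coefficients$term, terms),
                 logical(1))
  if (!all(same)) stop("mismatched term sets across replicants")

  est <- t(vapply(fits, function(f) f$coefficients$estimate,
                  numeric(length(terms))))
  p_raw <- t(vapply(fits, function(f) f$coefficients$p_value,
                    numeric(length(terms))))
  p_adj <- t(vapply(fits, function(f) f$coefficients$p_adjusted,
                    numeric(length(terms))))
  colnames(est) <- colnames(p_raw) <- colnames(p_adj) <- terms

  vc <- cbind(sigma = vapply(fits, `[[`, numeric(1), "sigma"),
              tau00 = vapply(fits, `[[`, numeric(1), "tau00"),
              tau11 = vapply(fits, `[[`, numeric(1), "tau11"))
  if (all(is.na(vc[, "tau11"]))) vc <- vc[, c("sigma", "tau00"), drop = FALSE]

  one_row <- function(name, x, p1 = NULL, p2 = NULL) {
    tr <- if (name %in% names(truth)) truth[[name]] else NA_real_
    data.frame(
      term = name,
      mean_est = mean(x), sd_est = stats::sd(x),
      min_est = min(x), max_est = max(x),
      std_bias = if (is.na(tr)) NA_real_ else standardized_bias(x, tr),
      prop_sig_raw = if (is.null(p1) || is.na(tr)) NA_real_ else
        proportion_significant(x, p1, tr),
      prop_sig_adj = if (is.null(p2) || is.na(tr)) NA_real_ else
        proportion_significant(x, p2, tr),
      row.names = NULL
    )
  }
  rows <- lapply(terms, function(tm)
    one_row(tm, est[, tm], p_raw[, tm], p_adj[, tm]))
  rows <- c(rows, lapply(colnames(vc), function(v) one_row(v, vc[, v])))
  out <- do.call(rbind, rows)
  structure(out,
            rho_mean = if (is.null(rho)) NA_real_ else mean(rho),
            rho_sd = if (is.null(rho)) NA_real_ else stats::sd(rho),
            vif_mean = if (is.null(vif)) NA_real_ else mean(vif),
            vif_sd = if (is.null(vif)) NA_real_ else stats::sd(vif),
            n_replicants = length(fits),
            class = c("replication_summary", "data.frame"))
}

#' @export
print.replication_summary <- function(x, digits = 3, ...) {
  cat("Replication summary over", attr(x, "n_replicants"),
      "converged replicants\n")
  if (!is.na(attr(x, "rho_mean")))
    cat(sprintf("  rho_growth: mean %.3f (sd %.3f)\n",
                attr(x, "rho_mean"), attr(x, "rho_sd")))
  if (!is.na(attr(x, "vif_mean")))
    cat(sprintf("  VIF:        mean %.2f (sd %.3f)\n",
                attr(x, "vif_mean"), attr(x, "vif_sd")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
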