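# REML fitting of growth models and extraction of estimates, Satterthwaite
# p-values and variance components.

#' Fit a linear mixed-effects growth model
#'
#' Fits `y ~ fixed terms + (1 | subject_id)` (or `(1 + age_c | subject_id)`
#' when a random age slope is requested) by REML and extracts fixed-effect
#' estimates, standard errors and two-sided p-values with Satterthwaite
#' degrees of freedom, together with the variance components on the SD
#' scale. Non-convergence and singular fits are flagged, not raised; the
#' ensemble harness drops flagged replicants from aggregation.
#'
#' @param data A simulated dataset with columns `y`, `subject_id` and every
#'   predictor named in `fixed_terms`.
#' @param fixed_terms Character vector of fixed-effect predictor columns
#'   (the intercept is always included).
#' @param random_slope Logical; estimate a subject-level random slope on
#'   `age_c` in addition to the random intercept (default `FALSE`).
#' @param label Optional model label (e.g. `"mis_specified"`), stored on the
#'   result.
#' @return An object of class `mlmgm_fit`: a list with `coefficients` (a
#'   data frame with columns `term`, `estimate`, `se`, `df`, `p_value`,
#'   `p_adjusted`), `sigma`, `tau00`, `tau11` (NA unless a random slope is
#'   modeled), `converged`, `singular`, `n_obs`, `n_subjects` and `label`.
#' @export
#' @examples
#' cfg <- scenario_config("additive", design = "accelerated")
#' d <- build_scenario(cfg, 1)$data
#' fit <- fit_mlm(d, c("age_c", "exposure_count_c"))
#' fit
fit_mlm <- function(data, fixed_terms, random_slope = FALSE, label = NULL) {
  if (!length(fixed_terms)) stop("fixed_terms must be non-empty")
  miss <- setdiff(c("y", "subject_id", fixed_terms), names(data))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  re <- if (random_slope) "(1 + age_c | subject_id)" else "(1 | subject_id)"
  fml <- stats::as.formula(
    paste("y ~", paste(c(fixed_terms, re), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = data, REML = TRUE)))
  converged <- length(fit@optinfo$conv$lme4$messages) == 0L &&
    fit@optinfo$conv$opt == 0L
  singular <- lme4::isSingular(fit)
  ct <- stats::coef(summary(fit))
  coefs <- data.frame(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    df = ct[, "df"],
    p_value = ct[, "Pr(>|t|)"],
    p_adjusted = ct[, "Pr(>|t|)"],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- sqrt(vc$vcov[vc$grp == "subject_id" &
                          vc$var1 == "(Intercept)" & is.na(vc$var2)][1])
  tau11 <- if (random_slope)
    sqrt(vc$vcov[vc$grp == "subject_id" & vc$var1 == "age_c" &
                   is.na(vc$var2)][1]) else NA_real_
  structure(list(
    coefficients = coefs,
    sigma = stats::sigma(fit),
    tau00 = tau00,
    tau11 = tau11,
    converged = converged,
    singular = singular,
    n_obs = nrow(data),
    n_subjects = length(unique(data$subject_id)),
    label = label %||% paste(fixed_terms, collapse = "+"),
    formula = fml
  ), class = "mlmgm_fit")
}

#' @export
print.mlmgm_fit <- function(x, digits = 3, ...) {
  cat("<mlmgm_fit>", x$label,
      if (!x$converged) "[NOT CONVERGED]" else if (x$singular) "[singular]",
      "\n")
  cat("  ", deparse(x$formula), "\n")
  print(cbind(
    estimate = round(x$coefficients$estimate, digits),
    se = round(x$coefficients$se, digits),
    p = signif(x$coefficients$p_value, 2),
    p_adj = signif(x$coefficients$p_adjusted, 2)
  ), quote = FALSE)
  cat(sprintf("  sigma = %.3f  tau00 = %.3f", x$sigma, x$tau00))
  if (!is.na(x$tau11)) cat(sprintf("  tau11 = %.3f", x$tau11))
  cat("\n")
  invisible(x)
}

#' Bonferroni-adjust the p-values of a fitted model
#'
#' Multiplies each growth predictor's p-value by the number of predictors in
#' the model (capped at 1). The intercept is left unadjusted.
#'
#' @param fit An `mlmgm_fit`.
#' @param n_predictors Number of growth predictors to account for; defaults
#'   to the number of non-intercept fixed terms in the model.
#' @return The fit with the `p_adjusted` column updated.
#' @export
#' @examples
#' cfg <- scenario_config("additive", design = "accelerated")
#' d <- build_scenario(cfg, 1)$data
#' adjust_pvalues(fit_mlm(d, c("age_c", "exposure_count_c")))
adjust_pvalues <- function(fit, n_predictors = NULL) {
  stopifnot(inherits(fit, "mlmgm_fit"))
  is_pred <- fit$coefficients$term != "(Intercept)"
  m <- n_predictors %||% sum(is_pred)
  if (m < 1) stop("n_predictors must be at least 1")
  fit$coefficients$p_adjusted <-
    ifelse(is_pred, pmin(1, m * fit$coefficients$p_value),
           fit$coefficients$p_value)
  fit
}

#' Implied vertex of a quadratic growth trajectory
#'
#' For a fitted trajectory `b1 * age_c + b2 * age_c^2`, the implied
#' inflection point (vertex) sits at `-b1 / (2 * b2)` on the centered age
#' scale.
#'
#' @param fit An `mlmgm_fit` containing both terms, or a named numeric
#'   vector of coefficients.
#' @param linear,quadratic Names of the linear and quadratic terms
#'   (defaults `"age_c"`, `"age_c2"`).
#' @param center_age Optional centering age; when given, the vertex is also
#'   reported on the original age scale.
#' @return The vertex on the centered scale, or a named vector
#'   `c(vertex, age)` when `center_age` is supplied.
#' @export
#' @examples
#' implied_vertex(c(age_c = 0.3, age_c2 = -0.1))  # 1.5
implied_vertex <- function(fit, linear = "age_c", quadratic = "age_c2",
                           center_age = NULL) {
  coefs <- if (inherits(fit, "mlmgm_fit"))
    stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  else fit
  if (!all(c(linear, quadratic) %in% names(coefs)))
    stop("fit must contain both the linear and the quadratic term")
  b2 <- coefs[[quadratic]]
  if (b2 == 0) stop("quadratic coefficient is zero: vertex undefined")
  v <- -coefs[[linear]] / (2 * b2)
  if (is.null(center_age)) v else c(vertex = v, age = center_age + v)
}
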