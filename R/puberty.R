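# Pubertal trajectory model: per-subject sigmoid curves with correlated
# timing (midpoint z) and tempo (steepness k) parameters, plus the ordinal
# Tanner-stage coarsening.

#' Draw correlated pubertal timing and tempo parameters
#'
#' Each subject's pubertal trajectory is a logistic curve with midpoint `z`
#' (years relative to the sample mean age; the age offset at which the
#' continuous puberty value crosses 0.5) and steepness `k` (1/years).
#' Marginally, `z` follows a normal distribution with mean 0 and SD
#' `location_sd`, truncated at `bounds`; `k` follows a gamma distribution
#' (shape `shape_gamma_shape`, rate `shape_gamma_rate`, so mean shape/rate,
#' about 3.33 at the defaults, i.e. a typical 2%-to-98% transition of
#' roughly 2.3 years). The two are coupled through a Gaussian copula with
#' correlation `zk_correlation`, so that early-starting subjects (small `z`)
#' tend to have protracted transitions (small `k`) while late starters move
#' through puberty faster; the marginals are preserved exactly.
#'
#' @param n Number of subjects.
#' @param location_sd SD of the (untruncated) midpoint distribution in
#'   years; 1.5 represents high between-subject variability in pubertal
#'   timing, 0.5 low variability.
#' @param shape_gamma_shape,shape_gamma_rate Gamma shape and rate for the
#'   steepness parameter (defaults 10 and 3).
#' @param zk_correlation Gaussian-copula correlation between `z` and `k` in
#'   `[0, 1)` (default 0.5); 0 gives independent draws.
#' @param bounds Truncation bounds for `z` (default `c(-3, 3)`).
#' @param seed Optional integer seed.
#' @return A `data.frame` with columns `z` and `k`, one row per subject.
#' @export
#' @examples
#' pp <- draw_puberty_params(5, seed = 1)
#' pp
draw_puberty_params <- function(n, location_sd = 1.5,
                                shape_gamma_shape = 10,
                                shape_gamma_rate = 3,
                                zk_correlation = 0.5,
                                bounds = c(-3, 3), seed = NULL) {
  if (n < 1L) stop("n must be at least 1")
  if (location_sd <= 0) stop("location_sd must be positive")
  if (shape_gamma_shape <= 0 || shape_gamma_rate <= 0)
    stop("gamma parameters must be positive")
  if (zk_correlation < 0 || zk_correlation >= 1)
    stop("zk_correlation must lie in [0, 1)")
  set_seed_if(seed)
  g1 <- stats::rnorm(n)
  g2 <- zk_correlation * g1 + sqrt(1 - zk_correlation^2) * stats::rnorm(n)
  # inverse-CDF transform keeps the truncated-normal marginal exact
  lo <- stats::pnorm(bounds[1] / location_sd)
  hi <- stats::pnorm(bounds[2] / location_sd)
  z <- stats::qnorm(lo + (hi - lo) * stats::pnorm(g1)) * location_sd
  k <- stats::qgamma(stats::pnorm(g2), shape = shape_gamma_shape,
                     rate = shape_gamma_rate)
  data.frame(z = z, k = k)
}

#' Evaluate the continuous pubertal trajectory
#'
#' The logistic curve `p = 1 / (1 + exp(-k * (x - z)))`, mapping an age
#' offset `x` (years from the sample mean age) to a pubertal status in
#' (0, 1), where 0 is pre-puberty and 1 post-puberty. Strictly increasing
#' in `x`, with `p = 0.5` at `x = z`.
#'
#' @param x Age offset(s) in years from the sample mean age.
#' @param z Trajectory midpoint(s), years.
#' @param k Steepness parameter(s), 1/years.
#' @return Pubertal status values in (0, 1), recycled over the longest
#'   argument.
#' @export
#' @examples
#' puberty_value(0, z = 0, k = 3.33)  # midpoint
#' puberty_value(c(-4, 4), z = 0, k = 3.33)
puberty_value <- function(x, z, k) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (any(k <= 0)) stop("k must be positive")
  1 / (1 + exp(-k * (x - z)))
}

#' Coarsen continuous pubertal status to Tanner stages
#'
#' Ordinal 5-stage coding with cut-points .05, .35, .65 and .95:
#' `p < .05` is stage 1 (pre-puberty), `.05 <= p < .35` stage 2,
#' `.35 <= p < .65` stage 3, `.65 <= p < .95` stage 4 and `p >= .95`
#' stage 5 (post-puberty). The boundary `p = .95` is assigned upward,
#' consistent with the half-open-up convention of the other cut-points.
#'
#' @param p Continuous pubertal status values, strictly inside (0, 1).
#' @return Integer Tanner stages 1--5.
#' @export
#' @examples
#' tanner_stage(c(0.04, 0.5, 0.7, 0.95))
tanner_stage <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  findInterval(p, c(0.05, 0.35, 0.65, 0.95)) + 1L
}
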