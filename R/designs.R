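# Observation-design generators.
#
# An observation grid is a long-format data frame with one row per
# (subject, occasion):
#   subject_id     integer subject label
#   occasion       integer wave index starting at 0
#   age            years, strictly increasing within subject
#   exposure_count prior-plus-current assessments minus 1 (equals occasion)
#   tx_count       cumulative intervention exposures (0 until assigned)
#   design_label   one of cohort, accelerated, school_cohort,
#                  puberty_cohort, puberty_accelerated
#
# Nominal ages are baseline + occasion * spacing; a small independent normal
# jitter is added to every observed age (and re-drawn for any subject whose
# ages would not be strictly increasing, an essentially zero-probability
# event at the default jitter SD).

new_grid <- function(baseline, n_waves, spacing, jitter_sd, design_label) {
  n <- length(baseline)
  if (n < 1L) stop("need at least one subject")
  if (n_waves < 2L) stop("need at least two waves")
  if (spacing <= 0) stop("wave spacing must be positive")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  occ <- matrix(rep(0:(n_waves - 1L), each = n), n, n_waves)
  nominal <- baseline + occ * spacing
  age <- nominal + matrix(stats::rnorm(n * n_waves, 0, jitter_sd), n, n_waves)
  tries <- 0L
  repeat {
    bad <- which(apply(age, 1L, function(a) any(diff(a) <= 0)))
    if (!length(bad)) break
    tries <- tries + 1L
    if (tries > 100L)
      stop("jitter_sd too large relative to spacing: ages not monotone")
    age[bad, ] <- nominal[bad, , drop = FALSE] +
      matrix(stats::rnorm(length(bad) * n_waves, 0, jitter_sd),
             length(bad), n_waves)
  }
  data.frame(
    subject_id = rep(seq_len(n), each = n_waves),
    occasion = rep(0:(n_waves - 1L), n),
    age = as.vector(t(age)),
    exposure_count = rep(0:(n_waves - 1L), n),
    tx_count = 0L,
    design_label = design_label
  )
}

#' Generate a cohort longitudinal observation grid
#'
#' All subjects enter at the same baseline age and are measured at every
#' wave, so age and assessment count are almost perfectly confounded
#' (pooled correlation about .998 at the defaults).
#'
#' @param n_subjects Number of subjects (default 150).
#' @param n_waves Number of waves per subject (default 5).
#' @param baseline_age Shared baseline age in years (default 10).
#' @param spacing Years between consecutive waves (default 1).
#' @param jitter_sd SD of the normal jitter added to each observed age, in
#'   years (default 0.1). Set to 0 for exactly regular ages.
#' @param seed Optional integer seed.
#' @return A long-format observation grid (`data.frame`), `n_subjects *
#'   n_waves` rows; see the package overview for the column contract.
#' @export
#' @examples
#' g <- make_cohort_grid(n_subjects = 10, seed = 1)
#' cor(g$age, g$exposure_count)
make_cohort_grid <- function(n_subjects = 150, n_waves = 5,
                             baseline_age = 10, spacing = 1,
                             jitter_sd = 0.1, seed = NULL) {
  set_seed_if(seed)
  new_grid(rep(baseline_age, n_subjects), n_waves, spacing, jitter_sd,
           "cohort")
}

#' Generate an accelerated longitudinal observation grid
#'
#' Subjects enter at staggered baseline ages drawn uniformly from a set of
#' yearly entry cohorts and are each observed over only a slice of the total
#' age range (planned missingness with respect to age). This decouples age
#' from assessment count: at the defaults (250 subjects, 3 annual waves,
#' seven entry cohorts) the pooled age-by-exposure correlation is about .38
#' and the variance inflation factor about 1.17.
#'
#' @inheritParams make_cohort_grid
#' @param entry_ages Baseline ages of the entry cohorts; each subject's
#'   baseline is sampled uniformly from this set (default `10:16`).
#' @return A long-format observation grid.
#' @export
#' @examples
#' g <- make_accelerated_grid(n_subjects = 50, seed = 1)
#' range(g$age)
make_accelerated_grid <- function(n_subjects = 250, n_waves = 3,
                                  entry_ages = 10:16, spacing = 1,
                                  jitter_sd = 0.1, seed = NULL) {
  set_seed_if(seed)
  # sample.int to keep a length-1 entry_ages literal, not a range
  baseline <- entry_ages[sample.int(length(entry_ages), n_subjects,
                                    replace = TRUE)]
  new_grid(baseline, n_waves, spacing, jitter_sd, "accelerated")
}

#' Generate a school-cohort observation grid
#'
#' A cohort design with respect to measurement occasions, but with baseline
#' ages uniformly distributed over a one-year band, as for children sampled
#' within a school grade. Used by the staggered-intervention and
#' time-varying-covariate scenarios.
#'
#' @inheritParams make_cohort_grid
#' @param baseline_age Lower edge of the baseline age band (default 10).
#' @param age_band Width of the uniform baseline age band in years
#'   (default 1). A zero-width band reduces to [make_cohort_grid()].
#' @return A long-format observation grid.
#' @export
make_school_grid <- function(n_subjects = 150, n_waves = 5,
                             baseline_age = 10, age_band = 1, spacing = 1,
                             jitter_sd = 0.1, seed = NULL) {
  set_seed_if(seed)
  if (age_band < 0) stop("age_band must be non-negative")
  baseline <- baseline_age + stats::runif(n_subjects, 0, age_band)
  new_grid(baseline, n_waves, spacing, jitter_sd, "school_cohort")
}

#' Assign a randomly staggered intervention to an observation grid
#'
#' Each subject's intervention onset occasion is drawn uniformly from
#' `{0, ..., n_waves}`; onset `n_waves` means the subject is never treated
#' during the observation window. `tx_count` is 0 before onset and then
#' counts occasions from onset onward (1, 2, ...). Randomizing onset across
#' occasions makes the design accelerated with respect to the intervention
#' even though it is a cohort with respect to age: at the defaults (150
#' subjects, 5 waves) the pooled age-by-treatment correlation is about .55.
#'
#' @param grid An observation grid with at least 2 waves.
#' @param include_never_treated Logical; if `TRUE` (default) the onset
#'   support includes one cell beyond the last occasion, so roughly
#'   1/(n_waves+1) of subjects remain untreated throughout.
#' @param seed Optional integer seed.
#' @return The grid with `tx_count` filled in.
#' @export
#' @examples
#' g <- assign_intervention(make_school_grid(n_subjects = 20, seed = 1), seed = 2)
#' table(g$tx_count)
assign_intervention <- function(grid, include_never_treated = TRUE,
                                seed = NULL) {
  set_seed_if(seed)
  n_waves <- max(grid$occasion) + 1L
  if (n_waves < 2L) stop("grid must have at least two waves")
  ids <- unique(grid$subject_id)
  top <- if (include_never_treated) n_waves else n_waves - 1L
  onset <- sample(0:top, length(ids), replace = TRUE)
  names(onset) <- as.character(ids)
  grid$tx_count <- pmax(0L, grid$occasion -
                          onset[as.character(grid$subject_id)] + 1L)
  grid
}

#' Generate an observation grid for the puberty scenarios
#'
#' All cells center the sampled ages on a mean of 12 years. The cohort frame
#' measures 188 subjects at 4 waves; `sampling = "slow"` uses the
#' traditional annual visit (3-year span) and `sampling = "fast"` a biannual
#' visit (1.5-year span). The accelerated frame measures 250 subjects at 3
#' waves with baseline ages uniform over a 3-year band, again centered so
#' the mean observed age is 12.
#'
#' @param sampling `"slow"` (annual) or `"fast"` (biannual visits).
#' @param frame `"cohort"` or `"accelerated"` with respect to age.
#' @param mean_age Target mean observed age in years (default 12).
#' @param jitter_sd SD of the per-observation age jitter (default 0.1).
#' @param seed Optional integer seed.
#' @return A long-format observation grid (752 rows for the cohort frame,
#'   750 for the accelerated frame).
#' @export
#' @examples
#' g <- make_puberty_grid("slow", "cohort", seed = 1)
#' round(mean(g$age), 2)
make_puberty_grid <- function(sampling = c("slow", "fast"),
                              frame = c("cohort", "accelerated"),
                              mean_age = 12, jitter_sd = 0.1, seed = NULL) {
  sampling <- match.arg(sampling)
  frame <- match.arg(frame)
  set_seed_if(seed)
  spacing <- if (sampling == "fast") 0.5 else 1
  if (frame == "cohort") {
    n <- 188L; w <- 4L
    baseline <- rep(mean_age - (w - 1L) / 2 * spacing, n)
    g <- new_grid(baseline, w, spacing, jitter_sd, "puberty_cohort")
  } else {
    n <- 250L; w <- 3L
    center <- mean_age - (w - 1L) / 2 * spacing
    baseline <- stats::runif(n, center - 1.5, center + 1.5)
    g <- new_grid(baseline, w, spacing, jitter_sd, "puberty_accelerated")
  }
  g
}
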