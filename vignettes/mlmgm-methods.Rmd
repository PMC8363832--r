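---
title: "Simulating and recovering multiple growth processes in longitudinal designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and recovering multiple growth processes in longitudinal designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmgm)
```

## The problem

Developmental outcomes rarely change along a single clock. A child tested
annually is simultaneously older, more practiced with the test battery,
further through puberty, and possibly further into an intervention. All of
these *growth processes* are monotone within person, so in a conventional
cohort design — everyone enrolled at the same age, everyone measured at every
wave — they advance in lock-step and become nearly collinear. The
conventional age-only growth model then silently attributes every omitted
process to age.

The multilevel multi-growth model (MLMGM) extends the standard mixed-effects
growth model with additional growth predictors:

$$
y_{ti} = \gamma_{00} + \gamma_{10}\,G^{(1)}_{ti} + \gamma_{20}\,G^{(2)}_{ti}
  + u_{0i} + u_{1i} G^{(1)}_{ti} + r_{ti},
$$

with subject random effects $u_{0i} \sim N(0, \tau_{00}^2)$ (and, in some
scenarios, a random age slope $u_{1i} \sim N(0, \tau_{11}^2)$) and residuals
$r_{ti} \sim N(0, \sigma^2)$. The model is well defined regardless of the
design, but whether its parameters are *recoverable* depends on the sampling
plan: only designs that observe each person on a subset of the levels of one
process — planned missingness, the defining feature of accelerated
longitudinal designs — keep the growth predictors decorrelated enough for
stable estimation.

This package is a simulation laboratory for that interaction between model
and design. It generates data under known multi-growth truths, fits both the
mis-specified (age-only) and properly specified models by REML, and
aggregates recovery diagnostics over replicated ensembles.

## Observation designs

Five design families are built in. All target a total budget of roughly 750
observations, which is large enough that the failures demonstrated are not
power problems.

* **Cohort** (`make_cohort_grid()`): 150 subjects, 5 annual waves, shared
  baseline age 10. Age and assessment count correlate at about .998,
  inflating the variance of either coefficient by a factor of roughly 200
  when both are modeled.
* **Accelerated** (`make_accelerated_grid()`): 250 subjects, 3 annual waves,
  baselines drawn uniformly from seven one-year entry cohorts (ages 10–16).
  The staggered entries cut the age-by-exposure correlation to about .38
  (VIF about 1.17). The seven-cohort span is what reproduces that
  correlation; a narrower two-year stagger would leave it above .8.
* **School cohort** (`make_school_grid()`): cohort with respect to
  occasions, but baseline ages uniform over a one-year band, as for
  children sampled within a grade.
* **Staggered intervention** (`assign_intervention()`): each subject's onset
  occasion is uniform over `{0, ..., n_waves}`, the last cell meaning never
  treated during the window. Including the never-treated cell is what yields
  the age-by-treatment correlations of about .55 (5 waves) and .53
  (4 waves); restricting onsets to observed occasions would push them to
  about .65.
* **Puberty** (`make_puberty_grid()`): 188 subjects at 4 waves centered on
  mean age 12; annual visits span 3 years ("slow") and biannual visits 1.5
  years ("fast"). Both rates share the same subject and wave counts so the
  sampling-rate comparison is not confounded with the budget. The
  accelerated frame uses 250 subjects at 3 waves with baselines spread over
  a 3-year band.

Every observed age carries independent `N(0, 0.1^2)` jitter. The jitter is
applied per observation, not accumulated across intervals: cumulative
jitter would double the effective age noise by the last wave and halve the
cohort design's variance inflation, which is a property of the designs under
study. Jitter that would break within-subject age monotonicity (essentially
impossible at the default SD, but possible for extreme settings) is redrawn
per subject, and a hundred failed redraws raise an error rather than emit an
invalid grid.

Age anchors (10, 12, and so on) are labels only: every predictor is
grand-mean centered before simulation and fitting, so shifting the anchors
changes nothing but axis labels.

## Pubertal trajectories

Each subject follows a logistic maturation curve
$p = 1 / (1 + e^{-k(x - z)})$ over the age offset $x$ from the sample mean.
The midpoint $z$ is truncated-normal with SD 1.5 (high-variability
conditions) or 0.5 (low variability) and bounds $\pm 3$; the steepness $k$
is Gamma with shape 10 and rate 3. Reading the gamma pair as shape/*rate*
(mean $k \approx 3.33$, central 2%–98% transition $2\ln(49)/k \approx
2.3$ years) is forced by the requirement that most transitions take more
than two years; a scale-3 reading would produce quarter-year transitions.
Timing and tempo are coupled through a Gaussian copula with correlation
+0.5 — early starters transition more slowly — which preserves both
marginals exactly. The magnitude of the coupling is a package choice (only
its sign is substantively motivated); under it the four design cells span
age-by-puberty correlations from .345 (high variability, biannual visits)
to .898 (low variability, annual visits).

Tanner staging (`tanner_stage()`) coarsens $p$ at cut-points
.05/.35/.65/.95 with half-open-up intervals, so the boundary value .95 maps
to stage 5. In the Tanner-model fits the stage enters as a numeric
predictor: its main effect is grand-mean centered, but the age-by-Tanner
product is built from the *raw* 1–5 score. That coding is deliberate. With
a fully centered product the Tanner model's age coefficient is unbiased
(~0.00), and the coarsening artifact under study disappears; with the raw
product the age term absorbs $-\gamma_{int}\,\overline{\text{stage}}
\approx .13 \times 2.9 \approx .39$, the upward age bias (standardized bias
roughly 4.5–8) that makes Tanner-based age effects untrustworthy. Judged
truths scale accordingly: the Tanner main effect is evaluated against
$\gamma_{puberty}/4$ per stage and the interaction against
$\gamma_{int}/4$.

## Scenarios and generating values

Fixed effects default to moderately strong values ($\gamma = 0.3$), with
weaker product terms; random intercepts default to SD 0.5 and residuals to
SD 1. The intervention and TVC scenarios use intercept SD 1.0, a random age
slope SD 0.15 and residual SD 0.5; the puberty scenarios use intercept SD
0.5 and residual SD 0.5 (these are the values the properly specified fits
recover as $\tau$ and $\sigma$). The scenario library:

| scenario | generating fixed effects |
|---|---|
| `practice_only` | age 0, practice 0.3 |
| `age_only` | age 0.3, practice 0 |
| `additive` | age 0.3, practice 0.3 |
| `quadratic` | age 0.3, age$^2$ $-0.1$, practice 0.3 |
| `habituation` | age 0.3, exposure $-0.3$ |
| `snr_inverse` | age $-0.3$, practice 0.3 |
| `intervention` | age 0.3, treatment 0.3, age$\times$tx $-0.1$ |
| `tvc_stress` | age 0.3, stress 0.3, age$\times$stress $-0.1$ |
| `puberty` | age 0, puberty 2, age$\times$puberty $-0.5$ |

Interactions and the quadratic are built from centered terms (except the
Tanner product, above), and outcome generation uses exactly the columns the
properly specified model fits — with one exception, the stress TVC.

### The stress TVC and its measurement error

Unlike assessment counts, a psychological covariate such as stress is
measured with error. The generator draws a latent stress signal
$s_{ti} = 0.5\,\text{age}_c + \eta_i + \epsilon_{ti}$ with a stable
person-level component ($\eta_i$, SD 1.3) and occasion-level fluctuation
($\epsilon$, SD 0.75); the observed covariate adds independent $N(0, 0.5^2)$
measurement error. The outcome is generated from the error-free signal while
the model is fit on the contaminated observation. The slope and variance
split were calibrated once — against the pooled age-stress correlation
(about .41) and the direction and magnitude of the resulting age bias
(standardized bias near 1.9) — and then frozen.

This scenario is the one place where a stated recovery property cannot be
met in full: classical measurement-error
theory guarantees that the error-contaminated stress coefficient is
attenuated (and the centered interaction with it), so no generating
mechanism of this family can leave the stress estimate exactly unbiased
while the age term absorbs almost two standard deviations of bias. The test
suite asserts both properties anyway; the attenuation assertions fail by
construction and are documented as a known limitation rather than loosened.

## Fitting and evaluation

Models are fit by REML via `lmerTest::lmer()` with subject random
intercepts (plus a random age slope where the generating model has one),
and two-sided p-values use Satterthwaite degrees of freedom. At 750
observations the df correction is nearly inconsequential, but it matches
the pipeline applied analysts actually run. Bonferroni adjustment multiplies
each p-value by the number of growth predictors in its own model (1–3).
Non-converged and singular fits are flagged and excluded from aggregation;
the harness warns when more than 2% of an ensemble drops, which does not
occur under the default conditions.

Ensemble diagnostics follow the conventions of simulation studies of
estimator recovery: the "standard error" of a parameter is the SD of its
estimates across replicants; standardized bias is (mean − truth)/SD with
|bias| > .25 flagged; significance proportions count only correct-sign
rejections (except under a zero truth, where they are plain false-positive
rates); the growth correlation is the pooled observation-level Pearson
correlation of the two uncentered predictors; and the VIF is 1/(1−R²) from
the observation-level regression of age on the other linear growth
predictor(s), products excluded. For quadratic fits, `implied_vertex()`
reports the inflection point $-\gamma_1 / (2\gamma_2)$, whose instability
under collinearity is itself a diagnostic.

## Reproducibility and problem sizes

Replicant $r$ of an ensemble uses the deterministic child seed
`child_seed(master_seed, r)`, so any single replicant can be regenerated in
isolation and results are independent of execution order; re-running a
configuration with the same master seed reproduces every output bit for
bit.

Full-fidelity ensembles use 1000 replicants per cell. The package defaults
to 200 (500 for significance-rate estimates), which keeps the Monte-Carlo
standard error of a mean estimate near the full-size ensemble SDs while a
full scenario cell runs in well under a minute; `reproduce_table()` accepts
`n_replicants = 1000` for full-fidelity runs. The bundled test-suite
checks compare ensemble statistics at tolerances of three Monte-Carlo
standard errors at these reduced sizes.

## What the generator does and does not emulate

The synthetic data reproduce the structural features that drive the
design–model interaction: monotone within-person growth predictors, their
design-controlled correlations, Gaussian random effects, and MCAR deletion
(`inject_mcar()`) at a configurable rate. They do not emulate attrition or
other non-random missingness, non-Gaussian or heteroskedastic errors,
group-specific (e.g., sex-specific) pubertal distributions, autoregressive
residual structure, or measurement models richer than the Tanner
coarsening and the stress error term. Passing recovery checks here
therefore demonstrates the design logic — which confounds are resolvable
under which sampling plans — not robustness of the fitted models to those
unmodeled real-data features.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config("practice_only", design = "accelerated")
run <- run_replications(cfg, n_replicants = 200, master_seed = 1)
run$summaries$mis     # age-only model: practice aliases into age
run$summaries$proper  # two-growth model: both effects recovered
```
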