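# mlmgm: a simulation laboratory for multilevel multi-growth models

Longitudinal studies of development face a structural confound: age,
accumulated assessment experience, interventions and pubertal maturation
are all *growth processes* — monotone within-person clocks — and in a
conventional cohort design (everyone enrolled at the same age, measured at
every wave) they advance in lock-step. An age-only growth model then
absorbs every omitted process into its age effect, and adding the omitted
predictor does not help when the two are correlated at ρ ≈ .998.

The multilevel multi-growth model (MLMGM) extends the mixed-effects growth
model to several simultaneous growth predictors,

y<sub>ti</sub> = γ₀₀ + γ₁₀·G¹<sub>ti</sub> + γ₂₀·G²<sub>ti</sub> +
u<sub>0i</sub> + u<sub>1i</sub>·G¹<sub>ti</sub> + r<sub>ti</sub>,

and recovers their separate effects *when the sampling design cooperates*:
each person must be observed on only a subset of the levels of one process
(planned missingness, as in accelerated longitudinal designs). This package
is the full Monte-Carlo pipeline for studying that interaction between
model and design:

* **Designs** — cohort, accelerated (staggered entry cohorts), school
  cohort, randomly staggered interventions, and biannual/annual puberty
  designs, all on a ~750-observation budget.
* **Generating models** — nine named scenarios (practice, habituation,
  additive, quadratic, intervention, error-contaminated stress TVC,
  puberty with Tanner-stage coarsening, ...) with configurable fixed and
  random effects, plus MCAR deletion.
* **Fitting** — mis-specified (age-only) and properly specified models by
  REML (`lme4`/`lmerTest`, Satterthwaite p-values, Bonferroni correction).
* **Diagnostics** — standardized bias ((mean estimate − truth)/SD across
  replicants, |bias| > .25 flagged), growth-predictor correlations,
  variance inflation factors, correct-sign significance rates, implied
  quadratic vertices.

Intended users are methodologists and developmental researchers planning
longitudinal studies or auditing inference from existing cohort data.

## Worked example

Practice effects only (age truly has no effect), accelerated design:

```r
library(mlmgm)
cfg <- scenario_config("practice_only", design = "accelerated")
run <- run_replications(cfg, n_replicants = 200, master_seed = 1)
run
```

```
<mlmgm_run> practice_only | 200 replicants | master seed 1

-- mis model --
Replication summary over 200 converged replicants
  rho_growth: mean 0.379 (sd 0.009)
  VIF:        mean 1.17 (sd 0.010)
        term mean_est sd_est min_est max_est std_bias prop_sig_raw prop_sig_adj
 (Intercept)    0.001  0.047  -0.130   0.131       NA           NA           NA
       age_c    0.068  0.022   0.001   0.132    3.018         0.88         0.88
       sigma    1.023  0.032   0.908   1.109    0.713           NA           NA
       tau00    0.493  0.062   0.308   0.668   -0.113           NA           NA

-- proper model --
Replication summary over 200 converged replicants
  rho_growth: mean 0.379 (sd 0.009)
  VIF:        mean 1.17 (sd 0.010)
             term mean_est sd_est min_est max_est std_bias prop_sig_raw prop_sig_adj
      (Intercept)    0.001  0.047  -0.130   0.131       NA           NA           NA
            age_c    0.001  0.025  -0.050   0.065    0.033         0.05        0.015
 exposure_count_c    0.302  0.052   0.107   0.444    0.031         1.00        0.995
            sigma    0.995  0.030   0.883   1.075   -0.153           NA           NA
            tau00    0.494  0.057   0.326   0.656   -0.104           NA           NA
```

Reading the output: in the mis-specified (age-only) model the practice
effect aliases into age — the mean age estimate is 0.068 instead of the
generating 0 (standardized bias 3.0), and 88% of replicants "detect" a
spurious age effect. The properly specified two-growth model recovers both
truths (age ≈ 0.001, practice ≈ 0.302) with the false-positive rate for age
at the nominal 5% and the practice effect detected in 100% of replicants —
possible here only because the accelerated design holds the age-practice
correlation at .379 (VIF 1.17). Re-running with `design = "cohort"` raises
the correlation to .998 and the practice effect survives detection in only
about a tenth of replicants.

`reproduce_table(5, n_replicants = 200, master_seed = 1)` regenerates a
full puberty table cell by cell; shipped YAML configurations for every
scenario live under `inst/extdata/scenarios/`, and a thin command-line
front end is installed at `inst/cli/mlmgm.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mlmgm.R", package = "mlmgm"))')
CFG=$(Rscript -e 'cat(mlmgm::list_scenario_configs()[["additive_cohort"]])')
Rscript "$CLI" run --config "$CFG" --reps 50 --seed 1 --out out/
```

## Package layout

```
R/designs.R     observation-grid generators (cohort, accelerated, school,
                intervention, puberty)
R/puberty.R     sigmoid trajectories, correlated timing/tempo, Tanner stages
R/scenarios.R   scenario configs, outcome simulation, stress TVC, MCAR
R/fitting.R     REML fits, Bonferroni adjustment, implied vertex
R/metrics.R     bias / correlation / VIF / significance diagnostics
R/harness.R     replication loops, table reproduction
```

See `vignettes/mlmgm-methods.Rmd` for the modeling assumptions, the design
decisions behind the default study conditions, and known limitations.
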