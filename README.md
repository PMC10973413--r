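# banditjars

Simulation and hierarchical Bayesian analysis of explore–exploit behaviour
under harshness in a restless four-armed bandit ("bandit jars")
fire-fighting task.

## The problem

How do people decide to abandon a working strategy? The *constrained
flexibility framework* predicts that switching is shaped jointly by the
variability of the environment and by its *harshness* — the severity of the
consequences of failure. The bandit-jars task operationalises this: on each
of 75 trials per block a player picks one of four water jars, collects its
puddle (1–100 reward units) into a tube, and every 300 collected units a
rain shower puts out one of up to 15 burning trees (a new fire ignites
every third trial). Blocks cross *stable vs variable* reward schedules with
a *harsh* condition in which the tube leaks 35 units at every selection; a
second, between-participant manipulation adds a monetary bonus (0.03 per
tube fill).

`banditjars` is for researchers who want to simulate this design, generate
constraint-satisfying reward schedules and synthetic cohorts with known
ground truth, and run the two inference arms — switching-probability
contrasts and a hierarchical Rescorla–Wagner model — with parameter
recovery as the primary validation.

## The models at its core

Switching behaviour: a nested ladder of hierarchical Bayesian logistic
regressions of the switch indicator (next choice ≠ current choice) on the
previous reward, environment variability *V*, harshness *H* (and incentive
*I*), with per-participant random intercepts and reward slopes, compared by
WAIC and summarised by 95% HPDI contrasts of predicted switch probability
after high (55–100, "elective") or low (0–45, "responsive") rewards.

Learning: attractions updated by the Rescorla–Wagner rule with
condition-indexed learning rate φ and softmax choice with elective
exploration weight λ,

    A[i, t+1] = (1 − φ) A[i, t] + φ π[i, t]
    P[i] = exp(λ A[i]) / Σ_m exp(λ A[m])      (λ = 0 ⇒ uniform choice)

fitted hierarchically (logit-normal φ, log-normal λ per condition cell) by
MAP with a Laplace posterior approximation; see the methods vignette
(`vignettes/banditjars-methods.Rmd`) for the estimation details and design
choices.

## Worked example

```r
library(banditjars)

# constraint-satisfying schedule sets (variance, pairwise-difference and
# grand-total windows all enforced by rejection sampling)
sets <- generate_study_sets(n_sets = 5, seed = 42)
sets[[1]]$stable
#> <reward_schedule> set 1, stable environment
#>   per-jar variances: 36.3, 22.8, 24.3, 21.8
#>   cumulative totals: 2323, 3226, 4124, 5028 (grand total 14701)
#>   rejections before acceptance: 0

# a synthetic cohort of 20 learning agents with known parameters
cohort <- simulate_cohort(cohort_config(n_agents = 20), seed = 42)

# switching arm: code switches, fit the interaction model, contrast
records <- code_switches(cohort$trials)
fit <- fit_switch_model(records, model_id = "1.3", seed = 42)
posterior_switch_contrast(fit, list(V = 1, H = 0), list(V = 1, H = 1),
                          bin = "elective",
                          label = "Variable: NotHarsh - Harsh, elective")
#> <bj_contrast> Variable: NotHarsh - Harsh, elective
#>   mean 0.1404, 95% HPDI [0.1026, 0.1747]

# RL arm: hierarchical fit, recovery against the known truth, contrast
rl <- fit_rl(cohort$trials, seed = 42)
recovery_report(cohort$params, rl)
#> <bj_recovery>
#>  parameter pearson spearman   bias  rmse coverage
#>        phi   0.831    0.838 -0.015 0.066    0.938
#>     lambda   0.935    0.964  2.319 7.217    0.963
contrast_rl_parameters(rl, "variable.harsh", "variable.not_harsh", "lambda")
#> <bj_rl_contrast> lambda: variable.harsh - variable.not_harsh
#>   link scale:    mean 0.4556, 95% HPDI [0.1670, 0.7136]
#>   natural scale: mean 5.1064, 95% HPDI [2.2034, 8.6492]

# perceived harshness from the ordinal stress ratings
stress_effect(cohort$ratings)
#> <bj_stress> harsh - not-harsh effect: 2.26 latent SD (95% interval [1.35, 3.20])
#>   tally: 90% harsh higher, 10% equal, 0% not-harsh higher (n = 20)
```

Reading the numbers: this cohort was generated with elective exploration
suppressed under harshness in variable environments, and both arms recover
that — switching after high rewards is about 14 percentage points more
likely in the Variable Not-Harsh than Variable Harsh condition, and the
harsh-minus-not-harsh λ contrast is positive (higher λ = less exploration).
Recovery correlations and ~95% interval coverage show the estimator tracks
the known ground truth. The stress model recovers the simulated 2.19-SD
latent effect.

`run_pipeline(config, seed, out_dir)` chains every stage (schedules →
cohort → switching ladder with WAIC and contrasts → RL fit with recovery
report → outcome statistics) into a deterministic output directory.

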