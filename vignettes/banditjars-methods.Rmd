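---
title: "Models and methods behind banditjars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind banditjars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditjars)
```

## The task and the scientific question

`banditjars` studies explore–exploit behaviour under *harshness* — the
severity of the consequences of strategy failure — in a restless four-armed
bandit framed as a fire-fighting game. On each of 75 trials per block a
player picks one of four water jars; the puddle it yields (1–100 reward
units) is collected into a tube. When the tube reaches 300 units a rain
shower extinguishes one burning tree; a new fire ignites every third trial
(rain resets the countdown; fires cap at 15 trees). Blocks cross two
manipulations:

* **Variability** — *stable* blocks have jar payoffs that keep their
  ordering over time; *variable* blocks have payoffs that drift strongly.
* **Harshness** — in *harsh* blocks the tube leaks 35 units at every jar
  selection, raising the cost of poor choices. A second, between-participant
  harshness manipulation pays a monetary bonus (0.03 currency units per
  fill) in the incentivised arm.

The package provides every stage needed to study this design end to end
without any external data: a constrained reward-schedule generator, a
deterministic task simulator, a synthetic cohort of learning agents with
known parameters, and the two inference arms (a hierarchical logistic
ladder for jar switching and a hierarchical Rescorla–Wagner model), with
parameter recovery as the primary validation surface.

## Reward schedules

Schedules are 4 jars × 75 trials of integer payoffs in [1, 100], drawn per
jar from an AR(1) process (`stats::arima.sim`) and accepted only when every
design window holds:

* per-jar sample variance in [20, 40] (stable) or [200, 400] (variable);
* every absolute pairwise difference of the four per-jar cumulative totals
  in [500, 3000];
* the grand total of all four jars in [14,500, 15,000].

Whole four-jar candidates are rejected together; patching single jars would
bias the coupled cumulative constraints. Design choices, made once:

* **AR order and coefficient.** The design names only "ARIMA"; we use
  AR(1) with coefficient 0.5, the simplest autocorrelated process
  consistent with that, with per-environment innovation SDs set so the
  marginal variance sits mid-window: `sd = sqrt(var * (1 - 0.5^2))` with
  target variance 30 (stable) and 300 (variable).
* **Centring.** Each jar's series is re-centred exactly on its target mean
  before rounding and clamping. The jar means (31, 43, 55, 67) put the
  pairwise cumulative differences (900 / 1800 / 2700) and grand total
  (14,700) inside their windows by construction, so rejections are driven
  almost entirely by the variance windows and acceptance is fast. The wide
  spread also makes the trial-wise argmax nearly always jar 4 in stable
  sets — the generator *verifies* rather than assumes this, since payoff
  noise can still cross adjacent jars on single trials.
* **Out-of-range values** are rounded and clamped into [1, 100]. Whether
  the original design clipped, rescaled, or re-simulated is unknown;
  clamping is this package's choice and affects < 3% of values in variable
  schedules.

## The task simulator

`step_trial()` is exact integer-unit bookkeeping, with these documented
resolutions of under-specified corners:

* the harsh leak applies *at selection, before collection*, floored at
  zero (an empty tube cannot leak) — so a constant payoff of 35 pins the
  tube at 35 units forever and never fills it;
* water above 300 at a fill carries over into the next cycle rather than
  vanishing;
* fires cap at 15 trees and the block continues;
* rain resets the fire countdown.

Two conservation identities are enforced in tests for every simulated
block: `tube_after = max(0, tube_before − leak·harsh) + reward − 300·rain`
per trial, and `Σ rewards = 300·fills + final tube + Σ leaked` per block.

## The learning model

Agents assign each jar an attraction $A_{i,t}$, updated only for the chosen
jar with payoffs normalized to $(0, 1]$ (division by 100):

$$A_{i,t+1} = (1 - \varphi)\,A_{i,t} + \varphi\, \pi_{i,t}$$

and choose by softmax over all four jars:

$$P_i = \frac{\exp(\lambda A_i)}{\sum_{m=1}^{4} \exp(\lambda A_m)}$$

$\varphi \in (0,1)$ is the learning rate; $\lambda \ge 0$ is the elective
exploration weight (on the normalized payoff scale), with $\lambda = 0$
uniform-random choice. Both are indexed by condition cell
(environment × harshness, and additionally by incentive arm when both arms
are present). Unchosen attractions are frozen (their payoffs are
unobserved). One printed source formulation bounds the softmax denominator
at 2; with four jars we treat that as a typographical slip and sum over all
four, noting the discrepancy rather than silently correcting it.

**Initial attractions.** We default to *optimistic initialization*
$A_{i,0} = 1$ (the normalized payoff maximum) at every block start, exposed
as `init_attraction` throughout. With zero initialization, any agent
exploitative enough to reproduce realistic stable-environment performance
locks onto whichever jar it samples first (the chosen jar immediately looks
better than the untouched zeros), which collapses optimal-choice rates to
chance; optimistic starts make early exploration an emergent property of
the same greedy policy. The fitted model uses the identical setting, so
generation and inference are consistent.

## The synthetic cohort

`simulate_cohort()` draws per-agent, condition-indexed parameters from
logit-normal ($\varphi$) and log-normal ($\lambda$) population
distributions, runs each agent through four counterbalanced blocks (either
environment first, either harshness first, environments adjacent), assigns
one of five schedule sets per agent, and generates 1–5 ordinal stress
ratings from a cumulative latent-normal model (harsh condition shifted by
2.19 latent SD by default, the study-level effect size).

The default population means were calibrated once against the study-level
behaviour the design reports — high optimal-choice proportions in stable
blocks, roughly 0.45 in variable blocks, learning slightly faster under
harshness, and elective exploration reduced (higher $\lambda$) under
harshness only in variable environments:
$\varphi$ = (0.42, 0.47, 0.45, 0.50) and $\lambda$ = (32, 32, 10, 13)
across (stable·not-harsh, stable·harsh, variable·not-harsh,
variable·harsh), with SDs 0.5 (logit) and 0.4 (log).

What the generator does *not* emulate: reaction times, attention lapses,
within-block parameter drift, and mixtures of qualitatively different
strategies (a deterministic pattern-cycling agent is available separately
via `simulate_cycler()` but is not mixed into the default cohort). Passing
recovery tests therefore show that the estimators work *when the model
family is correct*; they do not certify the model against real behaviour.

## Posterior inference: MAP + Laplace, by design

All Bayesian fits in the package use maximum a posteriori estimation with a
Laplace (quadratic) posterior approximation and analytic gradients, the
same approximation family popularised for applied Bayesian course work.
Two structural refinements matter for hierarchical models:

* **Hierarchical logistic models** (the switching ladder, the
  optimal-choice summaries): given the random-effect SDs the log posterior
  is strictly concave, so the inner mode over (fixed effects, random
  effects) is found by damped Newton with the exact analytic Hessian. The
  SDs themselves are updated by a penalized EM step whose sufficient
  statistic includes the Laplace variances of the random effects. A joint
  mode over all parameters including the SDs would be degenerate (the
  classic hierarchical funnel: the density grows without bound as the SD
  collapses onto perfectly-pooled effects); the EM step integrates over
  random-effect uncertainty and avoids this.
* **The hierarchical RL model**: the likelihood separates across
  agent-cells, so per-agent 2×2 damped-Newton blocks alternate with
  closed-form population-mean updates and the same penalized-EM SD update.
  Posterior draws are then taken from the Gaussian approximation over
  participant parameters and population means at the converged SDs.

Both are empirical-Bayes approximations: uncertainty in the random-effect
SDs is not propagated into the reported intervals. Priors are weakly
informative and recorded in every fit object: normal(0, 1.5²) on logistic
coefficients, normal(0, 1) on RL population means (logit/log scales),
half-normal(1) on all hierarchical SDs. Condition cells are fitted with
independent population distributions; a correlated-offsets variant was
considered and rejected because the Laplace machinery would gain little
inferential value for the added Hessian complexity.

Convergence is checked by the gradient norm at the mode and recorded in
`$diagnostics`; a non-positive-definite numeric Hessian is repaired by
flooring its eigenvalues at 0.04 (every direction carries prior curvature
far above this, so the floor only absorbs finite-difference noise) and the
repair is flagged.

## The switching arm

`code_switches()` emits one record per trial except block-final trials
(switch = 1 when the next choice differs). The model ladder mirrors the
design: model 1.0 has random intercepts only; 1.1 adds the previous-reward
slope; 1.2 lets intercept and slope depend on variability and harshness
(random reward slopes from here up); 1.3 adds their interaction. The 6.x
ladder adds the incentive predictor and its interactions, up to the
four-way 6.4. Predictors are coded Variable = 1, Harsh = 1,
No-incentive = 1; reward is standardized internally and coefficients can be
reported on either scale (`coef(fit, scale = "raw")`).

Models are compared by WAIC computed from pointwise log-likelihoods over
the posterior draws; `hpdi()` implements the shortest-interval definition
directly (both have brute-force oracles in the test suite). Posterior
contrasts average the population-level predicted switch probability
(random effects at zero) uniformly over the integer reward grid of a bin —
elective 55–100, responsive 0–45, with rewards 46–54 in neither bin
(excluded from binned contrasts but retained in fitting, where reward
enters continuously); the stricter supplementary responsive cutoff (≤ 25)
is available in `classify_switch_type()`. No multiplicity correction is
applied, matching interval-based reporting.

## The outcome statistics

* `optimal_choice_summary()`: hierarchical binomial (participant random
  intercepts, logit link) per condition cell, flagged against the 0.25
  four-jar chance level. The exact likelihood behind the original
  summaries is unstated; this is our documented choice.
* `score_trend()`: within-block cumulative collected reward regressed on
  trial with participant random intercepts (`lme4::lmer`). The original
  outcome definition and units are not recoverable from the text, so this
  is labelled an approximation and its numeric scale is not compared to
  printed values.
* `stress_effect()`: cumulative *probit* ordinal regression
  (`MASS::polr`) of the 1–5 ratings on the harshness condition, so the
  effect reads directly in latent SD units, plus the three-way tally
  (harsh higher / equal / not-harsh higher). The probit link is our choice
  precisely because the effect is reported in standard deviations.

## Numerical and validation choices

* Every random draw descends from one root seed via named substreams
  (`substream_seed`), so identical configuration and seed reproduce
  byte-identical outputs.
* Likelihood oracles: the RL sequence likelihood is checked against
  brute-force enumeration of all $4^T$ choice sequences ($T \le 6$,
  probabilities summing to 1 within 1e-10) and a pencil-and-paper
  three-trial example; HPDI against an exhaustive window scan; WAIC
  against a loop-level reimplementation.
* Parameter recovery (the primary validation): a 40-agent cohort with
  $\varphi, \lambda$ on a known full-factorial grid
  ({0.20, 0.35, 0.50, 0.65} × {2, 5, 9, 14}) over 4 blocks × 75 trials
  must achieve rank correlation ≥ 0.6 between truth and posterior means
  for both parameters, with 95% intervals covering truth at 95 ± 10
  points. $\lambda$ is only one-sidedly identified above ~20 on 75 trials
  (all sufficiently greedy policies look alike), which is why the grid
  tops out at 14 and why stable-environment $\lambda$ estimates rely more
  on pooling.
* The switching ladder is validated generatively: data simulated with a
  variability × harshness × reward interaction (100 agents) must rank
  model 1.3 best by WAIC, and the Variable NotHarsh − Harsh elective
  contrast must recover its positive sign in ≥ 90% of 10 replications.
  Ten replications (rather than 20) keep the default test suite inside a
  practical runtime at 100 agents each.
* Problem sizes in the shipped tests (cohorts of 3–12 agents for unit
  tests; 40 and 100 agents for the validation suites) were chosen to keep
  the full suite in the low minutes on a single core.

## Known limitations

* Intervals are Gaussian approximations at the mode; heavy-tailed or
  strongly skewed posteriors (small cohorts, extreme parameters) will be
  summarised optimistically, and random-effect-SD uncertainty is not
  propagated.
* The score-trend model is an approximation to an unspecified original;
  its slopes are not comparable to the printed intervals.
* The generator's parameters emulate study-level summaries, not the
  original participants; headline real-data interval estimates are outside
  the package's desk-scale claims.
* `optimal_jar()` breaks payoff ties toward the lower jar index; ties are
  rare with integer payoffs but the rule is load-bearing for exact chance
  calculations.
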