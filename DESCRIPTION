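Package: banditjars
Title: Simulation and Hierarchical Bayesian Analysis of a Harsh Restless Four-Armed Bandit Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying explore-exploit behaviour under environmental
    harshness in a restless four-armed bandit ("bandit jars") fire-fighting
    task. Provides a constrained autoregressive reward-schedule generator with
    rejection sampling against variance, cumulative-difference and grand-total
    acceptance windows; a deterministic simulator of the task block (puddle
    rewards, tube accounting with a harshness leak, fire and rain dynamics);
    a synthetic cohort of Rescorla-Wagner/softmax learning agents with known
    condition-indexed learning rate and elective-exploration parameters; a
    hierarchical Bayesian logistic ladder for jar-switching behaviour with
    WAIC model comparison and posterior HPDI contrasts; a hierarchical
    Rescorla-Wagner model fit with parameter-recovery diagnostics; and the
    accompanying outcome statistics (optimal-choice proportions against
    chance, score trends, and a cumulative ordinal model of perceived
    harshness). All posterior inference uses maximum a posteriori estimation
    with a Laplace (quadratic) approximation and analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
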