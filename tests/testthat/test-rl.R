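test_that("random choice gives exactly T log(1/4) and matches hand computation", {
  rows <- data.frame(choice = c(2, 4, 1, 3, 2), reward = c(50, 80, 10, 60, 30))
  expect_equal(sequence_loglik(rows, phi = 0.5, lambda = 0), 5 * log(0.25))

  # three-trial pencil-and-paper oracle, phi = 0.5, lambda = 2, A0 = 0
  rows3 <- data.frame(choice = c(1, 1, 2), reward = c(80, 40, 100))
  # t1: A = (0,0,0,0) -> log(1/4); A1 <- 0.5*0.8 = 0.4
  # t2: log(e^0.8 / (e^0.8 + 3)); A1 <- 0.5*0.4 + 0.5*0.4 = 0.4
  # t3: log(1 / (e^0.8 + 3))
  byhand <- log(0.25) + (0.8 - log(exp(0.8) + 3)) + (0 - log(exp(0.8) + 3))
  expect_equal(sequence_loglik(rows3, 0.5, 2, init_attraction = 0), byhand,
               tolerance = 1e-12)
})

test_that("sequence probabilities sum to one over all 4^T enumerations", {
  set.seed(21)
  rewards <- sample(1:100, 5)
  for (pars in list(c(0.3, 1.5), c(0.7, 6))) {
    total <- 0
    grid <- expand.grid(rep(list(1:4), 5))
    for (r in seq_len(nrow(grid))) {
      rows <- data.frame(choice = as.integer(grid[r, ]), reward = rewards)
      ll <- sequence_loglik(rows, pars[1], pars[2])
      oracle <- oracle_sequence_loglik(as.integer(grid[r, ]), rewards,
                                       pars[1], pars[2])
      expect_equal(ll, oracle, tolerance = 1e-10)
      total <- total + exp(ll)
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("payoff shifts cancel when the initial attraction shifts with them", {
  rows <- data.frame(choice = c(2, 3, 2, 1, 4, 2), reward = c(30, 70, 50, 20, 90, 60))
  base <- sequence_loglik(rows, 0.4, 3, init_attraction = 0)
  shifted <- rows
  shifted$reward <- shifted$reward + 25
  expect_equal(sequence_loglik(shifted, 0.4, 3, init_attraction = 0.25), base,
               tolerance = 1e-12)
})

test_that("attractions reset across blocks and trials must be contiguous", {
  one <- data.frame(block_position = 1, trial = 1:3,
                    environment = "stable", harshness = "harsh",
                    choice = c(1, 1, 1), reward = c(90, 90, 90))
  two <- one
  two$block_position <- 2
  two$environment <- "variable"
  both <- rbind(one, two)
  ph <- c(stable.harsh = 0.5, stable.not_harsh = 0.5,
          variable.harsh = 0.5, variable.not_harsh = 0.5)
  lm <- c(stable.harsh = 2, stable.not_harsh = 2,
          variable.harsh = 2, variable.not_harsh = 2)
  expect_equal(sequence_loglik(both, ph, lm),
               2 * sequence_loglik(one, 0.5, 2))
  bad <- one
  bad$trial <- c(1, 2, 4)
  expect_error(sequence_loglik(bad, 0.5, 2), "contiguous")
})

test_that("lower lambda produces more non-argmax choices in simulation", {
  sets <- fixture_sets(1, seed = 501)
  cells <- condition_cells()
  explo <- vapply(c(1, 5, 20), function(lam) {
    cfg <- cohort_config(
      n_agents = 6,
      phi_mean = stats::setNames(rep(qlogis(0.4), 4), cells),
      phi_sd = stats::setNames(rep(0, 4), cells),
      lambda_mean = stats::setNames(rep(log(lam), 4), cells),
      lambda_sd = stats::setNames(rep(0, 4), cells),
      n_schedule_sets = 1)
    co <- simulate_cohort(cfg, seed = 31, schedule_sets = sets)
    # proportion of choices that are not the current scheduled argmax
    opt <- integer(nrow(co$trials))
    for (env in c("stable", "variable")) {
      sel <- co$trials$environment == env
      opt[sel] <- optimal_jar(sets[[1]][[env]])[co$trials$trial[sel]]
    }
    mean(co$trials$choice != opt)
  }, numeric(1))
  expect_true(all(diff(explo) < 0))
})

test_that("the hierarchical RL fit recovers parameters and pools sensibly", {
  co <- fixture_cohort(n_agents = 12, seed = 502)
  fit <- fit_rl(co$trials, n_draws = 400, seed = 6)
  expect_lt(fit$diagnostics$grad_norm, 1)
  rec <- recovery_report(co$params, fit)
  expect_gt(rec$summary$spearman[rec$summary$parameter == "phi"], 0.5)
  expect_gt(rec$summary$spearman[rec$summary$parameter == "lambda"], 0.5)
  # per-draw antisymmetry and self-contrast of population contrasts
  ct <- contrast_rl_parameters(fit, "variable.harsh", "variable.not_harsh",
                               "lambda")
  ct_rev <- contrast_rl_parameters(fit, "variable.not_harsh", "variable.harsh",
                                   "lambda")
  expect_equal(ct$link$draws, -ct_rev$link$draws)
  self <- contrast_rl_parameters(fit, "stable.harsh", "stable.harsh", "phi")
  expect_equal(self$natural$mean, 0)
  expect_error(contrast_rl_parameters(fit, "nope", "stable.harsh", "phi"),
               "unknown condition cell")
})

test_that("a zero-variance cohort shrinks agents towards a common value", {
  cells <- condition_cells()
  cfg <- cohort_config(
    n_agents = 8,
    phi_sd = stats::setNames(rep(0, 4), cells),
    lambda_sd = stats::setNames(rep(0, 4), cells),
    n_schedule_sets = 1)
  co <- simulate_cohort(cfg, seed = 41)
  fit <- fit_rl(co$trials, n_draws = 200, seed = 7)
  est <- coef(fit)
  # spread of per-agent posterior means within a cell stays small
  for (cl in unique(est$cell)) {
    expect_lt(stats::sd(est$phi[est$cell == cl]), 0.1)
  }
})

test_that("recovery reporting demands overlapping identifiers", {
  co <- fixture_cohort(n_agents = 4, seed = 503)
  fit <- fit_rl(co$trials, n_draws = 100, seed = 8)
  truth_wrong <- co$params
  truth_wrong$agent_id <- truth_wrong$agent_id + 100
  expect_error(recovery_report(truth_wrong, fit), "no overlapping agent ids")
})
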