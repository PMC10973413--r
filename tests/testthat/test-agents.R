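test_that("the attraction update replaces, mixes, and converges geometrically", {
  expect_equal(rw_update(c(0.3, 0, 0, 0), 1, 0.8, phi = 1)[1], 0.8)
  expect_equal(rw_update(rep(0, 4), 2, 1, phi = 0.5), c(0, 0.5, 0, 0))
  # only the chosen jar moves
  a <- rw_update(c(0.1, 0.2, 0.3, 0.4), 3, 0.9, phi = 0.2)
  expect_equal(a[-3], c(0.1, 0.2, 0.4))
  # repeated identical payoff: fixed point at the payoff, geometric approach
  a <- rep(0, 4)
  errs <- numeric(20)
  for (i in 1:20) {
    a <- rw_update(a, 1, 0.6, phi = 0.3)
    errs[i] <- abs(a[1] - 0.6)
  }
  expect_lt(errs[20], 1e-2)
  expect_equal(errs[-1] / errs[-20], rep(0.7, 19), tolerance = 1e-10)
})

test_that("softmax probabilities are normalized, stable, and shift-invariant", {
  # lambda = 0 is uniform-random choice regardless of attractions
  expect_equal(softmax_prob(c(-3, 0, 2, 100), 0), rep(0.25, 4))
  # large lambda concentrates on the argmax
  p <- softmax_prob(c(0.1, 0.9, 0.2, 0.3), 50)
  expect_gt(p[2], 0.999)
  # shift invariance
  a <- c(0.2, -1, 3, 0.5)
  expect_equal(softmax_prob(a, 2.5), softmax_prob(a + 17.3, 2.5))
  # extreme attractions still sum to one
  for (a in list(c(1e4, -1e4, 0, 0), rep(1e4, 4), rep(-1e4, 4))) {
    p <- softmax_prob(a, 1)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 | a < max(a) - 50))
    expect_true(all(is.finite(p)))
  }
  expect_error(softmax_prob(c(1, 2, 3, 4), -1))
})

test_that("cycling agents walk their pattern verbatim with switch rate one", {
  sets <- fixture_sets(1, seed = 301)
  tt <- simulate_cycler(c(3, 2, 1, 4), sets[[1]], agent_id = 7)
  expect_equal(tt$choice[1:8], c(3, 2, 1, 4, 3, 2, 1, 4))
  recs <- code_switches(tt)
  expect_true(all(recs$switch == 1))
  # single-jar pattern never switches
  tt1 <- simulate_cycler(1L, sets[[1]])
  expect_equal(mean(code_switches(tt1)$switch), 0)
  expect_error(simulate_cycler(c(0, 5), sets[[1]]), "valid jar")
})

test_that("cohort simulation is deterministic with the documented shape", {
  co1 <- fixture_cohort(n_agents = 4, seed = 77)
  co2 <- fixture_cohort(n_agents = 4, seed = 77)
  expect_identical(co1$trials, co2$trials)
  expect_identical(co1$params, co2$params)
  expect_equal(nrow(co1$trials), 4 * 4 * 75)
  validate_trial_table(co1$trials)
  # four condition cells of ground truth per agent
  expect_equal(nrow(co1$params), 4 * 4)
  expect_true(all(co1$params$phi > 0 & co1$params$phi < 1))
  expect_true(all(co1$params$lambda >= 0))
  # block orders counterbalanced across agents
  first_env <- with(co1$trials[co1$trials$block_position == 1 &
                                 co1$trials$trial == 1, ],
                    table(environment))
  expect_equal(as.numeric(first_env), c(2, 2))
})

test_that("population draws match their configured distributions", {
  cfg <- cohort_config(n_agents = 1000)
  params <- draw_agent_params(cfg, seed = 5)
  for (cl in c("stable.not_harsh", "variable.harsh")) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    sub <- params[params$environment == parts[1] & params$harshness == parts[2], ]
    se <- cfg$phi_sd[[cl]] / sqrt(1000)
    expect_lt(abs(mean(sub$logit_phi) - cfg$phi_mean[[cl]]), 3 * se)
    se_l <- cfg$lambda_sd[[cl]] / sqrt(1000)
    expect_lt(abs(mean(sub$log_lambda) - cfg$lambda_mean[[cl]]), 3 * se_l)
  }
  # zero population SDs collapse every agent onto the means
  cfg0 <- cohort_config(n_agents = 5,
                        phi_sd = stats::setNames(rep(0, 4), condition_cells()),
                        lambda_sd = stats::setNames(rep(0, 4), condition_cells()))
  p0 <- draw_agent_params(cfg0, seed = 1)
  expect_equal(length(unique(round(p0$phi[p0$environment == "stable" &
                                            p0$harshness == "harsh"], 12))), 1)
})

test_that("switch rate decreases monotonically in lambda", {
  sets <- fixture_sets(1, seed = 303)
  cells <- condition_cells()
  rates <- vapply(c(0, 2, 8, 32), function(lam) {
    cfg <- cohort_config(
      n_agents = 8,
      phi_mean = stats::setNames(rep(qlogis(0.4), 4), cells),
      phi_sd = stats::setNames(rep(0, 4), cells),
      lambda_mean = stats::setNames(rep(log(lam + 1e-9), 4), cells),
      lambda_sd = stats::setNames(rep(0, 4), cells),
      n_schedule_sets = 1)
    co <- simulate_cohort(cfg, seed = 11, schedule_sets = sets)
    mean(code_switches(co$trials)$switch)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  # lambda = 0 agents switch at the 1 - 1/4 chance rate
  expect_lt(abs(rates[1] - 0.75), 0.03)
})

test_that("stress ratings follow the latent cumulative-normal model", {
  r0 <- simulate_stress_ratings(0, n_agents = 2000, seed = 3)
  expect_true(all(unlist(r0[, 2:3]) %in% 1:5))
  # no effect: direction of the difference is symmetric
  ph <- mean(r0$harsh_rating > r0$not_harsh_rating)
  pl <- mean(r0$harsh_rating < r0$not_harsh_rating)
  expect_lt(abs(ph - pl), 0.05)
  # strong effect: large majority rate harsh at or above not-harsh
  r2 <- simulate_stress_ratings(2, n_agents = 2000, seed = 4)
  expect_gt(mean(r2$harsh_rating >= r2$not_harsh_rating), 0.9)
  expect_error(simulate_stress_ratings(1, cutpoints = c(1, 0, 2, 3)),
               "increasing")
})
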