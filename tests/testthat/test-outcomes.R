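test_that("optimal-choice summaries agree with a direct recount", {
  co <- fixture_cohort(n_agents = 8, seed = 601)
  oc <- optimal_choice_summary(co$trials, co$schedule_sets, n_draws = 400,
                               seed = 1)
  # oracle recount of the empirical proportion per condition cell
  for (r in seq_len(nrow(oc))) {
    sub <- co$trials[co$trials$environment == oc$environment[r] &
                       co$trials$harshness == oc$harshness[r], ]
    hits <- vapply(seq_len(nrow(sub)), function(i) {
      sched <- co$schedule_sets[[sub$schedule_set_id[i]]][[sub$environment[i]]]
      sub$choice[i] == optimal_jar(sched, sub$trial[i])
    }, logical(1))
    expect_equal(oc$prop_empirical[r], mean(hits))
    # the posterior mean sits near the empirical proportion
    expect_lt(abs(oc$post_mean[r] - mean(hits)), 0.05)
  }
  expect_true(all(oc$hpdi_lower <= oc$post_mean & oc$post_mean <= oc$hpdi_upper))
})

test_that("uniform-random agents straddle chance; an oracle policy hits 1", {
  sets <- fixture_sets(1, seed = 602)
  cells <- condition_cells()
  cfg <- cohort_config(
    n_agents = 10,
    lambda_mean = stats::setNames(rep(log(1e-9), 4), cells),
    lambda_sd = stats::setNames(rep(0, 4), cells),
    n_schedule_sets = 1)
  co <- simulate_cohort(cfg, seed = 51, schedule_sets = sets)
  oc <- optimal_choice_summary(co$trials, sets, n_draws = 400, seed = 2)
  expect_true(all(!oc$excludes_chance))

  # an always-optimal trial table
  opt_rows <- do.call(rbind, lapply(1:3, function(ag) {
    do.call(rbind, lapply(1:4, function(b) {
      env <- if (b <= 2) "stable" else "variable"
      sched <- sets[[1]][[env]]
      data.frame(participant_id = ag, study_arm = "none", environment = env,
                 harshness = if (b %% 2) "not_harsh" else "harsh",
                 block_position = b, trial = 1:75,
                 choice = optimal_jar(sched),
                 reward = sched$values[cbind(optimal_jar(sched), 1:75)],
                 tube_after = 0, rain_triggered = FALSE, schedule_set_id = 1)
    }))
  }))
  oc1 <- optimal_choice_summary(opt_rows, sets, n_draws = 300, seed = 3)
  expect_true(all(oc1$prop_empirical == 1))
  expect_true(all(oc1$post_mean > 0.95))
  expect_true(all(oc1$excludes_chance))
})

test_that("score trends recover a constant per-trial accumulation rate", {
  # constant reward c per trial: cumulative score is exactly c * trial
  const_rows <- do.call(rbind, lapply(1:4, function(ag) {
    data.frame(participant_id = ag, study_arm = "none", environment = "stable",
               harshness = "not_harsh", block_position = 1, trial = 1:75,
               choice = 1, reward = 42, tube_after = 0,
               rain_triggered = FALSE, schedule_set_id = 1)
  }))
  st <- score_trend(const_rows)
  expect_equal(st$slope, 42, tolerance = 1e-6)
  expect_true(st$positive)

  # learning agents accumulate faster than uniform-random agents
  sets <- fixture_sets(1, seed = 603)
  cells <- condition_cells()
  mk <- function(lam) {
    cfg <- cohort_config(
      n_agents = 8,
      lambda_mean = stats::setNames(rep(log(lam), 4), cells),
      lambda_sd = stats::setNames(rep(0, 4), cells),
      n_schedule_sets = 1)
    simulate_cohort(cfg, seed = 61, schedule_sets = sets)$trials
  }
  st_learn <- score_trend(mk(25))
  st_rand <- score_trend(mk(1e-9))
  for (env in c("stable", "variable")) {
    expect_gt(mean(st_learn$slope[st_learn$environment == env]),
              mean(st_rand$slope[st_rand$environment == env]))
  }
})

test_that("the ordinal stress model recovers simulated latent effects", {
  effects <- c(0, 0.5, 1, 2)
  est <- vapply(effects, function(ef) {
    r <- simulate_stress_ratings(ef, n_agents = 200, seed = 70 + ef * 10)
    stress_effect(r, seed = 1)$effect
  }, numeric(1))
  # monotone in the simulated effect and covering truth at 2.0
  expect_true(all(diff(est) > 0))
  r2 <- simulate_stress_ratings(2, n_agents = 200, seed = 71)
  s2 <- stress_effect(r2, seed = 2)
  expect_true(s2$interval[1] <= 2 && 2 <= s2$interval[2])
  expect_equal(sum(s2$tally), 100)

  # degenerate: identical ratings for everyone
  rid <- data.frame(participant_id = 1:10, harsh_rating = 3,
                    not_harsh_rating = 3)
  sid <- stress_effect(rid)
  expect_true(sid$interval[1] <= 0 && 0 <= sid$interval[2])
  expect_equal(unname(sid$tally), c(0, 100, 0))
  expect_error(stress_effect(data.frame(participant_id = 1:3,
                                        harsh_rating = c(1, 2, 9),
                                        not_harsh_rating = c(1, 1, 1))),
               "1..5")
})
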