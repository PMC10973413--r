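test_that("switch coding matches a direct pairwise recount", {
  tt <- data.frame(participant_id = 1, study_arm = "none",
                   environment = "stable", harshness = "not_harsh",
                   block_position = 1, trial = 1:3, choice = c(1, 1, 2),
                   reward = c(60, 30, 80), tube_after = 0,
                   rain_triggered = FALSE, schedule_set_id = 1)
  recs <- code_switches(tt)
  expect_equal(recs$switch, c(0, 1))
  expect_equal(recs$prev_reward, c(60, 30))

  # full block: 75 trials produce 74 records, none spanning block boundaries
  co <- fixture_cohort(n_agents = 3, seed = 401)
  recs <- code_switches(co$trials)
  expect_equal(nrow(recs), 3 * 4 * 74)
  # independent oracle: recount switches with an explicit loop
  for (ag in 1:3) {
    for (b in 1:4) {
      blk <- co$trials[co$trials$participant_id == ag &
                         co$trials$block_position == b, ]
      blk <- blk[order(blk$trial), ]
      manual <- as.integer(blk$choice[-1] != blk$choice[-75])
      got <- recs[recs$participant_id == ag & recs$block_position == b, ]
      expect_equal(got$switch, manual)
      expect_equal(got$prev_reward, blk$reward[-75])
    }
  }
  # unsorted input is an integrity error
  shuffled <- co$trials[sample(nrow(co$trials)), ]
  expect_error(code_switches(shuffled), "sorted")
})

test_that("switch types bin by the printed reward cutoffs", {
  expect_equal(classify_switch_type(60), "elective")
  expect_equal(classify_switch_type(55), "elective")
  expect_equal(classify_switch_type(30), "responsive")
  expect_equal(classify_switch_type(45), "responsive")
  expect_equal(classify_switch_type(50), "unclassified")
  # supplementary stricter responsive cutoff
  expect_equal(classify_switch_type(30, responsive_max = 25), "unclassified")
  expect_equal(classify_switch_type(20, responsive_max = 25), "responsive")
  expect_error(classify_switch_type(101), "\\[0, 100\\]")
})

test_that("hpdi is the shortest mass-covering interval", {
  # all draws equal: degenerate point interval
  expect_equal(unname(hpdi(rep(3.3, 50))), c(3.3, 3.3))
  # uniform draws: interval length approaches the mass
  set.seed(8)
  u <- runif(100000)
  iv <- hpdi(u, 0.95)
  expect_lt(abs((iv[2] - iv[1]) - 0.95), 0.01)
  # skewed draws: matches the brute-force window scan exactly
  for (seed in 1:5) {
    set.seed(seed)
    x <- rgamma(500, shape = 2)
    expect_equal(unname(hpdi(x, 0.95)), oracle_hpdi(x, 0.95))
    expect_equal(unname(hpdi(x, 0.5)), oracle_hpdi(x, 0.5))
  }
  expect_error(hpdi(1), ">= 2")
  expect_error(hpdi(c(1, 2), mass = 1.5), "probability")
})

test_that("WAIC matches a brute-force computation from raw draws", {
  set.seed(9)
  ll <- matrix(rnorm(200 * 10, mean = -1.3, sd = 0.3), 200, 10)
  w <- waic_from_loglik(ll)
  expect_equal(w$waic, oracle_waic(ll), tolerance = 1e-8)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic))
})

test_that("the null intercept model recovers a 50% switch rate", {
  set.seed(10)
  recs <- data.frame(
    participant_id = rep(1:20, each = 60), study_arm = "none",
    environment = "stable", harshness = "not_harsh", block_position = 1,
    trial = rep(1:60, 20), prev_reward = sample(0:100, 1200, replace = TRUE),
    switch = rbinom(1200, 1, 0.5))
  fit <- fit_switch_model(recs, "1.0", n_draws = 500, seed = 2)
  iv <- hpdi(fit$draws[, "b_(Intercept)"])
  expect_lt(iv[1], 0)
  expect_gt(iv[2], 0)
})

test_that("a negative reward effect on switching is recovered by model 1.1", {
  recs <- simulate_switch_records(
    n_agents = 40,
    beta = c("(Intercept)" = 0, x = -1, V = 0, H = 0, "V:H" = 0,
             "x:V" = 0, "x:H" = 0, "x:V:H" = 0),
    trials_per_cell = 40, seed = 12)
  fit <- fit_switch_model(recs, "1.1", n_draws = 500, seed = 3)
  slope_draws <- fit$draws[, "b_x"]
  expect_gt(mean(slope_draws < 0), 0.95)
  # raw-scale slope is the standardized slope rescaled by the reward SD
  co <- coef(fit, scale = "raw")
  expect_equal(unname(co["x"]),
               unname(coef(fit)["x"]) / fit$reward_scale)
})

test_that("self-contrasts are centred on zero and full-bin contrasts match rates", {
  recs <- simulate_switch_records(n_agents = 40, trials_per_cell = 40,
                                  seed = 13)
  fit <- fit_switch_model(recs, "1.3", n_draws = 600, seed = 4)
  same <- posterior_switch_contrast(fit, list(V = 1, H = 1), list(V = 1, H = 1),
                                    "elective")
  expect_equal(same$mean, 0)
  expect_true(same$hpdi[1] <= 0 && same$hpdi[2] >= 0)
  # antisymmetry draw by draw
  ab <- posterior_switch_contrast(fit, list(V = 1, H = 0), list(V = 1, H = 1),
                                  "elective")
  ba <- posterior_switch_contrast(fit, list(V = 1, H = 1), list(V = 1, H = 0),
                                  "elective")
  expect_equal(ab$draws, -ba$draws)
  # full-range contrast approximates the marginal empirical rate difference
  full <- posterior_switch_contrast(fit, list(V = 1, H = 0), list(V = 1, H = 1),
                                    "full")
  emp <- with(recs[recs$environment == "variable", ],
              mean(switch[harshness == "not_harsh"]) -
                mean(switch[harshness == "harsh"]))
  expect_lt(abs(full$mean - emp), 0.05)
})

test_that("stress filtering keeps only harsh-more-stressful participants", {
  co <- fixture_cohort(n_agents = 5, seed = 404)
  ratings <- data.frame(participant_id = 1:5,
                        harsh_rating = c(4, 3, 5, 2, 3),
                        not_harsh_rating = c(2, 3, 1, 3, 2))
  sub <- filter_by_stress(co$trials, ratings)
  expect_setequal(unique(sub$participant_id), c(1, 3, 5))
  expect_error(filter_by_stress(co$trials, ratings[1:3, ]),
               "missing stress ratings")
})
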