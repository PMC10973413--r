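#' Rescorla-Wagner attraction update
#'
#' Updates only the chosen jar's attraction towards the (normalized) payoff:
#' `A_chosen <- (1 - phi) * A_chosen + phi * payoff`. Unchosen jars are left
#' unchanged (their payoffs are unobserved).
#'
#' @param attractions numeric vector of current attractions (one per jar).
#' @param choice chosen jar index.
#' @param payoff observed payoff, normalized to the \[0, 1\] scale.
#' @param phi learning rate in (0, 1].
#' @return updated attraction vector.
#' @export
rw_update <- function(attractions, choice, payoff, phi) {
  stopifnot(phi > 0, phi <= 1, choice >= 1, choice <= length(attractions))
  attractions[choice] <- (1 - phi) * attractions[choice] + phi * payoff
  attractions
}

#' Softmax choice probabilities
#'
#' `P_i = exp(lambda * A_i) / sum_m exp(lambda * A_m)` over all jars,
#' stabilized by max-subtraction. `lambda = 0` is uniform-random choice
#' (probability 0.25 per jar); larger `lambda` concentrates choice on the
#' highest attraction.
#'
#' @param attractions numeric vector of attractions.
#' @param lambda elective-exploration weight, >= 0 (lower = more exploration).
#' @return probability vector summing to 1.
#' @export
softmax_prob <- function(attractions, lambda) {
  stopifnot(lambda >= 0)
  z <- lambda * attractions
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @rdname softmax_prob
#' @param seed optional seed for the sampled jar.
#' @return `softmax_policy` returns `list(prob, choice)` with `choice`
#'   sampled from the probabilities.
#' @export
softmax_policy <- function(attractions, lambda, seed = NULL) {
  p <- softmax_prob(attractions, lambda)
  ch <- with_seed(seed, sample.int(length(p), 1L, prob = p))
  list(prob = p, choice = ch)
}

# The four counterbalanced block orders: environments kept adjacent, either
# environment first, either harshness first within environments.
block_orders <- function() {
  cells <- function(env, h1, h2) {
    data.frame(environment = env, harshness = c(h1, h2))
  }
  list(
    rbind(cells("stable", "not_harsh", "harsh"), cells("variable", "not_harsh", "harsh")),
    rbind(cells("stable", "harsh", "not_harsh"), cells("variable", "harsh", "not_harsh")),
    rbind(cells("variable", "not_harsh", "harsh"), cells("stable", "not_harsh", "harsh")),
    rbind(cells("variable", "harsh", "not_harsh"), cells("stable", "harsh", "not_harsh"))
  )
}

condition_cells <- function() {
  c("stable.not_harsh", "stable.harsh", "variable.not_harsh", "variable.harsh")
}

#' Cohort configuration for the synthetic-agent generator
#'
#' Population distributions of the condition-indexed learning rate `phi`
#' (logit-normal) and elective-exploration weight `lambda` (log-normal,
#' interpreted on the normalized 0-1 payoff scale), per condition cell
#' `environment.harshness`. The defaults emulate the study's qualitative
#' pattern: learning slightly faster under harshness, and elective
#' exploration reduced (higher lambda) under harshness in the variable
#' environment; the monetary arm suppresses exploration further in variable
#' environments.
#'
#' @param n_agents cohort size (the study analysed 100 per arm).
#' @param incentive "none" (Study-1 arm) or "monetary" (Study-2 arm).
#' @param phi_mean named numeric, logit-scale population means per cell.
#' @param phi_sd named numeric, logit-scale population SDs per cell.
#' @param lambda_mean named numeric, log-scale population means per cell.
#' @param lambda_sd named numeric, log-scale population SDs per cell.
#' @param n_schedule_sets number of counterbalanced schedule sets.
#' @param stress_effect latent-SD shift of the harsh stress rating.
#' @param stress_cutpoints 4 increasing cutpoints of the 5-point scale.
#' @param init_attraction starting attraction of every jar at each block
#'   start, on the normalized payoff scale. The default of 1 (optimistic
#'   initialization at the payoff maximum) makes agents sample every jar
#'   early before settling, which zero initialization cannot produce at
#'   exploitative lambda values.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_agents = 100L,
                          incentive = c("none", "monetary"),
                          phi_mean = NULL, phi_sd = NULL,
                          lambda_mean = NULL, lambda_sd = NULL,
                          n_schedule_sets = 5L,
                          stress_effect = 2.19,
                          stress_cutpoints = c(-0.5, 0.5, 1.5, 2.5),
                          init_attraction = 1) {
  incentive <- match.arg(incentive)
  cells <- condition_cells()
  named <- function(x) stats::setNames(x, cells)
  if (is.null(phi_mean)) {
    phi_nat <- if (incentive == "none") c(0.42, 0.47, 0.45, 0.50) else c(0.39, 0.43, 0.50, 0.55)
    phi_mean <- named(stats::qlogis(phi_nat))
  }
  if (is.null(lambda_mean)) {
    lam_nat <- if (incentive == "none") c(32, 32, 10, 13) else c(32, 32, 13, 15)
    lambda_mean <- named(log(lam_nat))
  }
  if (is.null(phi_sd)) phi_sd <- named(rep(0.5, 4))
  if (is.null(lambda_sd)) lambda_sd <- named(rep(0.4, 4))
  stopifnot(
    n_agents >= 1, all(phi_sd >= 0), all(lambda_sd >= 0),
    length(stress_cutpoints) == 4L, !is.unsorted(stress_cutpoints, strictly = TRUE),
    all(cells %in% names(phi_mean)), all(cells %in% names(lambda_mean))
  )
  structure(
    list(n_agents = as.integer(n_agents), incentive = incentive,
         phi_mean = phi_mean[cells], phi_sd = phi_sd[cells],
         lambda_mean = lambda_mean[cells], lambda_sd = lambda_sd[cells],
         n_schedule_sets = as.integer(n_schedule_sets),
         stress_effect = stress_effect, stress_cutpoints = stress_cutpoints,
         init_attraction = init_attraction),
    class = "cohort_config"
  )
}

#' Draw ground-truth agent parameters from the population distributions
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame: `agent_id`, `environment`, `harshness`, `incentive`,
#'   `phi`, `lambda`, and the link-scale values `logit_phi`, `log_lambda`.
#' @export
draw_agent_params <- function(config, seed = NULL) {
  cells <- condition_cells()
  with_seed(seed, {
    rows <- lapply(cells, function(cl) {
      lp <- stats::rnorm(config$n_agents, config$phi_mean[[cl]], config$phi_sd[[cl]])
      ll <- stats::rnorm(config$n_agents, config$lambda_mean[[cl]], config$lambda_sd[[cl]])
      parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
      data.frame(agent_id = seq_len(config$n_agents),
                 environment = parts[1], harshness = parts[2],
                 incentive = config$incentive,
                 phi = stats::plogis(lp), lambda = exp(ll),
                 logit_phi = lp, log_lambda = ll)
    })
    out <- do.call(rbind, rows)
    out[order(out$agent_id), , drop = FALSE]
  })
}

# Shared block-runner: threads the task state while choices come either from
# a Rescorla-Wagner/softmax learner or from a fixed cycling pattern.
run_agent_block <- function(kind, schedule, cfg, harsh,
                            phi = NULL, lambda = NULL, pattern = NULL,
                            payoff_scale = 100, init_attraction = 1) {
  n <- cfg$n_trials_per_block
  state <- task_state_init(cfg)
  A <- rep(init_attraction, cfg$n_jars)
  choice <- integer(n); reward <- numeric(n)
  tube_after <- numeric(n); rain <- logical(n)
  for (t in seq_len(n)) {
    ch <- if (kind == "learner") {
      sample.int(cfg$n_jars, 1L, prob = softmax_prob(A, lambda))
    } else {
      pattern[(t - 1L) %% length(pattern) + 1L]
    }
    res <- step_trial(state, ch, schedule, cfg, harsh)
    state <- res$state
    choice[t] <- ch
    reward[t] <- res$outcome$reward
    tube_after[t] <- res$outcome$tube_after
    rain[t] <- res$outcome$rain_triggered
    if (kind == "learner") {
      A[ch] <- (1 - phi) * A[ch] + phi * (reward[t] / payoff_scale)
    }
  }
  data.frame(trial = seq_len(n), choice = choice, reward = reward,
             tube_after = tube_after, rain_triggered = rain)
}

#' Simulate one learning agent through its four blocks
#'
#' Composes the Rescorla-Wagner update, the softmax policy, and the task
#' simulator. Attractions reset to `init_attraction` at every block start;
#' payoffs are normalized by 100 before entering the update.
#'
#' @param params data.frame of this agent's parameters (rows = condition
#'   cells, columns `environment`, `harshness`, `phi`, `lambda`) as produced
#'   by [draw_agent_params()] filtered to one agent.
#' @param schedules one study-set pair `list(stable=, variable=)`.
#' @param task_cfg a [task_config()].
#' @param block_order order index 1..4 (see the counterbalancing scheme) or a
#'   4-row data.frame with columns `environment`, `harshness`.
#' @param seed optional seed.
#' @param agent_id,incentive identifiers recorded on the rows.
#' @param init_attraction starting attraction for every jar at block start.
#' @return trial-table data.frame (4 blocks x 75 trials) with the canonical
#'   columns (see [write_trial_table()]).
#' @export
simulate_agent <- function(params, schedules, task_cfg = task_config(),
                           block_order = 1L, seed = NULL, agent_id = 1L,
                           incentive = "none", init_attraction = 1) {
  order_df <- if (is.data.frame(block_order)) block_order else
    block_orders()[[block_order]]
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(order_df)), function(b) {
      env <- order_df$environment[b]
      hl <- order_df$harshness[b]
      row <- params[params$environment == env & params$harshness == hl, ]
      if (nrow(row) != 1L) stop("params must contain exactly one row per condition cell")
      tr <- run_agent_block("learner", schedules[[env]], task_cfg,
                            harsh = hl == "harsh",
                            phi = row$phi, lambda = row$lambda,
                            init_attraction = init_attraction)
      data.frame(participant_id = agent_id, study_arm = incentive,
                 environment = env, harshness = hl, block_position = b,
                 trial = tr$trial, choice = tr$choice, reward = tr$reward,
                 tube_after = tr$tube_after, rain_triggered = tr$rain_triggered,
                 schedule_set_id = schedules[[env]]$set_id)
    })
    do.call(rbind, blocks)
  })
}

#' Simulate a pattern-cycling (meta-strategy) agent
#'
#' Choices follow the jar pattern verbatim, wrapping around; rewards and tube
#' dynamics come from the task simulator. A pattern with no immediate repeats
#' yields a coded switch rate of exactly 1.
#'
#' @param pattern non-empty vector of jar indices, e.g. `c(3, 2, 1, 4)`.
#' @inheritParams simulate_agent
#' @return trial-table data.frame as for [simulate_agent()].
#' @export
simulate_cycler <- function(pattern, schedules, task_cfg = task_config(),
                            block_order = 1L, agent_id = 1L,
                            incentive = "none") {
  if (length(pattern) == 0L || any(pattern < 1) || any(pattern > task_cfg$n_jars) ||
      any(pattern != round(pattern))) {
    stop("`pattern` must be a non-empty vector of valid jar indices")
  }
  order_df <- if (is.data.frame(block_order)) block_order else
    block_orders()[[block_order]]
  blocks <- lapply(seq_len(nrow(order_df)), function(b) {
    env <- order_df$environment[b]
    hl <- order_df$harshness[b]
    tr <- run_agent_block("cycler", schedules[[env]], task_cfg,
                          harsh = hl == "harsh", pattern = pattern)
    data.frame(participant_id = agent_id, study_arm = incentive,
               environment = env, harshness = hl, block_position = b,
               trial = tr$trial, choice = tr$choice, reward = tr$reward,
               tube_after = tr$tube_after, rain_triggered = tr$rain_triggered,
               schedule_set_id = schedules[[env]]$set_id)
  })
  do.call(rbind, blocks)
}

#' Simulate a full cohort with known ground truth
#'
#' Draws per-agent condition-indexed parameters, assigns counterbalanced
#' block orders and schedule sets, simulates every agent through its four
#' blocks, and generates ordinal stress ratings. Ground truth is retained for
#' parameter-recovery tests.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed (all stages derive named substreams).
#' @param schedule_sets optional pre-generated list from
#'   [generate_study_sets()]; generated fresh when `NULL`.
#' @param task_cfg a [task_config()].
#' @return list with `trials` (trial table), `params` (ground-truth
#'   data.frame), `ratings` (stress ratings data.frame), `schedule_sets`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            schedule_sets = NULL, task_cfg = task_config()) {
  if (is.null(schedule_sets)) {
    schedule_sets <- generate_study_sets(config$n_schedule_sets,
                                         seed = substream_seed(seed, "schedules"))
  }
  params <- draw_agent_params(config, seed = substream_seed(seed, "params"))
  n <- config$n_agents
  orders <- ((seq_len(n) - 1L) %% 4L) + 1L
  set_ids <- ((seq_len(n) - 1L) %% length(schedule_sets)) + 1L
  trials <- do.call(rbind, lapply(seq_len(n), function(j) {
    simulate_agent(params[params$agent_id == j, ],
                   schedule_sets[[set_ids[j]]], task_cfg,
                   block_order = orders[j],
                   seed = substream_seed(seed, paste0("agent", j)),
                   agent_id = j, incentive = config$incentive,
                   init_attraction = config$init_attraction)
  }))
  rownames(trials) <- NULL
  ratings <- simulate_stress_ratings(config$stress_effect,
                                     config$stress_cutpoints, n,
                                     seed = substream_seed(seed, "stress"))
  list(trials = trials, params = params, ratings = ratings,
       schedule_sets = schedule_sets)
}

#' Simulate ordinal stress ratings
#'
#' Cumulative latent-normal model of the 1-5 "did you feel stressed?" scale:
#' each participant's latent stress is standard normal in the Not-Harsh
#' condition and shifted by `effect_size` latent SD units in the Harsh
#' condition; cutpoints bin the latent value into the five categories.
#'
#' @param effect_size latent shift in SD units.
#' @param cutpoints 4 strictly increasing cutpoints.
#' @param n_agents number of participants.
#' @param seed integer seed.
#' @return data.frame: `participant_id`, `harsh_rating`, `not_harsh_rating`,
#'   each in 1..5.
#' @export
simulate_stress_ratings <- function(effect_size = 2.19,
                                    cutpoints = c(-0.5, 0.5, 1.5, 2.5),
                                    n_agents = 100L, seed = NULL) {
  if (length(cutpoints) != 4L || is.unsorted(cutpoints, strictly = TRUE)) {
    stop("`cutpoints` must be 4 strictly increasing values")
  }
  with_seed(seed, {
    z_nh <- stats::rnorm(n_agents)
    z_h <- stats::rnorm(n_agents, mean = effect_size)
    data.frame(
      participant_id = seq_len(n_agents),
      harsh_rating = findInterval(z_h, cutpoints) + 1L,
      not_harsh_rating = findInterval(z_nh, cutpoints) + 1L
    )
  })
}
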