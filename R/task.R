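#' Task configuration
#'
#' Fixed design constants of the fire-fighting bandit block: 75 trials per
#' block, a 300-unit tube that triggers a rain shower (extinguishing one
#' fire) when full, a 35-unit leak per jar selection in the Harsh condition,
#' a new fire every 3 trials (reset by rain), 15 trees, and 4 jars.
#'
#' @param n_trials_per_block trials per block.
#' @param tube_capacity reward units needed to trigger rain.
#' @param leak_amount units leaked per selection in the Harsh condition.
#' @param fire_interval trials between fire ignitions.
#' @param n_trees number of trees (cap on active fires).
#' @param n_jars number of jars.
#' @param practice_trials practice trials per environment (simulated but
#'   excluded from analysis tables).
#' @return list of class `task_config`.
#' @export
task_config <- function(n_trials_per_block = 75L, tube_capacity = 300,
                        leak_amount = 35, fire_interval = 3L, n_trees = 15L,
                        n_jars = 4L, practice_trials = 15L) {
  cfg <- list(n_trials_per_block = as.integer(n_trials_per_block),
              tube_capacity = tube_capacity, leak_amount = leak_amount,
              fire_interval = as.integer(fire_interval),
              n_trees = as.integer(n_trees), n_jars = as.integer(n_jars),
              practice_trials = as.integer(practice_trials))
  if (any(unlist(cfg) <= 0)) stop("all task_config fields must be positive")
  if (cfg$leak_amount >= cfg$tube_capacity) {
    stop("leak_amount must be smaller than tube_capacity")
  }
  structure(cfg, class = "task_config")
}

#' Initial task state for a block
#'
#' @param config a [task_config()].
#' @return list of class `task_state` with `trial_index` (0-based),
#'   `tube_level`, `active_fires`, `trials_since_event`, `fills_count`.
#' @export
task_state_init <- function(config = task_config()) {
  structure(
    list(trial_index = 0L, tube_level = 0, active_fires = 0L,
         trials_since_event = 0L, fills_count = 0L),
    class = "task_state"
  )
}

#' Advance the task by one trial
#'
#' Applies one jar selection: in the Harsh condition the tube first leaks
#' `leak_amount` units (floored at zero), then the scheduled puddle reward is
#' collected into the tube. If the tube reaches capacity a rain shower
#' triggers: one fire is extinguished, the fill counter increments, the
#' fire countdown resets, and the remainder above capacity carries over.
#' Otherwise the countdown advances and, on reaching `fire_interval`, a new
#' fire ignites (capped at `n_trees`).
#'
#' @param state a `task_state`.
#' @param choice jar index in 1..n_jars.
#' @param schedule a `reward_schedule` (or bare 4 x T matrix).
#' @param config a [task_config()].
#' @param harsh logical; apply the leak?
#' @return list with `state` (updated `task_state`) and `outcome` (list:
#'   `choice`, `reward`, `tube_before`, `tube_after`, `rain_triggered`,
#'   `fires_after`, `leaked`).
#' @export
step_trial <- function(state, choice, schedule, config = task_config(),
                       harsh = FALSE) {
  values <- if (is.matrix(schedule)) schedule else schedule$values
  if (state$trial_index >= config$n_trials_per_block) {
    stop("block exhausted: trial_index >= n_trials_per_block")
  }
  if (!is.numeric(choice) || length(choice) != 1L || choice < 1 ||
      choice > config$n_jars || choice != round(choice)) {
    stop("`choice` must be a jar index in 1..", config$n_jars)
  }
  t <- state$trial_index + 1L
  reward <- values[choice, t]
  tube_before <- state$tube_level
  leaked <- 0
  tube <- tube_before
  if (harsh) {
    leaked <- min(tube, config$leak_amount)
    tube <- tube - leaked
  }
  tube <- tube + reward
  rain <- tube >= config$tube_capacity
  fires <- state$active_fires
  counter <- state$trials_since_event
  fills <- state$fills_count
  if (rain) {
    fires <- max(0L, fires - 1L)
    fills <- fills + 1L
    counter <- 0L
    tube <- tube - config$tube_capacity
  } else {
    counter <- counter + 1L
    if (counter >= config$fire_interval) {
      fires <- min(config$n_trees, fires + 1L)
      counter <- 0L
    }
  }
  state$trial_index <- t
  state$tube_level <- tube
  state$active_fires <- fires
  state$trials_since_event <- counter
  state$fills_count <- fills
  list(state = state,
       outcome = list(choice = as.integer(choice), reward = reward,
                      tube_before = tube_before, tube_after = tube,
                      rain_triggered = rain, fires_after = fires,
                      leaked = leaked))
}

#' Run one full block under a choice policy
#'
#' @param policy function `(state, trial)` returning a jar index; `trial` is
#'   1-based. Built-ins: `policy_fixed(j)`, `policy_random()`,
#'   `policy_cycle(pattern)`.
#' @param schedule a `reward_schedule`.
#' @param config a [task_config()].
#' @param harsh logical.
#' @param seed optional seed for stochastic policies.
#' @return data.frame with one row per trial: `trial`, `choice`, `reward`,
#'   `tube_before`, `tube_after`, `rain_triggered`, `fires_after`, `leaked`.
#' @export
run_block <- function(policy, schedule, config = task_config(),
                      harsh = FALSE, seed = NULL) {
  with_seed(seed, {
    n <- config$n_trials_per_block
    state <- task_state_init(config)
    choice <- integer(n); reward <- numeric(n)
    tube_before <- numeric(n); tube_after <- numeric(n)
    rain <- logical(n); fires <- integer(n); leaked <- numeric(n)
    for (t in seq_len(n)) {
      j <- policy(state, t)
      if (!is.numeric(j) || length(j) != 1L || j < 1 || j > config$n_jars ||
          j != round(j)) {
        stop(sprintf("policy returned an invalid jar at trial %d", t))
      }
      res <- step_trial(state, j, schedule, config, harsh)
      state <- res$state
      o <- res$outcome
      choice[t] <- o$choice; reward[t] <- o$reward
      tube_before[t] <- o$tube_before; tube_after[t] <- o$tube_after
      rain[t] <- o$rain_triggered; fires[t] <- o$fires_after
      leaked[t] <- o$leaked
    }
    data.frame(trial = seq_len(n), choice = choice, reward = reward,
               tube_before = tube_before, tube_after = tube_after,
               rain_triggered = rain, fires_after = fires, leaked = leaked)
  })
}

#' Built-in choice policies
#'
#' `policy_fixed` always picks one jar; `policy_random` picks uniformly at
#' random among the four jars; `policy_cycle` walks a jar pattern verbatim,
#' wrapping around.
#'
#' @param jar jar index for the fixed policy.
#' @param n_jars number of jars.
#' @param pattern integer vector of jar indices to cycle.
#' @return a policy function `(state, trial) -> jar`.
#' @export
policy_fixed <- function(jar) {
  force(jar)
  function(state, trial) jar
}

#' @rdname policy_fixed
#' @export
policy_random <- function(n_jars = 4L) {
  force(n_jars)
  function(state, trial) sample.int(n_jars, 1L)
}

#' @rdname policy_fixed
#' @export
policy_cycle <- function(pattern) {
  if (length(pattern) == 0L || any(pattern < 1) || any(pattern != round(pattern))) {
    stop("`pattern` must be a non-empty vector of valid jar indices")
  }
  force(pattern)
  function(state, trial) pattern[(trial - 1L) %% length(pattern) + 1L]
}

#' Trial-by-trial optimal jar
#'
#' The argmax jar of the four scheduled values at each trial; ties break to
#' the lowest jar index.
#'
#' @param schedule a `reward_schedule` or bare 4 x T matrix.
#' @param trial 1-based trial index or vector of indices; `NULL` for all.
#' @return integer vector of jar indices.
#' @export
optimal_jar <- function(schedule, trial = NULL) {
  values <- if (is.matrix(schedule)) schedule else schedule$values
  if (is.null(trial)) trial <- seq_len(ncol(values))
  if (any(trial < 1) || any(trial > ncol(values))) stop("trial out of range")
  apply(values[, trial, drop = FALSE], 2, which.max)
}

#' Bonus payment for tube fills
#'
#' @param fills_count number of times the tube was filled, >= 0.
#' @param rate currency per fill (GBP 0.03 in the incentivised arm).
#' @return currency amount.
#' @export
bonus_payment <- function(fills_count, rate = 0.03) {
  if (any(fills_count < 0)) stop("`fills_count` must be non-negative")
  fills_count * rate
}
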