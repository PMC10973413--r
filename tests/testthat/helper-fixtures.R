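# Shared small fixtures, built fresh in code.

fixture_sets <- function(n_sets = 2L, seed = 101L) {
  generate_study_sets(n_sets, seed = seed)
}

fixture_cohort <- function(n_agents = 6L, seed = 202L, ...) {
  simulate_cohort(cohort_config(n_agents = n_agents, n_schedule_sets = 2L, ...),
                  seed = seed)
}

# Brute-force RL sequence likelihood: explicit attraction bookkeeping, written
# independently of the package's vectorized path.
oracle_sequence_loglik <- function(choices, rewards, phi, lambda,
                                   init_attraction = 1, payoff_scale = 100) {
  A <- rep(init_attraction, 4)
  ll <- 0
  for (t in seq_along(choices)) {
    e <- exp(lambda * A - max(lambda * A))
    ll <- ll + log(e[choices[t]] / sum(e))
    A[choices[t]] <- (1 - phi) * A[choices[t]] + phi * rewards[t] / payoff_scale
  }
  ll
}

# Brute-force HPDI: scan every contiguous window of the sorted draws.
oracle_hpdi <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  w <- min(n, max(1L, ceiling(mass * n)))
  best <- c(s[1], s[w])
  for (i in seq_len(n - w + 1L)) {
    if (s[i + w - 1L] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + w - 1L])
  }
  best
}

# Brute-force WAIC from a loglik matrix using plain loops.
oracle_waic <- function(ll) {
  n <- ncol(ll)
  lppd <- 0; pw <- 0
  for (i in seq_len(n)) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    pw <- pw + var(ll[, i])
  }
  -2 * (lppd - pw)
}
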