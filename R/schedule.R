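#' Configuration for the reward-schedule generator
#'
#' The generator draws one autocorrelated series per jar from an AR(1)
#' process, re-centres each series exactly on its jar's target mean, rounds
#' and clamps into the 1-100 reward scale, and rejection-samples whole
#' four-jar candidates against the acceptance windows (see
#' [validate_schedule()]).
#'
#' Defaults: jar target means (31, 43, 55, 67) place every pairwise
#' cumulative difference (900 / 1800 / 2700 units over 75 trials) and the
#' grand total (14,700) inside their windows by construction; innovation
#' standard deviations are set so the marginal AR(1) variance sits mid-window
#' (30 for stable, 300 for variable): sd = sqrt(var * (1 - ar^2)).
#'
#' @param ar_coefficient AR(1) weight, in (-1, 1).
#' @param innovation_sd named numeric, per-environment innovation standard
#'   deviation (names "stable", "variable"), each >= 0.
#' @param target_means length-4 numeric, per-jar centring means on the
#'   reward scale.
#' @param target_mean overall centring mean; kept for single-series use
#'   ([simulate_raw_series()]) and defaults to the mean of `target_means`.
#' @param max_rejections positive integer; generation aborts with a
#'   diagnostic once this many whole-candidate rejections occur.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(ar_coefficient = 0.5,
                             innovation_sd = c(stable = sqrt(30 * 0.75),
                                               variable = sqrt(300 * 0.75)),
                             target_means = c(31, 43, 55, 67),
                             target_mean = mean(target_means),
                             max_rejections = 10000L) {
  stopifnot(
    is.numeric(ar_coefficient), length(ar_coefficient) == 1L,
    abs(ar_coefficient) < 1,
    is.numeric(innovation_sd), all(innovation_sd >= 0),
    all(c("stable", "variable") %in% names(innovation_sd)),
    is.numeric(target_means), length(target_means) == 4L,
    is.numeric(max_rejections), max_rejections >= 1
  )
  structure(
    list(ar_coefficient = ar_coefficient,
         innovation_sd = innovation_sd,
         target_means = target_means,
         target_mean = target_mean,
         max_rejections = as.integer(max_rejections)),
    class = "generator_config"
  )
}

# Acceptance windows printed for the task design.
schedule_windows <- function(environment) {
  list(
    variance = if (environment == "stable") c(20, 40) else c(200, 400),
    pairwise_diff = c(500, 3000),
    grand_total = c(14500, 15000)
  )
}

#' Simulate one raw autocorrelated series
#'
#' AR(1) simulation via [stats::arima.sim()], shifted to `config$target_mean`.
#' Degenerate settings (zero AR weight and/or zero innovation SD) are handled
#' directly so the limiting cases behave as expected.
#'
#' @param n_trials series length, >= 1.
#' @param config a [generator_config()].
#' @param seed integer seed; identical seed gives an identical series. `NULL`
#'   draws from the current RNG stream.
#' @param environment which innovation SD to use ("stable" or "variable").
#' @return numeric vector of length `n_trials`.
#' @export
simulate_raw_series <- function(n_trials, config = generator_config(),
                                seed = NULL, environment = "stable") {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  sd_in <- unname(config$innovation_sd[[environment]])
  phi <- config$ar_coefficient
  with_seed(seed, {
    if (sd_in == 0) {
      rep(config$target_mean, n_trials)
    } else if (phi == 0) {
      config$target_mean + stats::rnorm(n_trials, sd = sd_in)
    } else {
      config$target_mean +
        as.numeric(stats::arima.sim(model = list(ar = phi), n = n_trials,
                                    sd = sd_in))
    }
  })
}

#' Map a raw series into the 1-100 reward scale
#'
#' Rounds to the nearest integer and clamps into \[1, 100\]. Total function:
#' order-preserving for in-range values and the identity on integral values
#' already inside the range.
#'
#' @param series non-empty numeric vector.
#' @return integer vector with all values in 1..100.
#' @export
scale_to_reward_range <- function(series) {
  if (length(series) == 0L) stop("`series` must be non-empty")
  as.integer(pmin(100, pmax(1, round(series))))
}

#' Generate one accepted reward schedule
#'
#' Draws whole four-jar candidates (one AR(1) series per jar, each re-centred
#' exactly on its target mean, then rounded/clamped to 1-100) and rejects the
#' entire candidate until all acceptance windows pass: per-jar variance 20-40
#' (stable) or 200-400 (variable), every absolute pairwise difference of the
#' per-jar cumulative totals in 500-3000, and the grand total in
#' 14,500-15,000.
#'
#' @param environment "stable" or "variable".
#' @param config a [generator_config()].
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @param set_id identifier recorded on the schedule.
#' @param n_trials trials per jar (75 for the task).
#' @return object of class `reward_schedule`: list with `values` (4 x 75
#'   integer matrix, jars in rows), `environment`, `per_jar_variance`,
#'   `cumulative_totals`, `set_id`, `rejections`.
#' @export
generate_schedule <- function(environment = c("stable", "variable"),
                              config = generator_config(), seed = NULL,
                              set_id = 1L, n_trials = 75L) {
  environment <- match.arg(environment)
  with_seed(seed, {
    rejections <- 0L
    repeat {
      values <- vapply(seq_len(4L), function(i) {
        raw <- simulate_raw_series(n_trials, config, seed = NULL,
                                   environment = environment)
        centred <- raw - mean(raw) + config$target_means[i]
        scale_to_reward_range(centred)
      }, integer(n_trials))
      values <- t(values) # jars in rows
      sched <- new_reward_schedule(values, environment, set_id, rejections)
      report <- validate_schedule(sched)
      if (attr(report, "overall_pass")) return(sched)
      rejections <- rejections + 1L
      if (rejections >= config$max_rejections) {
        first_fail <- report$constraint[!report$pass][1]
        stop(sprintf(
          "schedule generation failed after %d rejections; first violated constraint: %s",
          rejections, first_fail))
      }
    }
  })
}

new_reward_schedule <- function(values, environment, set_id, rejections = 0L) {
  structure(
    list(values = values,
         environment = environment,
         per_jar_variance = apply(values, 1, stats::var),
         cumulative_totals = rowSums(values),
         set_id = set_id,
         rejections = rejections),
    class = "reward_schedule"
  )
}

#' Validate a reward schedule against the acceptance windows
#'
#' Independent re-check of every constraint the generator enforces: the 4 x 75
#' shape and 1-100 range (structural), the per-jar variance window for the
#' schedule's environment, the absolute pairwise cumulative-difference window
#' \[500, 3000\] over all six jar pairs, and the grand-total window
#' \[14,500, 15,000\].
#'
#' @param schedule a `reward_schedule` (or a bare 4 x 75 matrix plus
#'   `environment`).
#' @param environment required only when `schedule` is a bare matrix.
#' @return data.frame with one row per constraint (`constraint`, `measured`,
#'   `lower`, `upper`, `pass`) and attribute `overall_pass`.
#' @export
validate_schedule <- function(schedule, environment = NULL) {
  if (is.matrix(schedule)) {
    if (is.null(environment)) stop("`environment` required for a bare matrix")
    schedule <- new_reward_schedule(schedule, environment, set_id = NA)
  }
  v <- schedule$values
  if (!is.matrix(v) || nrow(v) != 4L || ncol(v) != 75L) {
    stop("malformed schedule: values must be a 4 x 75 matrix")
  }
  if (any(v < 1) || any(v > 100)) {
    stop("malformed schedule: values outside [1, 100]")
  }
  w <- schedule_windows(schedule$environment)
  rows <- list()
  jar_var <- apply(v, 1, stats::var)
  for (i in 1:4) {
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = sprintf("variance_jar%d", i), measured = jar_var[i],
      lower = w$variance[1], upper = w$variance[2],
      pass = jar_var[i] >= w$variance[1] & jar_var[i] <= w$variance[2])
  }
  totals <- rowSums(v)
  pairs <- utils::combn(4, 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- abs(totals[i] - totals[j])
    rows[[length(rows) + 1L]] <- data.frame(
      constraint = sprintf("cumdiff_jar%d_jar%d", i, j), measured = d,
      lower = w$pairwise_diff[1], upper = w$pairwise_diff[2],
      pass = d >= w$pairwise_diff[1] & d <= w$pairwise_diff[2])
  }
  gt <- sum(totals)
  rows[[length(rows) + 1L]] <- data.frame(
    constraint = "grand_total", measured = gt,
    lower = w$grand_total[1], upper = w$grand_total[2],
    pass = gt >= w$grand_total[1] & gt <= w$grand_total[2])
  report <- do.call(rbind, rows)
  attr(report, "overall_pass") <- all(report$pass)
  report
}

#' Generate counterbalanced sets of stable/variable schedule pairs
#'
#' One stable and one variable schedule per set. Within a participant's
#' assignment both Harsh and Not-Harsh blocks of the same environment reuse
#' the identical schedule, so a pair fully determines a participant's four
#' blocks.
#'
#' @param n_sets number of sets (the study used 5).
#' @param seed integer seed.
#' @param config a [generator_config()].
#' @return list of length `n_sets`; each element is
#'   `list(stable = <reward_schedule>, variable = <reward_schedule>)`.
#' @export
generate_study_sets <- function(n_sets = 5L, seed = NULL,
                                config = generator_config()) {
  stopifnot(n_sets >= 1)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      list(stable = generate_schedule("stable", config, seed = NULL, set_id = s),
           variable = generate_schedule("variable", config, seed = NULL, set_id = s))
    })
  })
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat(sprintf("<reward_schedule> set %s, %s environment\n",
              as.character(x$set_id), x$environment))
  cat(sprintf("  per-jar variances: %s\n",
              paste(sprintf("%.1f", x$per_jar_variance), collapse = ", ")))
  cat(sprintf("  cumulative totals: %s (grand total %d)\n",
              paste(x$cumulative_totals, collapse = ", "),
              sum(x$cumulative_totals)))
  cat(sprintf("  rejections before acceptance: %d\n", x$rejections))
  invisible(x)
}

#' Serialize schedules to / from long-format CSV
#'
#' Columns: `set_id`, `environment`, `jar`, `trial`, `value`. Round-trips
#' losslessly.
#'
#' @param sets list of schedule pairs as returned by [generate_study_sets()].
#' @param path CSV file path.
#' @return `write_schedules` returns `path` invisibly; `read_schedules`
#'   returns a list of schedule pairs.
#' @export
write_schedules <- function(sets, path) {
  rows <- lapply(sets, function(pair) {
    lapply(pair, function(s) {
      data.frame(set_id = s$set_id, environment = s$environment,
                 jar = rep(1:4, each = ncol(s$values)),
                 trial = rep(seq_len(ncol(s$values)), times = 4),
                 value = as.integer(t(s$values)))
    })
  })
  df <- do.call(rbind, unlist(rows, recursive = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("set_id", "environment", "jar", "trial", "value")
  if (!all(needed %in% names(df))) {
    stop("schedule CSV must have columns: ", paste(needed, collapse = ", "))
  }
  sets <- list()
  for (s in sort(unique(df$set_id))) {
    pair <- list()
    for (env in c("stable", "variable")) {
      sub <- df[df$set_id == s & df$environment == env, ]
      if (nrow(sub) == 0L) next
      n_trials <- max(sub$trial)
      values <- matrix(NA_integer_, 4, n_trials)
      values[cbind(sub$jar, sub$trial)] <- sub$value
      if (anyNA(values)) stop(sprintf("incomplete schedule for set %s / %s", s, env))
      pair[[env]] <- new_reward_schedule(values, env, s)
    }
    sets[[length(sets) + 1L]] <- pair
  }
  sets
}
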