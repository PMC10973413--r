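# Hierarchical binomial posterior (logit link, participant random effects)
# via MAP + Laplace; returns draws of the population-level proportion.
binomial_hierarchy_draws <- function(k, n, n_draws = 1000L, seed = 1L,
                                     prior_sd_mu = 1.5, prior_sd_tau = 1) {
  J <- length(k)
  X <- matrix(1, J, 1)
  la <- hier_logit_laplace(X, y = k, size = n, pid = seq_len(J), J = J,
                           prior_sd_beta = prior_sd_mu,
                           prior_sd_tau = prior_sd_tau,
                           n_draws = n_draws, seed = seed)
  stats::plogis(la$draws[, 1])
}

#' Optimal-choice proportions against the 0.25 chance reference
#'
#' Per condition cell, fits a hierarchical binomial model (per-participant
#' success counts of choosing the trial-wise argmax jar, participant random
#' intercepts on the logit scale) and reports the population-level posterior
#' proportion with its 95% HPDI and whether the interval excludes chance
#' (0.25 for four jars).
#'
#' @param trial_table canonical trial table.
#' @param schedule_sets list of schedule pairs (indexed by
#'   `schedule_set_id`) used to determine the trial-wise optimal jar.
#' @param n_draws posterior draws per cell.
#' @param seed integer seed.
#' @return data.frame per condition cell: empirical proportion, posterior
#'   mean, HPDI bounds, `excludes_chance`.
#' @export
optimal_choice_summary <- function(trial_table, schedule_sets,
                                   n_draws = 1000L, seed = 1L) {
  opt <- integer(nrow(trial_table))
  for (sid in unique(trial_table$schedule_set_id)) {
    if (sid > length(schedule_sets) || sid < 1) {
      stop("trial table references schedule_set_id ", sid,
           " not present in `schedule_sets`")
    }
    for (env in unique(trial_table$environment)) {
      sel <- trial_table$schedule_set_id == sid & trial_table$environment == env
      if (!any(sel)) next
      opt_jars <- optimal_jar(schedule_sets[[sid]][[env]])
      opt[sel] <- opt_jars[trial_table$trial[sel]]
    }
  }
  is_opt <- as.integer(trial_table$choice == opt)
  cellkey <- interaction(trial_table$environment, trial_table$harshness,
                         trial_table$study_arm, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trial_table)), cellkey), function(idx) {
    sub <- trial_table[idx, ]
    kk <- tapply(is_opt[idx], sub$participant_id, sum)
    nn <- tapply(rep(1L, length(idx)), sub$participant_id, sum)
    draws <- binomial_hierarchy_draws(as.numeric(kk), as.numeric(nn),
                                      n_draws = n_draws,
                                      seed = substream_seed(seed, as.character(cellkey[idx][1])))
    ci <- hpdi(draws)
    data.frame(environment = sub$environment[1], harshness = sub$harshness[1],
               study_arm = sub$study_arm[1],
               prop_empirical = sum(kk) / sum(nn),
               post_mean = mean(draws),
               hpdi_lower = ci[1], hpdi_upper = ci[2],
               excludes_chance = ci[1] > 0.25 | ci[2] < 0.25)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trend of cumulative score over trials
#'
#' Per condition cell, regresses the within-block cumulative collected
#' reward on trial number with participant random intercepts
#' ([lme4::lmer()]), and summarises the slope with a 95% interval from its
#' asymptotic normal approximation. This is a documented approximation of
#' the choice-quality-over-time analysis, not an exact replication (the
#' original outcome definition is unspecified).
#'
#' @param trial_table canonical trial table.
#' @param n_draws draws for the slope interval.
#' @param seed integer seed.
#' @return data.frame per condition cell: `slope`, `lower`, `upper`,
#'   `positive` flag.
#' @export
score_trend <- function(trial_table, n_draws = 2000L, seed = 1L) {
  tt <- trial_table[order(trial_table$participant_id,
                          trial_table$block_position, trial_table$trial), ]
  blockkey <- interaction(tt$participant_id, tt$block_position, drop = TRUE)
  tt$cum_score <- unlist(lapply(split(tt$reward, blockkey), cumsum),
                         use.names = FALSE)
  cellkey <- interaction(tt$environment, tt$harshness, tt$study_arm, drop = TRUE)
  rows <- lapply(split(tt, cellkey), function(sub) {
    est_se <- tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(cum_score ~ trial + (1 | participant_id), data = sub)
      ))
      suppressWarnings(
        c(lme4::fixef(fit)[["trial"]],
          sqrt(as.matrix(stats::vcov(fit))["trial", "trial"]))
      )
    }, error = function(e) {
      # degenerate (e.g. zero-residual) data: plain least squares
      fit <- stats::lm(cum_score ~ trial, data = sub)
      sm <- suppressWarnings(summary(fit))$coefficients
      c(sm["trial", "Estimate"], sm["trial", "Std. Error"])
    })
    est <- est_se[1]
    se <- if (is.finite(est_se[2])) est_se[2] else 0
    draws <- with_seed(substream_seed(seed, as.character(sub$environment[1])),
                       stats::rnorm(n_draws, est, se))
    ci <- if (se > 0) hpdi(draws) else c(lower = est, upper = est)
    data.frame(environment = sub$environment[1], harshness = sub$harshness[1],
               study_arm = sub$study_arm[1], slope = est,
               lower = ci[1], upper = ci[2], positive = ci[1] > 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Perceived-harshness effect from ordinal stress ratings
#'
#' Cumulative probit model of the 1-5 stress ratings with a harsh/not-harsh
#' condition predictor, so the condition effect reads in latent standard
#' deviation units. Reports the effect with a 95% interval and the
#' three-way tally of participants rating Harsh above / equal to / below
#' Not-Harsh.
#'
#' @param ratings data.frame with `participant_id`, `harsh_rating`,
#'   `not_harsh_rating`, each in 1..5.
#' @param n_draws draws for the interval.
#' @param seed integer seed.
#' @return list of class `bj_stress`: `effect`, `interval`, `tally`
#'   (percentages summing to 100), `n`.
#' @export
stress_effect <- function(ratings, n_draws = 2000L, seed = 1L) {
  r <- c(ratings$harsh_rating, ratings$not_harsh_rating)
  if (any(!r %in% 1:5)) stop("ratings must lie in 1..5")
  if (nrow(ratings) < 2L) stop("need >= 2 participants")
  tally <- c(
    harsh_higher = 100 * mean(ratings$harsh_rating > ratings$not_harsh_rating),
    equal = 100 * mean(ratings$harsh_rating == ratings$not_harsh_rating),
    not_harsh_higher = 100 * mean(ratings$harsh_rating < ratings$not_harsh_rating)
  )
  long <- data.frame(
    rating = factor(r, levels = 1:5, ordered = TRUE),
    harsh = rep(c(1, 0), each = nrow(ratings))
  )
  if (length(unique(r)) < 2L) {
    out <- list(effect = 0, interval = c(lower = 0, upper = 0),
                tally = tally, n = nrow(ratings),
                note = "degenerate ratings: no variance in the response")
    return(structure(out, class = "bj_stress"))
  }
  fit <- MASS::polr(rating ~ harsh, data = long, method = "probit", Hess = TRUE)
  est <- unname(stats::coef(fit)["harsh"])
  se <- sqrt(stats::vcov(fit)["harsh", "harsh"])
  draws <- with_seed(seed, stats::rnorm(n_draws, est, se))
  structure(
    list(effect = est, interval = hpdi(draws), tally = tally,
         n = nrow(ratings)),
    class = "bj_stress"
  )
}

#' @export
print.bj_stress <- function(x, ...) {
  cat(sprintf(
    "<bj_stress> harsh - not-harsh effect: %.2f latent SD (95%% interval [%.2f, %.2f])\n",
    x$effect, x$interval[1], x$interval[2]))
  cat(sprintf("  tally: %.0f%% harsh higher, %.0f%% equal, %.0f%% not-harsh higher (n = %d)\n",
              x$tally[1], x$tally[2], x$tally[3], x$n))
  invisible(x)
}
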