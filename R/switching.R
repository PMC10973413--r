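#' Code jar switches from a trial table
#'
#' A switch is 1 when the next choice within the same block differs from the
#' current choice. One record per trial except the block-final trial;
#' `prev_reward` is the reward just obtained on the current trial.
#'
#' @param trial_table canonical trial table (see [write_trial_table()]).
#' @return data.frame of switch records: `participant_id`, `study_arm`,
#'   `environment`, `harshness`, `block_position`, `trial`, `prev_reward`,
#'   `switch`.
#' @export
code_switches <- function(trial_table) {
  key <- interaction(trial_table$participant_id, trial_table$block_position,
                     drop = TRUE)
  out <- lapply(split(trial_table, key), function(b) {
    if (is.unsorted(b$trial, strictly = TRUE)) {
      stop("trial table must be strictly sorted by trial within blocks ",
           "(participant ", b$participant_id[1], ", block ", b$block_position[1], ")")
    }
    if (!all(diff(b$trial) == 1L)) {
      stop("non-contiguous trials for participant ", b$participant_id[1],
           ", block ", b$block_position[1])
    }
    n <- nrow(b)
    if (n < 2L) return(NULL)
    idx <- seq_len(n - 1L)
    data.frame(participant_id = b$participant_id[idx],
               study_arm = b$study_arm[idx],
               environment = b$environment[idx],
               harshness = b$harshness[idx],
               block_position = b$block_position[idx],
               trial = b$trial[idx],
               prev_reward = b$reward[idx],
               switch = as.integer(b$choice[idx + 1L] != b$choice[idx]))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$participant_id, res$block_position, res$trial), ]
  rownames(res) <- NULL
  res
}

#' Classify a switch by the reward that preceded it
#'
#' Elective switching follows high rewards (55-100), responsive switching
#' follows low rewards (0-45); the 46-54 gap is unclassified. The
#' supplementary stricter responsive cutoff (<= 25) is available through
#' `responsive_max`.
#'
#' @param prev_reward numeric vector in \[0, 100\].
#' @param elective_min lower edge of the elective bin.
#' @param responsive_max upper edge of the responsive bin.
#' @return character vector in `{"elective", "responsive", "unclassified"}`.
#' @export
classify_switch_type <- function(prev_reward, elective_min = 55,
                                 responsive_max = 45) {
  if (any(prev_reward < 0 | prev_reward > 100)) {
    stop("`prev_reward` must lie in [0, 100]")
  }
  ifelse(prev_reward >= elective_min, "elective",
         ifelse(prev_reward <= responsive_max, "responsive", "unclassified"))
}

# The nested ladder of fixed-effect structures. Predictors: x = standardized
# previous reward, V = variable environment (1) vs stable (0), H = harsh (1)
# vs not harsh (0), I = no added incentive (1) vs monetary (0).
switch_model_terms <- function(model_id) {
  base <- switch(model_id,
    "1.0" = , "6.0" = "1",
    "1.1" = , "6.1" = "x",
    "1.2" = "x + V + H + x:V + x:H",
    "1.3" = "x + V + H + V:H + x:V + x:H + x:V:H",
    "6.2" = "x + V + H + I + x:V + x:H + x:I",
    "6.3" = "x + V + H + I + V:H + V:I + H:I + x:V + x:H + x:I + x:V:H + x:V:I + x:H:I",
    "6.4" = "x + V + H + I + V:H + V:I + H:I + V:H:I + x:V + x:H + x:I + x:V:H + x:V:I + x:H:I + x:V:H:I",
    stop("unknown model_id: ", model_id)
  )
  stats::as.formula(paste("~", base))
}

switch_random_slope <- function(model_id) {
  model_id %in% c("1.2", "1.3", "6.2", "6.3", "6.4")
}

# Predictor columns for the ladder from coded switch records.
switch_design_data <- function(records, reward_center, reward_scale) {
  data.frame(
    x = (records$prev_reward - reward_center) / reward_scale,
    V = as.numeric(records$environment == "variable"),
    H = as.numeric(records$harshness == "harsh"),
    I = as.numeric(records$study_arm == "none")
  )
}

#' Fit one hierarchical Bayesian logistic switching model
#'
#' Bernoulli logistic regression of the switch indicator with the ladder's
#' fixed-effect structure, per-participant random intercepts (and random
#' standardized-reward slopes from model x.2 upward), weakly informative
#' priors (normal on coefficients, half-normal on random-effect SDs), fitted
#' by MAP with a Laplace (quadratic) posterior approximation. Previous reward
#' is standardized internally; [coef.bj_switch_fit()] can report either
#' scale.
#'
#' @param records switch records from [code_switches()].
#' @param model_id one of "1.0", "1.1", "1.2", "1.3" (single-arm ladder) or
#'   "6.0".."6.4" (two-arm ladder with the incentive predictor).
#' @param prior_sd_beta SD of the normal prior on fixed effects.
#' @param prior_sd_tau scale of the half-normal prior on random-effect SDs.
#' @param n_draws posterior draws from the Gaussian approximation.
#' @param seed seed for the posterior draws.
#' @return object of class `bj_switch_fit`.
#' @export
fit_switch_model <- function(records, model_id = "1.3", prior_sd_beta = 1.5,
                             prior_sd_tau = 1, n_draws = 1000L, seed = 1L) {
  pid_levels <- sort(unique(records$participant_id))
  if (length(pid_levels) < 2L) stop("need >= 2 participants")
  pid <- match(records$participant_id, pid_levels)
  J <- length(pid_levels)
  m <- mean(records$prev_reward)
  s <- stats::sd(records$prev_reward)
  if (s == 0) s <- 1
  dd <- switch_design_data(records, m, s)
  X <- stats::model.matrix(switch_model_terms(model_id), dd)
  y <- records$switch
  n <- length(y)
  p <- ncol(X)
  q <- if (switch_random_slope(model_id)) 2L else 1L
  xv <- dd$x

  la <- hier_logit_laplace(X, y, size = rep(1, n), pid = pid, J = J,
                           xv = if (q == 2L) xv else NULL,
                           prior_sd_beta = prior_sd_beta,
                           prior_sd_tau = prior_sd_tau,
                           n_draws = n_draws, seed = seed)
  tau_cols <- matrix(rep(log(la$tau), each = n_draws), n_draws)
  draws <- cbind(la$draws, tau_cols)
  colnames(draws) <- c(paste0("b_", colnames(X)),
                       paste0("u", rep(seq_len(q), each = J),
                              "_", rep(pid_levels, q)),
                       paste0("log_tau_", seq_len(q)))
  structure(
    list(model_id = model_id, draws = draws,
         mode = c(la$mode, log(la$tau)),
         terms = colnames(X), n_fixed = p, n_participants = J, q = q,
         pid_levels = pid_levels, pid = pid, X = X, y = y, xv = xv,
         reward_center = m, reward_scale = s,
         priors = list(sd_beta = prior_sd_beta, sd_tau = prior_sd_tau),
         diagnostics = list(converged = la$converged,
                            grad_norm = la$grad_norm),
         n_obs = n),
    class = "bj_switch_fit"
  )
}

#' @export
print.bj_switch_fit <- function(x, ...) {
  cat(sprintf("<bj_switch_fit> model %s: %d obs, %d participants, %d fixed effects, q=%d random terms\n",
              x$model_id, x$n_obs, x$n_participants, x$n_fixed, x$q))
  if (!x$diagnostics$converged) cat("  WARNING: optimizer did not report convergence\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Fixed-effect posterior means of a switching fit
#'
#' @param object a `bj_switch_fit`.
#' @param scale `"standardized"` (internal reward standardization) or
#'   `"raw"` (per reward unit on the 0-100 scale).
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.bj_switch_fit <- function(object, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  b <- colMeans(object$draws[, seq_len(object$n_fixed), drop = FALSE])
  names(b) <- object$terms
  if (scale == "raw") {
    m <- object$reward_center; s <- object$reward_scale
    raw <- b
    has_x <- grepl("(^|:)x($|:)", object$terms)
    # each x-bearing term scales by 1/s; its x-free partner absorbs -m/s
    for (i in which(has_x)) {
      term <- object$terms[i]
      parts <- setdiff(strsplit(term, ":")[[1]], "x")
      partner <- if (length(parts) == 0L) "(Intercept)" else paste(parts, collapse = ":")
      raw[i] <- b[i] / s
      if (partner %in% names(raw)) raw[partner] <- raw[partner] - b[i] * m / s
    }
    b <- raw
  }
  b
}

#' @export
summary.bj_switch_fit <- function(object, mass = 0.95, ...) {
  bd <- object$draws[, seq_len(object$n_fixed), drop = FALSE]
  est <- colMeans(bd)
  ints <- t(apply(bd, 2, hpdi, mass = mass))
  tau <- exp(colMeans(object$draws[, ncol(object$draws) - seq_len(object$q) + 1L,
                                   drop = FALSE]))[object$q:1]
  out <- data.frame(term = object$terms, mean = est,
                    hpdi_lower = ints[, 1], hpdi_upper = ints[, 2])
  rownames(out) <- NULL
  structure(list(model_id = object$model_id, fixed = out,
                 random_sd = stats::setNames(tau, paste0("tau_", seq_len(object$q))),
                 reward_center = object$reward_center,
                 reward_scale = object$reward_scale,
                 diagnostics = object$diagnostics),
            class = "summary.bj_switch_fit")
}

#' @export
print.summary.bj_switch_fit <- function(x, ...) {
  cat(sprintf("Model %s (reward standardized: centre %.2f, scale %.2f)\n",
              x$model_id, x$reward_center, x$reward_scale))
  print(transform(x$fixed, mean = round(mean, 3),
                  hpdi_lower = round(hpdi_lower, 3),
                  hpdi_upper = round(hpdi_upper, 3)))
  cat("Random-effect SDs:", paste(sprintf("%.3f", x$random_sd), collapse = ", "), "\n")
  invisible(x)
}

#' WAIC of a fitted switching model
#'
#' Pointwise log-likelihoods are computed for every posterior draw over the
#' fitted records and summarised by [waic_from_loglik()].
#'
#' @param fit a `bj_switch_fit`.
#' @param chunk draws per block when building the pointwise matrix (memory
#'   control only).
#' @return list: `model_id`, `waic`, `p_waic`, `se`.
#' @export
compute_waic <- function(fit, chunk = 200L) {
  S <- nrow(fit$draws)
  p <- fit$n_fixed
  J <- fit$n_participants
  q <- fit$q
  ll <- matrix(NA_real_, S, fit$n_obs)
  for (start in seq(1L, S, by = chunk)) {
    idx <- start:min(S, start + chunk - 1L)
    beta <- fit$draws[idx, seq_len(p), drop = FALSE]
    eta <- fit$X %*% t(beta)
    u1 <- fit$draws[idx, p + seq_len(J), drop = FALSE]
    eta <- eta + t(u1)[fit$pid, , drop = FALSE]
    if (q == 2L) {
      u2 <- fit$draws[idx, p + J + seq_len(J), drop = FALSE]
      eta <- eta + t(u2)[fit$pid, , drop = FALSE] * fit$xv
    }
    ll[idx, ] <- t(fit$y * eta - log1pexp(eta))
  }
  w <- waic_from_loglik(ll)
  list(model_id = fit$model_id, waic = w$waic, p_waic = w$p_waic, se = w$se)
}

#' Compare a ladder of switching models by WAIC
#'
#' @param fits list of `bj_switch_fit` objects.
#' @return data.frame sorted by WAIC with `model_id`, `waic`, `p_waic`, `se`,
#'   `d_waic` (difference to the best model); attribute `best_model`.
#' @export
waic_table <- function(fits) {
  rows <- do.call(rbind, lapply(fits, function(f) {
    w <- compute_waic(f)
    data.frame(model_id = w$model_id, waic = w$waic, p_waic = w$p_waic,
               se = w$se)
  }))
  rows <- rows[order(rows$waic), ]
  rows$d_waic <- rows$waic - rows$waic[1]
  rownames(rows) <- NULL
  attr(rows, "best_model") <- rows$model_id[1]
  rows
}

#' Posterior contrast of switch probability between two condition cells
#'
#' For every posterior draw, the population-level predicted switch
#' probability (random effects at their mean of zero) is averaged uniformly
#' over the bin's integer reward grid for each condition cell; the contrast
#' is the per-draw difference cell A minus cell B, summarised by its mean and
#' 95% HPDI.
#'
#' @param fit a `bj_switch_fit`.
#' @param cell_a,cell_b named lists giving the condition cells, e.g.
#'   `list(V = 1, H = 0)` (and `I` for the two-arm ladder).
#' @param bin `"elective"` (rewards 55-100), `"responsive"` (0-45), or
#'   `"full"` (0-100).
#' @param mass HPDI mass.
#' @param label optional contrast label.
#' @return object of class `bj_contrast`: list with `label`, `mean`,
#'   `hpdi` and the contrast `draws`.
#' @export
posterior_switch_contrast <- function(fit, cell_a, cell_b,
                                      bin = c("elective", "responsive", "full"),
                                      mass = 0.95, label = NULL) {
  bin <- match.arg(bin)
  grid <- switch(bin, elective = 55:100, responsive = 0:45, full = 0:100)
  if (length(grid) == 0L) stop("empty reward bin")
  pr <- function(cell) {
    dd <- data.frame(
      x = (grid - fit$reward_center) / fit$reward_scale,
      V = cell$V %||% 0, H = cell$H %||% 0, I = cell$I %||% 0
    )
    M <- stats::model.matrix(switch_model_terms(fit$model_id), dd)
    beta <- fit$draws[, seq_len(fit$n_fixed), drop = FALSE]
    colMeans(stats::plogis(M %*% t(beta)))     # per-draw bin-average probability
  }
  d <- pr(cell_a) - pr(cell_b)
  structure(
    list(label = label %||% sprintf("%s bin: cellA - cellB", bin),
         bin = bin, mean = mean(d), hpdi = hpdi(d, mass), draws = d),
    class = "bj_contrast"
  )
}

#' @export
print.bj_contrast <- function(x, ...) {
  cat(sprintf("<bj_contrast> %s\n  mean %.4f, 95%% HPDI [%.4f, %.4f]\n",
              x$label, x$mean, x$hpdi[1], x$hpdi[2]))
  invisible(x)
}

#' Restrict a trial table to participants who found Harsh more stressful
#'
#' @param trial_table canonical trial table.
#' @param ratings stress ratings as from [simulate_stress_ratings()].
#' @return subset of `trial_table`.
#' @export
filter_by_stress <- function(trial_table, ratings) {
  missing <- setdiff(unique(trial_table$participant_id), ratings$participant_id)
  if (length(missing) > 0L) {
    stop("missing stress ratings for participants: ",
         paste(missing, collapse = ", "))
  }
  keep <- ratings$participant_id[ratings$harsh_rating > ratings$not_harsh_rating]
  trial_table[trial_table$participant_id %in% keep, , drop = FALSE]
}

#' Simulate switch records directly from the ladder's generative structure
#'
#' Draws Bernoulli switch indicators from a hierarchical logistic model with
#' the full variability x harshness x reward interaction structure (the
#' "1.3" design), with per-participant random intercepts and reward slopes.
#' Coefficients are specified on the standardized-reward scale
#' (`x = (reward - 50) / 29`). The defaults encode elective switching
#' suppressed by harshness in the variable environment, i.e. a positive
#' Variable NotHarsh - Harsh elective contrast.
#'
#' @param n_agents number of participants.
#' @param beta named coefficients for the 1.3 design (names as in
#'   [fit_switch_model()] terms).
#' @param intercept_sd,slope_sd random-effect SDs.
#' @param trials_per_cell switch records per condition cell per participant.
#' @param seed integer seed.
#' @return switch-records data.frame compatible with [fit_switch_model()].
#' @export
simulate_switch_records <- function(n_agents = 100L,
                                    beta = c("(Intercept)" = -0.4, x = -1.2,
                                             V = 0.8, H = 0, "V:H" = -0.3,
                                             "x:V" = 0.8, "x:H" = 0,
                                             "x:V:H" = -0.8),
                                    intercept_sd = 0.5, slope_sd = 0.3,
                                    trials_per_cell = 74L, seed = 1L) {
  with_seed(seed, {
    u0 <- stats::rnorm(n_agents, 0, intercept_sd)
    u1 <- stats::rnorm(n_agents, 0, slope_sd)
    cells <- expand.grid(environment = c("stable", "variable"),
                         harshness = c("not_harsh", "harsh"),
                         stringsAsFactors = FALSE)
    rows <- lapply(seq_len(n_agents), function(j) {
      do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
        reward <- sample(0:100, trials_per_cell, replace = TRUE)
        dd <- data.frame(
          x = (reward - 50) / 29,
          V = as.numeric(cells$environment[ci] == "variable"),
          H = as.numeric(cells$harshness[ci] == "harsh"),
          I = 1
        )
        M <- stats::model.matrix(switch_model_terms("1.3"), dd)
        eta <- as.vector(M %*% beta[colnames(M)]) + u0[j] + u1[j] * dd$x
        data.frame(participant_id = j, study_arm = "none",
                   environment = cells$environment[ci],
                   harshness = cells$harshness[ci],
                   block_position = ci, trial = seq_len(trials_per_cell),
                   prev_reward = reward,
                   switch = stats::rbinom(trials_per_cell, 1, stats::plogis(eta)))
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
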