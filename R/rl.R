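#' Log-likelihood of one agent's choice sequence under the RL model
#'
#' Attractions start at `init_attraction` (default 1: optimistic
#' initialization at the normalized payoff maximum, matching the cohort
#' generator) at every block start and follow the
#' Rescorla-Wagner update on the chosen jar with payoffs normalized by
#' `payoff_scale`; each observed choice contributes the log softmax
#' probability computed from the attractions *before* that trial's update.
#'
#' @param rows one agent's trial rows, time-ordered within blocks, with
#'   columns `choice`, `reward`, and a block identifier (`block_position`, or
#'   all rows treated as one block when absent).
#' @param phi learning rate(s): a scalar, or a named vector indexed by
#'   `environment.harshness` condition cells.
#' @param lambda elective-exploration weight(s), same shapes as `phi`.
#' @param payoff_scale divisor normalizing rewards (100 maps 1-100 into
#'   (0, 1\]).
#' @param init_attraction starting attraction for every jar.
#' @param n_jars number of jars.
#' @return total log-likelihood (scalar).
#' @export
sequence_loglik <- function(rows, phi, lambda, payoff_scale = 100,
                            init_attraction = 1, n_jars = 4L) {
  blocks <- if ("block_position" %in% names(rows)) {
    split(rows, rows$block_position)
  } else list(rows)
  total <- 0
  for (b in blocks) {
    if ("trial" %in% names(b)) {
      if (is.unsorted(b$trial, strictly = TRUE) || !all(diff(b$trial) == 1L)) {
        stop("trials must be contiguous and strictly increasing within a block")
      }
    }
    cell <- if (all(c("environment", "harshness") %in% names(b))) {
      paste(b$environment[1], b$harshness[1], sep = ".")
    } else NULL
    ph <- if (length(phi) > 1L || !is.null(names(phi))) phi[[cell]] else phi
    lm <- if (length(lambda) > 1L || !is.null(names(lambda))) lambda[[cell]] else lambda
    A <- rep(init_attraction, n_jars)
    for (t in seq_len(nrow(b))) {
      p <- softmax_prob(A, lm)
      total <- total + log(p[b$choice[t]])
      A <- rw_update(A, b$choice[t], b$reward[t] / payoff_scale, ph)
    }
  }
  total
}

# Arrange a trial table into agent-cell matrices for the vectorized
# hierarchical likelihood. A "cell" is one environment x harshness (x arm)
# combination; each participant contributes one 75-trial block per cell.
rl_prepare <- function(trial_table, payoff_scale = 100) {
  tt <- trial_table[order(trial_table$participant_id,
                          trial_table$block_position, trial_table$trial), ]
  multi_arm <- length(unique(tt$study_arm)) > 1L
  cell_of <- function(env, hl, arm) {
    if (multi_arm) paste(env, hl, arm, sep = ".") else paste(env, hl, sep = ".")
  }
  key <- interaction(tt$participant_id, tt$environment, tt$harshness, drop = TRUE)
  groups <- split(tt, key)
  Tn <- unique(vapply(groups, nrow, integer(1)))
  if (length(Tn) != 1L) stop("all agent-cells must have the same number of trials")
  ac_df <- do.call(rbind, lapply(groups, function(g) {
    data.frame(agent_id = g$participant_id[1], environment = g$environment[1],
               harshness = g$harshness[1], study_arm = g$study_arm[1],
               cell = cell_of(g$environment[1], g$harshness[1], g$study_arm[1]))
  }))
  rownames(ac_df) <- NULL
  ord <- order(ac_df$agent_id, ac_df$cell)
  ac_df <- ac_df[ord, ]
  groups <- groups[ord]
  choices <- t(vapply(groups, function(g) g$choice, integer(Tn)))
  rewards <- t(vapply(groups, function(g) g$reward, numeric(Tn))) / payoff_scale
  cells <- sort(unique(ac_df$cell))
  list(ac_df = ac_df, choices = choices, rewards = rewards,
       cells = cells, cell_idx = match(ac_df$cell, cells), T = Tn)
}

# Vectorized log-likelihood (and, optionally, analytic gradient wrt the
# natural-scale phi and lambda) across all agent-cells simultaneously.
rl_loglik_all <- function(prep, phi, lambda, grad = FALSE,
                          init_attraction = 1) {
  AC <- nrow(prep$choices)
  nj <- 4L
  A <- matrix(init_attraction, AC, nj)
  ll <- numeric(AC)
  rows <- seq_len(AC)
  if (grad) {
    D <- matrix(0, AC, nj)  # dA/dphi
    g_phi <- numeric(AC)
    g_lam <- numeric(AC)
  }
  for (t in seq_len(prep$T)) {
    ch <- prep$choices[, t]
    idx <- cbind(rows, ch)
    z <- lambda * A
    zmax <- z[cbind(rows, max.col(z, ties.method = "first"))]
    ez <- exp(z - zmax)
    sez <- rowSums(ez)
    ll <- ll + z[idx] - zmax - log(sez)
    if (grad) {
      P <- ez / sez
      g_lam <- g_lam + A[idx] - rowSums(P * A)
      g_phi <- g_phi + lambda * (D[idx] - rowSums(P * D))
      D[idx] <- (1 - phi) * D[idx] + (prep$rewards[, t] - A[idx])
    }
    A[idx] <- (1 - phi) * A[idx] + phi * prep$rewards[, t]
  }
  if (grad) list(ll = ll, g_phi = g_phi, g_lam = g_lam) else list(ll = ll)
}

#' Hierarchical Bayesian fit of the Rescorla-Wagner/softmax model
#'
#' Condition-indexed learning rates (logit link) and elective-exploration
#' weights (log link) per participant, partially pooled through per-cell
#' population means and SDs (normal(0, 1) hyperpriors on the means,
#' half-normal(1) on the SDs). Fitted by MAP with a Laplace (quadratic)
#' posterior approximation using analytic likelihood gradients. When the
#' trial table holds both incentive arms, cells are environment x harshness
#' x arm, which estimates the arms separately.
#'
#' @param trial_table canonical trial table.
#' @param n_draws posterior draws from the Gaussian approximation.
#' @param seed seed for the posterior draws.
#' @param payoff_scale payoff normalization divisor.
#' @param prior_mean_sd SD of the normal hyperprior on population means.
#' @param prior_tau_sd scale of the half-normal hyperprior on population SDs.
#' @param init_attraction starting attraction at each block start (must
#'   match the generative setting; the package-wide default is optimistic
#'   initialization at 1).
#' @return object of class `bj_rl_fit`.
#' @export
fit_rl <- function(trial_table, n_draws = 1000L, seed = 1L,
                   payoff_scale = 100, prior_mean_sd = 1, prior_tau_sd = 1,
                   init_attraction = 1) {
  if (length(unique(trial_table$participant_id)) < 2L) {
    stop("need >= 2 participants")
  }
  prep <- rl_prepare(trial_table, payoff_scale)
  AC <- nrow(prep$ac_df)
  C <- length(prep$cells)
  ci <- prep$cell_idx
  # theta: [logit_phi (AC)] [log_lambda (AC)] [mu_phi (C)] [mu_lam (C)]
  #        [log_sd_phi (C)] [log_sd_lam (C)]
  unpack <- function(theta) {
    list(lp = theta[seq_len(AC)],
         llam = theta[AC + seq_len(AC)],
         mu_p = theta[2 * AC + seq_len(C)],
         mu_l = theta[2 * AC + C + seq_len(C)],
         sd_p = exp(theta[2 * AC + 2 * C + seq_len(C)]),
         sd_l = exp(theta[2 * AC + 3 * C + seq_len(C)]))
  }
  group_prior_lp <- function(x, mu, sd) {
    -sum((x - mu[ci])^2 / (2 * sd[ci]^2)) - sum(tabulate(ci, C) * log(sd))
  }
  logpost <- function(theta) {
    p <- unpack(theta)
    phi <- stats::plogis(p$lp)
    lam <- exp(p$llam)
    ll <- sum(rl_loglik_all(prep, phi, lam,
                            init_attraction = init_attraction)$ll)
    lp <- group_prior_lp(p$lp, p$mu_p, p$sd_p) +
      group_prior_lp(p$llam, p$mu_l, p$sd_l) -
      sum(p$mu_p^2 + p$mu_l^2) / (2 * prior_mean_sd^2) -
      sum(p$sd_p^2 + p$sd_l^2) / (2 * prior_tau_sd^2) +
      sum(log(p$sd_p)) + sum(log(p$sd_l))
    ll + lp
  }
  grad <- function(theta) {
    p <- unpack(theta)
    phi <- stats::plogis(p$lp)
    lam <- exp(p$llam)
    g <- rl_loglik_all(prep, phi, lam, grad = TRUE,
                       init_attraction = init_attraction)
    g_lp <- g$g_phi * phi * (1 - phi) - (p$lp - p$mu_p[ci]) / p$sd_p[ci]^2
    g_llam <- g$g_lam * lam - (p$llam - p$mu_l[ci]) / p$sd_l[ci]^2
    g_mu_p <- as.vector(rowsum((p$lp - p$mu_p[ci]) / p$sd_p[ci]^2, ci)) -
      p$mu_p / prior_mean_sd^2
    g_mu_l <- as.vector(rowsum((p$llam - p$mu_l[ci]) / p$sd_l[ci]^2, ci)) -
      p$mu_l / prior_mean_sd^2
    nC <- tabulate(ci, C)
    g_lsd_p <- as.vector(rowsum((p$lp - p$mu_p[ci])^2 / p$sd_p[ci]^2, ci)) -
      nC - p$sd_p^2 / prior_tau_sd^2 + 1
    g_lsd_l <- as.vector(rowsum((p$llam - p$mu_l[ci])^2 / p$sd_l[ci]^2, ci)) -
      nC - p$sd_l^2 / prior_tau_sd^2 + 1
    c(g_lp, g_llam, g_mu_p, g_mu_l, g_lsd_p, g_lsd_l)
  }
  # The joint posterior is extremely stiff (greedy sequences leave lambda
  # only one-sidedly identified), so the MAP is found by coordinate ascent:
  # batched damped-Newton updates of the per-agent-cell parameters (their
  # likelihood separates across agent-cells, so 2x2 blocks are exact)
  # alternate with closed-form/1-D updates of the population parameters.
  nCc <- tabulate(ci, C)
  x_p <- rep(0, AC); x_l <- rep(2, AC)
  mu_p <- rep(0, C); mu_l <- rep(2, C)
  sd_p <- rep(0.5, C); sd_l <- rep(0.5, C)
  pack <- function() c(x_p, x_l, mu_p, mu_l, log(sd_p), log(sd_l))
  unit_ll <- function(xp, xl) {
    rl_loglik_all(prep, stats::plogis(xp), exp(xl),
                  init_attraction = init_attraction)$ll -
      (xp - mu_p[ci])^2 / (2 * sd_p[ci]^2) -
      (xl - mu_l[ci])^2 / (2 * sd_l[ci]^2)
  }
  unit_grad <- function(xp, xl) {
    phi <- stats::plogis(xp)
    g <- rl_loglik_all(prep, phi, exp(xl), grad = TRUE,
                       init_attraction = init_attraction)
    cbind(g$g_phi * phi * (1 - phi) - (xp - mu_p[ci]) / sd_p[ci]^2,
          g$g_lam * exp(xl) - (xl - mu_l[ci]) / sd_l[ci]^2)
  }
  unit_blocks <- function(xp, xl) {
    h <- 1e-4
    dp <- (unit_grad(xp + h, xl) - unit_grad(xp - h, xl)) / (2 * h)
    dl <- (unit_grad(xp, xl + h) - unit_grad(xp, xl - h)) / (2 * h)
    list(a11 = -dp[, 1], a22 = -dl[, 2], a12 = -(dp[, 2] + dl[, 1]) / 2)
  }
  prev <- -Inf
  for (sweep in seq_len(60L)) {
    for (newton in seq_len(4L)) {
      g <- unit_grad(x_p, x_l)
      if (max(abs(g)) < 1e-7) break
      bl <- unit_blocks(x_p, x_l)
      a11 <- bl$a11; a22 <- bl$a22; a12 <- bl$a12
      # floor the smaller eigenvalue of each 2x2 block at 0.05
      disc <- sqrt(pmax(0, (a11 - a22)^2 / 4 + a12^2))
      add <- pmax(0, 0.05 - ((a11 + a22) / 2 - disc))
      a11 <- a11 + add; a22 <- a22 + add
      dt <- a11 * a22 - a12^2
      s_p <- (a22 * g[, 1] - a12 * g[, 2]) / dt
      s_l <- (a11 * g[, 2] - a12 * g[, 1]) / dt
      f0 <- unit_ll(x_p, x_l)
      st <- rep(1, AC)
      f1 <- f0
      for (bt in seq_len(14L)) {
        f1 <- unit_ll(x_p + st * s_p, x_l + st * s_l)
        bad <- !is.finite(f1) | f1 < f0
        if (!any(bad)) break
        st[bad] <- st[bad] / 2
      }
      ok <- is.finite(f1) & f1 >= f0
      x_p[ok] <- x_p[ok] + st[ok] * s_p[ok]
      x_l[ok] <- x_l[ok] + st[ok] * s_l[ok]
    }
    # penalized EM update of the population SDs: the per-unit Laplace
    # variances enter the sufficient statistic, which prevents the
    # hierarchical funnel collapse a joint mode would suffer
    bl <- unit_blocks(x_p, x_l)
    dt <- pmax(bl$a11 * bl$a22 - bl$a12^2, 1e-8)
    v_p <- pmax(bl$a22 / dt, 0)
    v_l <- pmax(bl$a11 / dt, 0)
    for (c in seq_len(C)) {
      idx <- ci == c
      mu_p[c] <- (sum(x_p[idx]) / sd_p[c]^2) /
        (nCc[c] / sd_p[c]^2 + 1 / prior_mean_sd^2)
      mu_l[c] <- (sum(x_l[idx]) / sd_l[c]^2) /
        (nCc[c] / sd_l[c]^2 + 1 / prior_mean_sd^2)
      ssq_p <- sum((x_p[idx] - mu_p[c])^2) + sum(v_p[idx])
      ssq_l <- sum((x_l[idx] - mu_l[c])^2) + sum(v_l[idx])
      sdobj <- function(ssq) function(ls) {
        ssq / (2 * exp(2 * ls)) + nCc[c] * ls +
          exp(2 * ls) / (2 * prior_tau_sd^2) - ls
      }
      sd_p[c] <- exp(stats::nlminb(log(sd_p[c]), sdobj(ssq_p),
                                   lower = log(0.05), upper = log(5))$par)
      sd_l[c] <- exp(stats::nlminb(log(sd_l[c]), sdobj(ssq_l),
                                   lower = log(0.05), upper = log(5))$par)
    }
    cur <- logpost(pack())
    if (is.finite(cur) && is.finite(prev) && abs(cur - prev) < 1e-5) break
    prev <- cur
  }
  # Laplace approximation over participant parameters and population means
  # at the converged population SDs (empirical-Bayes: SD uncertainty is not
  # propagated)
  theta_xm <- c(x_p, x_l, mu_p, mu_l)
  logpost_xm <- function(th) {
    logpost(c(th, log(sd_p), log(sd_l)))
  }
  grad_xm <- function(th) {
    grad(c(th, log(sd_p), log(sd_l)))[seq_len(2 * AC + 2 * C)]
  }
  init <- pack()
  names(init) <- c(paste0("logit_phi.", prep$ac_df$agent_id, ".", prep$ac_df$cell),
                   paste0("log_lambda.", prep$ac_df$agent_id, ".", prep$ac_df$cell),
                   paste0("mu_phi.", prep$cells), paste0("mu_lambda.", prep$cells),
                   paste0("log_sd_phi.", prep$cells),
                   paste0("log_sd_lambda.", prep$cells))
  names(theta_xm) <- names(init)[seq_len(2 * AC + 2 * C)]
  la <- laplace_approx(logpost_xm, grad_xm, theta_xm, n_draws = n_draws,
                       seed = seed, optimize = FALSE)
  sd_cols <- matrix(rep(c(log(sd_p), log(sd_l)), each = n_draws), n_draws)
  colnames(sd_cols) <- names(init)[2 * AC + 2 * C + seq_len(2 * C)]
  la$draws <- cbind(la$draws, sd_cols)
  structure(
    list(draws = la$draws, mode = la$mode, ac_df = prep$ac_df,
         cells = prep$cells, n_agent_cells = AC,
         payoff_scale = payoff_scale,
         diagnostics = list(converged = la$converged,
                            grad_norm = la$grad_norm,
                            hessian_jittered = la$jittered)),
    class = "bj_rl_fit"
  )
}

#' @export
print.bj_rl_fit <- function(x, ...) {
  cat(sprintf("<bj_rl_fit> %d agent-cells over %d condition cells\n",
              x$n_agent_cells, length(x$cells)))
  if (!x$diagnostics$converged) cat("  WARNING: optimizer did not report convergence\n")
  s <- summary(x)
  print(transform(s, phi_mean = round(phi_mean, 3), lambda_mean = round(lambda_mean, 3),
                  phi_sd_link = round(phi_sd_link, 3), lambda_sd_link = round(lambda_sd_link, 3)))
  invisible(x)
}

#' @export
summary.bj_rl_fit <- function(object, ...) {
  d <- object$draws
  cells <- object$cells
  data.frame(
    cell = cells,
    phi_mean = vapply(cells, function(cl)
      mean(stats::plogis(d[, paste0("mu_phi.", cl)])), numeric(1)),
    lambda_mean = vapply(cells, function(cl)
      mean(exp(d[, paste0("mu_lambda.", cl)])), numeric(1)),
    phi_sd_link = vapply(cells, function(cl)
      mean(exp(d[, paste0("log_sd_phi.", cl)])), numeric(1)),
    lambda_sd_link = vapply(cells, function(cl)
      mean(exp(d[, paste0("log_sd_lambda.", cl)])), numeric(1)),
    row.names = NULL
  )
}

#' Per-agent-cell posterior summaries on the natural scale
#'
#' @param object a `bj_rl_fit`.
#' @param mass interval mass for the per-parameter HPDIs.
#' @param ... unused.
#' @return data.frame: agent/cell identifiers, posterior mean and HPDI of
#'   `phi` and `lambda`.
#' @export
coef.bj_rl_fit <- function(object, mass = 0.95, ...) {
  ac <- object$ac_df
  out <- ac
  n <- nrow(ac)
  phi_draws <- stats::plogis(object$draws[, seq_len(n), drop = FALSE])
  lam_draws <- exp(object$draws[, n + seq_len(n), drop = FALSE])
  out$phi <- colMeans(phi_draws)
  pi_ <- apply(phi_draws, 2, hpdi, mass = mass)
  out$phi_lower <- pi_[1, ]; out$phi_upper <- pi_[2, ]
  out$lambda <- colMeans(lam_draws)
  li <- apply(lam_draws, 2, hpdi, mass = mass)
  out$lambda_lower <- li[1, ]; out$lambda_upper <- li[2, ]
  out
}

#' Posterior contrast of population RL parameters between two condition cells
#'
#' Per-draw difference of the population-level means, cell A minus cell B,
#' reported on the link scale (logit for `phi`, log for `lambda`) and on the
#' natural back-transformed scale.
#'
#' @param fit a `bj_rl_fit`.
#' @param cell_a,cell_b condition-cell labels (e.g. `"variable.harsh"`).
#' @param parameter `"phi"` or `"lambda"`.
#' @param mass HPDI mass.
#' @return list of class `bj_rl_contrast` with `link` and `natural`
#'   components, each carrying `mean`, `hpdi`, `draws`.
#' @export
contrast_rl_parameters <- function(fit, cell_a, cell_b,
                                   parameter = c("phi", "lambda"),
                                   mass = 0.95) {
  parameter <- match.arg(parameter)
  if (!all(c(cell_a, cell_b) %in% fit$cells)) {
    stop("unknown condition cell; available: ", paste(fit$cells, collapse = ", "))
  }
  pref <- if (parameter == "phi") "mu_phi." else "mu_lambda."
  inv <- if (parameter == "phi") stats::plogis else exp
  a <- fit$draws[, paste0(pref, cell_a)]
  b <- fit$draws[, paste0(pref, cell_b)]
  link_d <- a - b
  nat_d <- inv(a) - inv(b)
  structure(
    list(label = sprintf("%s: %s - %s", parameter, cell_a, cell_b),
         parameter = parameter,
         link = list(mean = mean(link_d), hpdi = hpdi(link_d, mass), draws = link_d),
         natural = list(mean = mean(nat_d), hpdi = hpdi(nat_d, mass), draws = nat_d)),
    class = "bj_rl_contrast"
  )
}

#' @export
print.bj_rl_contrast <- function(x, ...) {
  cat(sprintf("<bj_rl_contrast> %s\n", x$label))
  cat(sprintf("  link scale:    mean %.4f, 95%% HPDI [%.4f, %.4f]\n",
              x$link$mean, x$link$hpdi[1], x$link$hpdi[2]))
  cat(sprintf("  natural scale: mean %.4f, 95%% HPDI [%.4f, %.4f]\n",
              x$natural$mean, x$natural$hpdi[1], x$natural$hpdi[2]))
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares ground-truth agent parameters with their posterior summaries:
#' Pearson and Spearman correlation, mean bias, RMSE, and 95%-interval
#' coverage, per parameter overall and per condition cell.
#'
#' @param truth ground-truth data.frame as from [draw_agent_params()].
#' @param fit a `bj_rl_fit` on data simulated from that truth.
#' @param file optional path prefix; writes `<file>.csv` (merged per-agent
#'   table) and `<file>.md` (summary).
#' @return list of class `bj_recovery`: `merged` (per agent-cell), `summary`
#'   (metrics per parameter), `by_cell`.
#' @export
recovery_report <- function(truth, fit, file = NULL) {
  est <- coef(fit)
  merged <- merge(truth, est,
                  by = c("agent_id", "environment", "harshness"),
                  suffixes = c("_true", "_est"))
  if (nrow(merged) == 0L) stop("no overlapping agent ids between truth and fit")
  metrics <- function(tr, mn, lo, hi) {
    data.frame(pearson = stats::cor(tr, mn),
               spearman = stats::cor(tr, mn, method = "spearman"),
               bias = mean(mn - tr),
               rmse = sqrt(mean((mn - tr)^2)),
               coverage = mean(tr >= lo & tr <= hi))
  }
  summ <- rbind(
    cbind(parameter = "phi",
          metrics(merged$phi_true, merged$phi_est, merged$phi_lower, merged$phi_upper)),
    cbind(parameter = "lambda",
          metrics(merged$lambda_true, merged$lambda_est,
                  merged$lambda_lower, merged$lambda_upper))
  )
  by_cell <- do.call(rbind, lapply(split(merged, merged$cell), function(g) {
    rbind(cbind(cell = g$cell[1], parameter = "phi",
                metrics(g$phi_true, g$phi_est, g$phi_lower, g$phi_upper)),
          cbind(cell = g$cell[1], parameter = "lambda",
                metrics(g$lambda_true, g$lambda_est, g$lambda_lower, g$lambda_upper)))
  }))
  rownames(by_cell) <- NULL
  out <- structure(list(merged = merged, summary = summ, by_cell = by_cell),
                   class = "bj_recovery")
  if (!is.null(file)) {
    utils::write.csv(merged, paste0(file, ".csv"), row.names = FALSE)
    md <- c("# Parameter recovery", "",
            utils::capture.output(print(summ, row.names = FALSE)), "",
            "## By condition cell", "",
            utils::capture.output(print(by_cell, row.names = FALSE)))
    writeLines(md, paste0(file, ".md"))
  }
  out
}

#' @export
print.bj_recovery <- function(x, ...) {
  cat("<bj_recovery>\n")
  print(transform(x$summary, pearson = round(pearson, 3),
                  spearman = round(spearman, 3), bias = round(bias, 3),
                  rmse = round(rmse, 3), coverage = round(coverage, 3)),
        row.names = FALSE)
  invisible(x)
}
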