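# Hierarchical Bayesian logistic regression by Newton + EM.
#
# Model: y_i ~ Binomial(size_i, plogis(eta_i)),
#   eta = X beta + u1[pid] (+ u2[pid] * xv),
#   beta ~ N(0, prior_sd_beta^2), u_k,j ~ N(0, tau_k^2),
#   tau_k ~ half-normal(prior_sd_tau).
#
# Given tau the log posterior in (beta, u) is strictly concave, so the inner
# mode is found by damped Newton with the exact analytic Hessian; tau is
# updated by a penalized EM step whose sufficient statistic includes the
# Laplace variances of the random effects (avoiding the degenerate tau -> 0
# joint mode). Posterior draws come from the Gaussian approximation over
# (beta, u) at the converged tau (empirical Bayes: tau uncertainty is not
# propagated).
hier_logit_laplace <- function(X, y, size, pid, J, xv = NULL,
                               prior_sd_beta = 1.5, prior_sd_tau = 1,
                               n_draws = 1000L, seed = 1L,
                               max_em = 40L, tol = 1e-5) {
  p <- ncol(X)
  q <- if (is.null(xv)) 1L else 2L
  n <- length(y)
  beta <- c(stats::qlogis(min(0.99, max(0.01, sum(y) / sum(size)))),
            rep(0, p - 1L))
  u <- matrix(0, J, q)
  tau <- rep(0.5, q)
  eta_of <- function(beta, u) {
    eta <- as.vector(X %*% beta) + u[pid, 1L]
    if (q == 2L) eta <- eta + u[pid, 2L] * xv
    eta
  }
  pen_ll <- function(beta, u) {
    eta <- eta_of(beta, u)
    val <- sum(y * eta) - sum(size * log1pexp(eta)) -
      sum(beta^2) / (2 * prior_sd_beta^2)
    for (k in seq_len(q)) val <- val - sum(u[, k]^2) / (2 * tau[k]^2)
    val
  }
  H <- NULL
  inner_newton <- function(beta, u) {
    for (it in seq_len(30L)) {
      eta <- eta_of(beta, u)
      mu <- size * stats::plogis(eta)
      r <- y - mu
      w <- pmax(size * stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
      g <- c(as.vector(crossprod(X, r)) - beta / prior_sd_beta^2,
             as.vector(rowsum(r, pid, reorder = TRUE)) - u[, 1L] / tau[1L]^2,
             if (q == 2L)
               as.vector(rowsum(r * xv, pid, reorder = TRUE)) - u[, 2L] / tau[2L]^2)
      XtWX <- crossprod(X, X * w) + diag(1 / prior_sd_beta^2, p)
      su_w <- as.vector(rowsum(w, pid, reorder = TRUE))
      B1 <- t(rowsum(X * w, pid, reorder = TRUE))
      if (q == 2L) {
        su_wx <- as.vector(rowsum(w * xv, pid, reorder = TRUE))
        su_wx2 <- as.vector(rowsum(w * xv^2, pid, reorder = TRUE))
        B2 <- t(rowsum(X * (w * xv), pid, reorder = TRUE))
        Hm <- rbind(
          cbind(XtWX, B1, B2),
          cbind(t(B1), diag(su_w + 1 / tau[1L]^2, J), diag(su_wx, J)),
          cbind(t(B2), diag(su_wx, J), diag(su_wx2 + 1 / tau[2L]^2, J))
        )
      } else {
        Hm <- rbind(cbind(XtWX, B1),
                    cbind(t(B1), diag(su_w + 1 / tau[1L]^2, J)))
      }
      H <<- Hm
      if (max(abs(g)) < 1e-8) break
      step <- tryCatch(solve(Hm, g), error = function(e)
        solve(Hm + diag(1e-6, nrow(Hm)), g))
      f0 <- pen_ll(beta, u)
      sc <- 1
      repeat {
        beta1 <- beta + sc * step[seq_len(p)]
        u1 <- u
        u1[, 1L] <- u[, 1L] + sc * step[p + seq_len(J)]
        if (q == 2L) u1[, 2L] <- u[, 2L] + sc * step[p + J + seq_len(J)]
        if (pen_ll(beta1, u1) >= f0 || sc < 1e-6) break
        sc <- sc / 2
      }
      if (pen_ll(beta1, u1) < f0) break
      beta <- beta1; u <- u1
    }
    list(beta = beta, u = u)
  }
  for (em in seq_len(max_em)) {
    res <- inner_newton(beta, u)
    beta <- res$beta; u <- res$u
    Sinv_diag <- diag(chol2inv(chol(H)))
    tau_new <- tau
    for (k in seq_len(q)) {
      vk <- Sinv_diag[p + (k - 1L) * J + seq_len(J)]
      ssq <- sum(u[, k]^2) + sum(vk)
      obj <- function(ls) {
        ssq / (2 * exp(2 * ls)) + J * ls +
          exp(2 * ls) / (2 * prior_sd_tau^2) - ls
      }
      tau_new[k] <- exp(stats::nlminb(log(tau[k]), obj, lower = log(0.01),
                                      upper = log(10))$par)
    }
    done <- max(abs(tau_new - tau)) < tol
    tau <- tau_new
    if (done) break
  }
  res <- inner_newton(beta, u)
  beta <- res$beta; u <- res$u
  Sigma <- chol2inv(chol(H))
  mode <- c(beta, as.vector(u))
  draws <- with_seed(seed, MASS::mvrnorm(n_draws, mu = mode, Sigma = Sigma))
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1)
  eta <- eta_of(beta, u)
  gfin <- c(as.vector(crossprod(X, y - size * stats::plogis(eta))) -
              beta / prior_sd_beta^2,
            as.vector(rowsum(y - size * stats::plogis(eta), pid,
                             reorder = TRUE)) - u[, 1L] / tau[1L]^2)
  list(beta = beta, u = u, tau = tau, mode = mode, draws = draws,
       vcov = Sigma, grad_norm = sqrt(sum(gfin^2)), converged = TRUE)
}
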