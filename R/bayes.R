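#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `ceiling(mass * n)` of the
#' sorted draws. This is the interval summary used throughout the package for
#' posterior contrasts.
#'
#' @param samples numeric vector of posterior draws (length >= 2, finite).
#' @param mass probability mass the interval must contain, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hpdi(rnorm(1000), 0.95)
#' @export
hpdi <- function(samples, mass = 0.95) {
  if (!is.numeric(samples) || length(samples) < 2L || anyNA(samples)) {
    stop("`samples` must be a numeric vector of >= 2 finite draws")
  }
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("`mass` must be a single probability in (0, 1)")
  }
  s <- sort(samples)
  n <- length(s)
  w <- min(n, max(1L, ceiling(mass * n)))
  n_windows <- n - w + 1L
  widths <- s[w:n] - s[seq_len(n_windows)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + w - 1L])
}

#' Widely applicable information criterion from a pointwise log-likelihood matrix
#'
#' Computes WAIC = -2 (lppd - p_waic) where lppd is the log pointwise
#' predictive density and p_waic is the sum of the pointwise posterior
#' variances of the log-likelihood. The standard error comes from the
#' pointwise WAIC contributions.
#'
#' @param loglik_matrix draws x observations matrix of pointwise
#'   log-likelihood values.
#' @return list with `waic`, `lppd`, `p_waic`, `se`, `pointwise` (matrix with
#'   columns lppd, p_waic, waic per observation).
#' @export
waic_from_loglik <- function(loglik_matrix) {
  if (!is.matrix(loglik_matrix) || anyNA(loglik_matrix)) {
    stop("`loglik_matrix` must be a complete draws x observations matrix")
  }
  S <- nrow(loglik_matrix)
  # column-wise log-mean-exp, stabilised by the column maximum
  mx <- apply(loglik_matrix, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(loglik_matrix, 2, mx))))
  p_i <- apply(loglik_matrix, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  n <- length(waic_i)
  list(
    waic = sum(waic_i),
    lppd = sum(lppd_i),
    p_waic = sum(p_i),
    se = sqrt(n * stats::var(waic_i)),
    pointwise = cbind(lppd = lppd_i, p_waic = p_i, waic = waic_i)
  )
}

# Central-difference Jacobian of an analytic gradient: the negative Hessian
# of the log posterior at the mode, used for the Laplace approximation.
numeric_hessian <- function(grad_fn, theta, eps = 1e-5) {
  d <- length(theta)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    hi <- eps * max(1, abs(theta[i]))
    up <- theta; up[i] <- up[i] + hi
    dn <- theta; dn[i] <- dn[i] - hi
    H[i, ] <- (grad_fn(up) - grad_fn(dn)) / (2 * hi)
  }
  (H + t(H)) / 2
}

# MAP + Laplace (quadratic) approximation of a posterior.
# `logpost` and `grad` take the full parameter vector; draws come from the
# Gaussian approximation N(mode, -H^{-1}).
laplace_approx <- function(logpost, grad, init, n_draws = 1000, seed = NULL,
                           maxit = 2000L, optimize = TRUE) {
  converged <- TRUE
  if (optimize) {
    fit <- stats::optim(
      par = init, fn = logpost, gr = grad, method = "L-BFGS-B",
      control = list(fnscale = -1, maxit = maxit, factr = 1e7)
    )
    # restart on stiff posteriors until the gradient is genuinely small
    tries <- 0
    while (sqrt(sum(grad(fit$par)^2)) > 1e-3 * sqrt(length(init)) && tries < 3) {
      tries <- tries + 1
      fit <- stats::optim(
        par = fit$par, fn = logpost, gr = grad, method = "L-BFGS-B",
        control = list(fnscale = -1, maxit = maxit, factr = 1e2)
      )
    }
    mode <- fit$par
    converged <- fit$convergence == 0L
  } else {
    mode <- init
  }
  H <- numeric_hessian(grad, mode)
  prec <- -H
  # repair marginal non-positive-definiteness of the numeric Hessian: every
  # direction carries prior curvature well above this floor, so flooring
  # only absorbs finite-difference noise
  repaired <- FALSE
  ch <- tryCatch(chol(prec), error = function(e) NULL)
  if (is.null(ch)) {
    repaired <- TRUE
    e <- eigen(prec, symmetric = TRUE)
    vals <- pmax(e$values, 0.04)
    prec <- e$vectors %*% (vals * t(e$vectors))
    ch <- chol((prec + t(prec)) / 2)
  }
  Sigma <- chol2inv(ch)
  draws <- with_seed(seed, MASS::mvrnorm(n_draws, mu = mode, Sigma = Sigma))
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- names(init)
  list(
    mode = mode,
    draws = draws,
    vcov = Sigma,
    converged = converged,
    grad_norm = sqrt(sum(grad(mode)^2)),
    jittered = repaired
  )
}
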