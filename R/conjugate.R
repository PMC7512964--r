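# Conjugate normal-inverse-gamma machinery for standard (KL) updating of
# Gaussian linear models.  Serves both as a fast exact route for the KL
# columns of the experiments and as the analytic oracle the MCMC sampler is
# validated against.

#' Conjugate normal-inverse-gamma posterior for a Gaussian linear model
#'
#' For `y ~ N(X beta, sigma^2 I)` with prior
#' `beta | sigma^2 ~ N(0, c sigma^2 I)`, `sigma^2 ~ IG(a0, b0)`, the
#' posterior is normal-inverse-gamma with
#' `V_n = (I/c + X'X)^-1`, `m_n = V_n X' y`, `a_n = a0 + n/2`,
#' `b_n = b0 + (y'y - m_n' V_n^-1 m_n) / 2`.
#'
#' @param X Design matrix.
#' @param y Response vector.
#' @param prior A [prior_regression()] specification.
#' @return List with `m`, `V`, `a`, `b`, plus the posterior means
#'   `beta_mean = m` and `sigma2_mean = b / (a - 1)`.
#' @export
conjugate_regression_posterior <- function(X, y, prior = prior_regression(ncol(X))) {
  stopifnot(inherits(prior, "prior_spec"), prior$type == "regression")
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  Vinv <- diag(p) / prior$coef_scale + crossprod(X)
  V <- solve(Vinv)
  m <- drop(V %*% crossprod(X, y))
  a <- prior$sigma2_shape + n / 2
  b <- prior$sigma2_scale + (sum(y^2) - sum(m * (Vinv %*% m))) / 2
  list(m = m, V = V, Vinv = Vinv, a = a, b = b,
       beta_mean = m, sigma2_mean = b / (a - 1))
}

#' Exact draws from a conjugate normal-inverse-gamma posterior
#'
#' Draws `sigma^2 ~ IG(a_n, b_n)` and `beta | sigma^2 ~ N(m_n, sigma^2 V_n)`,
#' returned in the same `posterior_samples` layout the MCMC sampler
#' produces, so predictive machinery applies uniformly.
#'
#' @param post Output of [conjugate_regression_posterior()].
#' @param n_draws Number of independent draws.
#' @param seed Integer seed.
#' @param param_names Column names (`p` coefficients then `"sigma"`).
#' @return A `posterior_samples` object (independent draws, so `ess` equals
#'   the number of draws).
#' @export
sample_conjugate_posterior <- function(post, n_draws = 4000L, seed = 1L,
                                       param_names = NULL) {
  set.seed(seed)
  p <- length(post$m)
  s2 <- post$b / stats::rgamma(n_draws, shape = post$a)
  Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  Lc <- chol(post$V)
  beta <- sweep(Z %*% Lc, 1L, sqrt(s2), "*")
  beta <- sweep(beta, 2L, post$m, "+")
  draws <- cbind(beta, sqrt(s2))
  colnames(draws) <- if (is.null(param_names))
    c(paste0("beta", seq_len(p)), "sigma") else param_names
  structure(list(draws = draws, accept_rate = 1,
                 ess = rep(n_draws, p + 1L), seed = seed,
                 burn_in = 0L, thin = 1L),
            class = "posterior_samples")
}

#' Analytic log-posterior of the conjugate model (unnormalised check value)
#'
#' Joint log density of `(beta, sigma^2)` under the normal-inverse-gamma
#' posterior, used to validate the general Bayesian KL log-target up to an
#' additive constant.
#'
#' @param post Output of [conjugate_regression_posterior()].
#' @param beta Coefficient vector.
#' @param sigma2 Variance.
#' @return Log density value.
#' @export
conjugate_log_density <- function(post, beta, sigma2) {
  p <- length(post$m)
  dev <- beta - post$m
  -(post$a + 1 + p / 2) * log(sigma2) - post$b / sigma2 -
    sum(dev * (post$Vinv %*% dev)) / (2 * sigma2)
}
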