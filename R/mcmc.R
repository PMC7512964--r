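# Adaptive random-walk Metropolis on the unconstrained parameter scale.

# Geyer-style initial-positive-sequence effective sample size
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 1L, 1000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0.05) break
    s <- s + rho[k]
  }
  max(1, n / (1 + 2 * s))
}

#' Sample a general Bayesian posterior by adaptive random-walk Metropolis
#'
#' A Gaussian random-walk Metropolis sampler on the unconstrained
#' parameterisation (`log sigma`, raw coefficients).  During burn-in the
#' global proposal scale follows a Robbins-Monro recursion toward a target
#' acceptance rate, and the proposal covariance is refreshed periodically
#' from the accumulated history; both are frozen when burn-in ends.  Given
#' the same seed the chain is reproduced exactly.
#'
#' @param posterior A [build_general_posterior()] object (anything with
#'   fields `log_target`, `n_params`, `to_natural`, `param_names`,
#'   `init_u` works).
#' @param n_iter Total iterations, `n_iter > burn_in`.
#' @param burn_in Iterations discarded (and used for adaptation).
#' @param seed Integer seed.
#' @param init Optional unconstrained starting vector; defaults to the
#'   posterior's least-squares initialiser.
#' @param target_accept Acceptance rate targeted by the scale adaptation.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return Object of class `posterior_samples`: `draws` (matrix on the
#'   natural scale, named columns), `accept_rate` (post burn-in), `ess`,
#'   `seed`, `burn_in`.
#' @export
sample_posterior <- function(posterior, n_iter = 20000L, burn_in = 5000L,
                             seed = 1L, init = NULL, target_accept = 0.25,
                             thin = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0L, thin >= 1L)
  d <- posterior$n_params
  lt <- posterior$log_target

  set.seed(seed)
  u <- if (is.null(init)) posterior$init_u else as.numeric(init)
  if (length(u) != d) stop("init has wrong length", call. = FALSE)
  lp <- lt(u)
  if (is.nan(lp))
    stop("log-target is NaN at the initial value theta_u = (",
         paste(signif(u, 4), collapse = ", "), ")", call. = FALSE)
  if (!is.finite(lp)) {
    u <- rep(0, d)
    lp <- lt(u)
    if (!is.finite(lp))
      stop("could not find a starting value with finite log-target",
           call. = FALSE)
  }

  log_s <- log(2.38 / sqrt(d))
  L <- diag(d)
  history <- matrix(0, n_iter, d)
  n_keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(0, n_keep, d)
  acc_post <- 0L
  kept <- 0L

  for (i in seq_len(n_iter)) {
    prop <- u + exp(log_s) * drop(L %*% stats::rnorm(d))
    lpp <- lt(prop)
    if (is.nan(lpp))
      stop("log-target returned NaN at theta_u = (",
           paste(signif(prop, 4), collapse = ", "), ")", call. = FALSE)
    acc_prob <- if (lpp == -Inf) 0 else min(1, exp(lpp - lp))
    if (stats::runif(1) < acc_prob) {
      u <- prop
      lp <- lpp
      if (i > burn_in) acc_post <- acc_post + 1L
    }
    history[i, ] <- u

    if (i <= burn_in) {
      log_s <- log_s + min(1, 5 * i^(-0.6)) * (acc_prob - target_accept)
      if (i >= 400L && i %% 200L == 0L) {
        cov_hist <- stats::cov(history[(i %/% 2):i, , drop = FALSE])
        ch <- tryCatch(chol(cov_hist + 1e-10 * diag(d)), error = function(e) NULL)
        if (!is.null(ch)) L <- t(ch)
      }
    } else if ((i - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- posterior$to_natural(u)
    }
  }

  colnames(draws) <- posterior$param_names
  structure(
    list(draws = draws,
         accept_rate = acc_post / (n_iter - burn_in),
         ess = apply(draws, 2L, .ess),
         seed = seed, burn_in = burn_in, thin = thin,
         proposal_scale = exp(log_s)),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %d draws x %d parameters, acceptance %.2f\n",
              nrow(x$draws), ncol(x$draws), x$accept_rate))
  print(round(rbind(mean = colMeans(x$draws),
                    sd = apply(x$draws, 2, stats::sd),
                    ess = x$ess), 4))
  invisible(x)
}

#' Posterior summaries
#'
#' @param object A `posterior_samples` object.
#' @param ... Unused.
#' @return Data frame with posterior mean and sd per parameter.
#' @export
summary.posterior_samples <- function(object, ...) {
  data.frame(parameter = colnames(object$draws),
             mean = colMeans(object$draws),
             sd = apply(object$draws, 2L, stats::sd),
             ess = object$ess,
             row.names = NULL)
}
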