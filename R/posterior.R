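# Assembly of the general Bayesian log-target
#   log pi(theta | x) = log pi(theta) - w * sum_i l_d(x_i, f(.; theta)) + const.

#' Build a general Bayesian posterior
#'
#' Combines a proper prior, a parametric model, a divergence specification
#' and data into the general Bayesian log-target
#' `log pi(theta) - w * sum_i l_d(x_i, f(.; theta))` with calibration
#' weight `w = 1` by default.  With the KL divergence this is the standard
#' Bayes log-posterior up to an additive constant.  Divergences whose
#' empirical loss involves the data generating density (TV, Hellinger,
#' alpha, alpha-beta) require a fitted density estimate, whose values at
#' the observations are pre-computed once (they do not depend on `theta`).
#'
#' Sampling happens on an unconstrained scale: the scale parameter enters
#' as `log sigma`, with the appropriate Jacobian added to the log-target.
#'
#' @param prior A [prior_location_scale()] or [prior_regression()] matched to the model
#'   family.
#' @param model A [gaussian_model()] family object.
#' @param divergence A [divergence_spec()]; `"s_hellinger"` is a
#'   functional-only family and is rejected here.
#' @param data Observations (see [model_design()]); empty data returns the
#'   prior as the target.
#' @param density_estimate An `fkde`/`cond_kde`, required iff
#'   `divergence$requires_density_estimate`; see [fit_density_estimate()].
#' @param kl_cap Optional finite cap on the per-observation log score
#'   (see [loss_kl()]).
#' @param floor Density floor for the estimate values.
#' @param g_values Optional pre-computed density-estimate values at the
#'   observations, overriding evaluation of `density_estimate` (used by the
#'   influence diagnostics' fast leave-one-out refits).
#' @return Object of class `general_posterior` carrying `log_target(u)`
#'   (a function of the unconstrained parameter vector), `param_names`,
#'   `to_natural(u)` and a deterministic least-squares initialiser.
#' @export
build_general_posterior <- function(prior, model, divergence, data,
                                    density_estimate = NULL,
                                    kl_cap = Inf, floor = density_floor(),
                                    g_values = NULL) {
  stopifnot(inherits(prior, "prior_spec"),
            inherits(model, "parametric_model"),
            inherits(divergence, "divergence_spec"))
  if (divergence$name == "s_hellinger")
    stop("the S-Hellinger divergence is available as a functional only, ",
         "not as a posterior target", call. = FALSE)
  if (divergence$requires_density_estimate &&
      is.null(density_estimate) && is.null(g_values))
    stop("divergence '", divergence$name,
         "' requires a density estimate (see fit_density_estimate)",
         call. = FALSE)

  empty <- is.null(data) ||
    (is.numeric(data) && length(data) == 0L)
  if (!empty) {
    d <- model_design(model, data)
    X <- d$X; y <- d$y; n <- length(y)
  } else {
    X <- matrix(0, 0L, model$n_coef); y <- numeric(0); n <- 0L
  }

  g_obs <- NULL
  if (divergence$requires_density_estimate && n > 0L) {
    g_obs <- if (!is.null(g_values)) {
      if (length(g_values) != n)
        stop("'g_values' must have one value per observation", call. = FALSE)
      as.numeric(g_values)
    } else if (inherits(density_estimate, "fkde")) {
      evaluate_density(density_estimate, y)
    } else {
      Xg <- if (model$family == "ar_gaussian") X[, -1L, drop = FALSE] else X
      evaluate_conditional_density(density_estimate, Xg, y)
    }
    g_obs <- pmax(g_obs, floor)
  }

  p <- model$n_coef
  w <- divergence$weight_w
  a <- divergence$alpha; b <- divergence$beta
  dname <- divergence$name
  is_ls_prior <- prior$type == "location_scale"

  log_target <- function(u) {
    beta <- u[seq_len(p)]
    logs <- u[p + 1L]
    sigma <- exp(logs)
    if (!is.finite(sigma) || sigma <= 0) return(-Inf)
    # Jacobian: d sigma = sigma d log(sigma); d sigma^2 = 2 sigma^2 d log(sigma)
    lp <- log_prior(prior, beta, sigma) +
      if (is_ls_prior) logs else log(2) + 2 * logs
    if (!is.finite(lp)) return(-Inf)
    if (n == 0L) return(lp)

    mu <- drop(X %*% beta)
    data_term <- switch(dname,
      kl = {
        lf <- stats::dnorm(y, mu, sigma, log = TRUE)
        -sum(pmin(-lf, kl_cap))
      },
      dpd = {
        fa <- stats::dnorm(y, mu, sigma)^a
        sum(fa) / a - n * gaussian_power_integral(sigma, a) / (1 + a)
      },
      hellinger = sum(sqrt(stats::dnorm(y, mu, sigma) / g_obs)),
      tv = -0.5 * sum(abs(1 - stats::dnorm(y, mu, sigma) / g_obs)),
      alpha = sum(g_obs^(a - 1) * stats::dnorm(y, mu, sigma)^(1 - a)) /
        (a * (1 - a)),
      alphabeta = sum(g_obs^(a - 1) * stats::dnorm(y, mu, sigma)^b) /
        (a * b) -
        n * gaussian_power_integral(sigma, a + b - 1) / (a * (a + b)))
    lp + w * data_term
  }

  init_u <- if (n > p) {
    fit <- stats::lm.fit(X, y)
    res_sd <- stats::sd(fit$residuals)
    if (!is.finite(res_sd) || res_sd <= 0) res_sd <- 1
    c(fit$coefficients, log(res_sd))
  } else {
    c(rep(0, p), 0)
  }
  init_u[!is.finite(init_u)] <- 0

  structure(
    list(prior = prior, model = model, divergence = divergence,
         X = X, y = y, n = n, g_obs = g_obs,
         log_target = log_target,
         n_params = p + 1L,
         param_names = c(model$coef_names, "sigma"),
         to_natural = function(u) c(u[seq_len(p)], exp(u[p + 1L])),
         init_u = init_u),
    class = "general_posterior")
}

#' @export
print.general_posterior <- function(x, ...) {
  cat(sprintf("<general_posterior> %s model, %s divergence, n = %d\n",
              x$model$family, x$divergence$name, x$n))
  invisible(x)
}
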