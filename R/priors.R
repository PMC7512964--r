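# Prior specifications.  Bounded-score divergences make posterior tails
# prior-driven, so only proper priors are allowed.

#' Priors for the Gaussian location-scale family
#'
#' `mu ~ N(mu_mean, mu_sd^2)` and `sigma ~ Gamma(shape, rate)` (shape-rate
#' parametrisation on the standard deviation itself).  The defaults are the
#' weakly informative `N(0, 10^2)` and `Gamma(0.001, 0.001)` used in the
#' simple-inference study.
#'
#' @param mu_mean,mu_sd Normal prior on the location.
#' @param sigma_shape,sigma_rate Gamma prior (shape, rate) on `sigma`.
#' @return Object of class `prior_spec`.
#' @export
prior_location_scale <- function(mu_mean = 0, mu_sd = 10,
                                 sigma_shape = 0.001, sigma_rate = 0.001) {
  stopifnot(mu_sd > 0, sigma_shape > 0, sigma_rate > 0)
  structure(list(type = "location_scale", mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_shape = sigma_shape, sigma_rate = sigma_rate),
            class = "prior_spec")
}

#' Hierarchical prior for Gaussian linear models
#'
#' `sigma^2 ~ InvGamma(shape, scale)` (density proportional to
#' `(sigma^2)^-(shape+1) exp(-scale / sigma^2)`) and conditionally
#' `beta_i | sigma^2 ~ N(0, coef_scale * sigma^2)`.  This is the conjugate
#' normal-inverse-gamma family for standard (KL) updating; defaults are the
#' `IG(2, 0.5)`, `N(0, 5 sigma^2)` prior of the regression and time-series
#' studies.
#'
#' @param p Number of mean coefficients (including any intercept/lag terms).
#' @param coef_scale Prior variance multiplier `c` in `N(0, c sigma^2)`.
#' @param sigma2_shape,sigma2_scale Inverse-gamma (shape, scale) on
#'   `sigma^2`.
#' @return Object of class `prior_spec`.
#' @export
prior_regression <- function(p, coef_scale = 5,
                             sigma2_shape = 2, sigma2_scale = 0.5) {
  stopifnot(p >= 1, coef_scale > 0, sigma2_shape > 0, sigma2_scale > 0)
  structure(list(type = "regression", p = as.integer(p),
                 coef_scale = coef_scale,
                 sigma2_shape = sigma2_shape, sigma2_scale = sigma2_scale),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  if (x$type == "location_scale") {
    cat(sprintf("<prior_spec> mu ~ N(%g, %g^2), sigma ~ Gamma(%g, %g)\n",
                x$mu_mean, x$mu_sd, x$sigma_shape, x$sigma_rate))
  } else {
    cat(sprintf(
      "<prior_spec> sigma^2 ~ IG(%g, %g), beta_i | sigma^2 ~ N(0, %g sigma^2), p = %d\n",
      x$sigma2_shape, x$sigma2_scale, x$coef_scale, x$p))
  }
  invisible(x)
}

#' Log prior density on the natural parameter scale
#'
#' @param prior A `prior_spec`.
#' @param beta Coefficient vector.
#' @param sigma Standard deviation (positive).
#' @return Log prior density of `(beta, sigma)` with respect to
#'   `d beta d sigma` for location-scale priors and `d beta d sigma^2` for
#'   regression priors (sampling-scale Jacobians are handled by the
#'   posterior object).
#' @keywords internal
#' @export
log_prior <- function(prior, beta, sigma) {
  stopifnot(inherits(prior, "prior_spec"))
  if (sigma <= 0) return(-Inf)
  if (prior$type == "location_scale") {
    stats::dnorm(beta, prior$mu_mean, prior$mu_sd, log = TRUE) +
      stats::dgamma(sigma, shape = prior$sigma_shape, rate = prior$sigma_rate,
                    log = TRUE)
  } else {
    s2 <- sigma^2
    a <- prior$sigma2_shape; b <- prior$sigma2_scale
    sum(stats::dnorm(beta, 0, sqrt(prior$coef_scale * s2), log = TRUE)) +
      a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
  }
}
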