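# Parametric families fitted by the package.  All three are conditionally
# Gaussian linear models, so they share one design-matrix representation:
# y | x ~ N(x' beta, sigma^2), with the location-scale family using an
# intercept-only design and the AR family a lagged design.

#' Parametric model families
#'
#' Constructors for the model families available to the general Bayesian
#' update: a Gaussian location-scale family `N(mu, sigma^2)`, a Gaussian
#' linear regression `y | x ~ N(x' beta, sigma^2)` and a Gaussian AR(L)
#' process `x_t | past ~ N(mu_0 + sum_i mu_i x_{t-i}, sigma^2)` that
#' conditions on its first `L` observations.  Every family exposes a
#' log-density, a sampler through the simulators, and the closed-form
#' Gaussian power integral needed by the density power divergence.
#'
#' @param p Number of regression covariates.
#' @param L Autoregressive lag order.
#' @return Object of class `parametric_model`.
#' @seealso [model_log_density()], [power_integral()]
#' @export
gaussian_model <- function() {
  structure(list(family = "gaussian_location_scale",
                 coef_names = "mu", n_coef = 1L),
            class = "parametric_model")
}

#' @rdname gaussian_model
#' @export
regression_model <- function(p) {
  stopifnot(p >= 1L)
  structure(list(family = "linear_regression_gaussian",
                 coef_names = paste0("beta", seq_len(p)), n_coef = as.integer(p)),
            class = "parametric_model")
}

#' @rdname gaussian_model
#' @export
ar_model <- function(L) {
  stopifnot(L >= 1L)
  structure(list(family = "ar_gaussian",
                 coef_names = c("mu0", paste0("mu", seq_len(L))),
                 n_coef = as.integer(L) + 1L, L = as.integer(L)),
            class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  cat("<parametric_model> ", x$family, ": parameters (",
      paste(c(x$coef_names, "sigma"), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# lagged design for an AR(L): rows t = L+1..T, columns (1, y_{t-1..t-L})
.lag_design <- function(series, L) {
  Tn <- length(series)
  if (Tn <= L) stop("series shorter than the lag order", call. = FALSE)
  E <- stats::embed(series, L + 1L)
  list(X = cbind(1, E[, -1L, drop = FALSE]), y = E[, 1L])
}

#' Design-matrix view of data under a model
#'
#' Internal canonical form: every family reduces to a Gaussian linear model
#' `y ~ N(X beta, sigma^2)`.  `data` may be a `simulated_dataset` or, for
#' the location-scale family a numeric vector, for regression a
#' `list(X, y)`, for AR a numeric series.
#'
#' @param model A `parametric_model`.
#' @param data Observations in one of the forms above.
#' @return `list(X, y)` with `X` including any intercept/lag columns.
#' @keywords internal
#' @export
model_design <- function(model, data) {
  if (inherits(data, "simulated_dataset")) data <- data$data
  switch(model$family,
    gaussian_location_scale = {
      y <- as.numeric(data)
      list(X = matrix(1, length(y), 1L), y = y)
    },
    linear_regression_gaussian = {
      X <- as.matrix(data$X)
      if (ncol(X) != model$n_coef)
        stop("design has ", ncol(X), " columns but the model expects ",
             model$n_coef, call. = FALSE)
      list(X = X, y = as.numeric(data$y))
    },
    ar_gaussian = .lag_design(as.numeric(data), model$L))
}

.theta_split <- function(model, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != model$n_coef + 1L)
    stop("theta must have ", model$n_coef + 1L, " elements", call. = FALSE)
  list(beta = theta[seq_len(model$n_coef)], sigma = theta[model$n_coef + 1L])
}

#' Per-observation model log-density
#'
#' Gaussian families: `log phi((y - x' beta)/sigma) - log sigma` per row of
#' the design.  The AR family conditions on its first `L` observations, so
#' a series of length `T` yields exactly `T - L` terms.  A non-positive
#' `sigma` returns `-Inf` for every observation (rejected in MCMC).
#'
#' @param model A [gaussian_model()] family object.
#' @param theta Parameter vector `(coefficients, sigma)`.
#' @param data Observations (see [model_design()]).
#' @return Numeric vector of log-density contributions.
#' @export
model_log_density <- function(model, theta, data) {
  d <- model_design(model, data)
  th <- .theta_split(model, theta)
  if (!is.finite(th$sigma) || th$sigma <= 0)
    return(rep(-Inf, length(d$y)))
  stats::dnorm(d$y, drop(d$X %*% th$beta), th$sigma, log = TRUE)
}

#' Gaussian power integral
#'
#' `int N(z; mu, sigma^2)^(1+alpha) dz = (2 pi sigma^2)^(-alpha/2) (1+alpha)^(-1/2)`,
#' the model-side quantity entering the density power divergence loss.
#' For the conditionally Gaussian families the integral over the response is
#' the same for every covariate value, so a scalar is returned.
#'
#' @param model A [gaussian_model()] family object.
#' @param theta Parameter vector `(coefficients, sigma)`.
#' @param alpha Power parameter, `1 + alpha > 0`.
#' @return The power integral (a single positive number).
#' @export
power_integral <- function(model, theta, alpha) {
  th <- .theta_split(model, theta)
  gaussian_power_integral(th$sigma, alpha)
}

#' @rdname power_integral
#' @param sigma Gaussian standard deviation.
#' @export
gaussian_power_integral <- function(sigma, alpha) {
  if (1 + alpha <= 0) stop("power integral requires 1 + alpha > 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  (2 * pi * sigma^2)^(-alpha / 2) / sqrt(1 + alpha)
}

#' Fit the density estimate a divergence needs for a given model
#'
#' Dispatches to the marginal fixed-width KDE for the location-scale family
#' and to the conditional KDE (response given covariates, or given lagged
#' values for AR models) otherwise.
#'
#' @param model A [gaussian_model()] family object.
#' @param data Observations (see [model_design()]).
#' @param ... Passed on to [fit_kde()] or [fit_conditional_kde()].
#' @return An `fkde` or `cond_kde` object.
#' @export
fit_density_estimate <- function(model, data, ...) {
  if (model$family == "gaussian_location_scale") {
    if (inherits(data, "simulated_dataset")) data <- data$data
    fit_kde(as.numeric(data), ...)
  } else {
    d <- model_design(model, data)
    X <- d$X
    # drop the deterministic intercept/lag-one column for AR designs
    if (model$family == "ar_gaussian") X <- X[, -1L, drop = FALSE]
    fit_conditional_kde(X, d$y, ...)
  }
}
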