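# Seeded generators for the three simulation studies.  Re-running with the
# same seed reproduces every dataset bit for bit.

.new_dataset <- function(name, data, params, seed, extra = list()) {
  structure(c(list(generator = name, data = data, params = params,
                   seed = seed), extra),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", x$generator, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate from an epsilon-contaminated normal
#'
#' Draws i.i.d. observations from the two-component mixture
#' `(1 - eps) N(0, 1) + eps N(5, 5^2)` (defaults `eps = 0.01`), the
#' canonical outlier-contamination mechanism of the simple-inference study.
#' The component indicator is drawn independently per observation.
#'
#' @param n Sample size.
#' @param seed Integer seed.
#' @param contamination Mixture weight `eps` of the contaminating component.
#' @param main_mean,main_sd Bulk component parameters.
#' @param contam_mean,contam_sd Contaminating component parameters.
#' @return A `simulated_dataset` whose `$data` is the observation vector.
#' @export
simulate_contaminated_normal <- function(n, seed, contamination = 0.01,
                                         main_mean = 0, main_sd = 1,
                                         contam_mean = 5, contam_sd = 5) {
  stopifnot(n >= 1, contamination >= 0, contamination <= 1)
  set.seed(seed)
  comp <- stats::rbinom(n, 1L, contamination)
  x <- stats::rnorm(n,
                    mean = ifelse(comp == 1L, contam_mean, main_mean),
                    sd = ifelse(comp == 1L, contam_sd, main_sd))
  .new_dataset("contaminated_normal", x,
               list(contamination = contamination, main_mean = main_mean,
                    main_sd = main_sd, contam_mean = contam_mean,
                    contam_sd = contam_sd), seed)
}

#' Simulate Student-t observations
#'
#' i.i.d. draws from `t(df)`; with `df = 4` (the default) the tails are
#' consistently heavier than any Gaussian, which is the second
#' misspecification mechanism of the simple-inference study.
#'
#' @param n Sample size.
#' @param df Degrees of freedom, `df > 0`.
#' @param seed Integer seed.
#' @return A `simulated_dataset` whose `$data` is the observation vector.
#' @export
simulate_student_t <- function(n, df = 4, seed = 1) {
  stopifnot(n >= 1, df > 0)
  set.seed(seed)
  .new_dataset("student_t", stats::rt(n, df), list(df = df), seed)
}

#' Draw the fixed regression coefficients of the heteroscedastic study
#'
#' `beta_i ~ Unif(-2, 2)`, drawn once per study with its own seed and held
#' constant across the repeat datasets.
#'
#' @param p Number of coefficients.
#' @param seed Integer seed.
#' @return Numeric coefficient vector of length `p`.
#' @export
draw_regression_coefficients <- function(p, seed) {
  stopifnot(p >= 1)
  set.seed(seed)
  stats::runif(p, -2, 2)
}

#' Simulate the heteroscedastic linear model
#'
#' `y_i = x_i' beta + exp(2 x_i1 / 3) z_i` with `x_i ~ N_p(0, I)` and
#' `z_i ~ N(0, 1)`: a homoscedastic Gaussian linear model is misspecified
#' for these data because the error scale depends on the first covariate
#' (marginal error variance `E exp(4 X_1 / 3) = exp(8/9)`).  A test block
#' of `n_test` fresh covariate rows with exactly noiseless responses
#' `X beta` is emitted alongside.
#'
#' @param n Training sample size.
#' @param p Covariate dimension.
#' @param beta Coefficient vector of length `p` (see
#'   [draw_regression_coefficients()]).
#' @param seed Integer seed.
#' @param n_test Size of the noiseless test block.
#' @return A `simulated_dataset`; `$data` is `list(X, y)`, with `$X_test`
#'   and noiseless `$y_test` alongside.
#' @export
simulate_heteroscedastic_regression <- function(n, p, beta, seed,
                                                n_test = 100L) {
  stopifnot(n >= 1, p >= 1, length(beta) == p)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- drop(X %*% beta) + exp(2 * X[, 1L] / 3) * stats::rnorm(n)
  X_test <- matrix(stats::rnorm(n_test * p), n_test, p)
  y_test <- drop(X_test %*% beta)
  .new_dataset("heteroscedastic_regression", list(X = X, y = y),
               list(n = n, p = p, beta = beta), seed,
               extra = list(X_test = X_test, y_test = y_test))
}

#' Simulate an AR(L) series with optional GARCH(1,1) observation error
#'
#' The latent signal follows
#' `x_t = mu_0 + sum_i mu_i x_{t-i} + eps_t`, `eps_t ~ N(0, sigma^2)`;
#' the observed series is `y_t = x_t + e_t` where the error follows a
#' GARCH(1,1) recursion `e_t = psi_t z_t`, `z_t ~ N(0,1)`,
#' `psi_t^2 = omega + alpha1 e_{t-1}^2 + beta1 psi_{t-1}^2`
#' (`omega > 0`, `alpha1 >= 0`, `beta1 >= 0`).  With `garch = NULL` the
#' observation error is dropped and `y = x`.  The GARCH state starts at the
#' stationary variance `omega / (1 - alpha1 - beta1)` when
#' `alpha1 + beta1 < 1` and at `omega` on or beyond that boundary (the
#' high-volatility study sits exactly on the integrated boundary, where no
#' stationary variance exists); a `burn`-step prefix is discarded.
#'
#' The test block continues the latent AR process (innovations `eps_t`
#' included, observation error excluded) for `n_test` further steps; the
#' `L` values preceding it are returned as `$test_history`.
#'
#' @param T Length of the observed training series.
#' @param mu Numeric vector `(intercept, lag coefficients)`; length `L + 1`.
#' @param sigma Innovation standard deviation of the AR process.
#' @param garch `NULL`, or `list(omega, alpha1, beta1)`.
#' @param seed Integer seed.
#' @param n_test Length of the error-free AR test continuation.
#' @param burn Number of initial steps discarded.
#' @return A `simulated_dataset`; `$data` is the observed series `y`,
#'   with `$x` (latent signal), `$test_series` and `$test_history`.
#' @export
simulate_ar_garch <- function(T, mu, sigma = 1, garch = NULL, seed = 1,
                              n_test = 100L, burn = 500L) {
  stopifnot(T >= 1, length(mu) >= 2, sigma > 0)
  lags <- mu[-1L]
  L <- length(lags)
  if (L >= T / 10) stop("lag order too large for the series length", call. = FALSE)
  roots <- polyroot(c(1, -lags))
  if (any(Mod(roots) <= 1 + 1e-8))
    stop("explosive AR coefficients: lag polynomial root inside the unit circle",
         call. = FALSE)
  if (!is.null(garch)) {
    omega <- garch$omega; a1 <- garch$alpha1; b1 <- garch$beta1
    if (is.null(omega) || omega <= 0 || a1 < 0 || b1 < 0)
      stop("GARCH requires omega > 0, alpha1 >= 0, beta1 >= 0", call. = FALSE)
  }

  set.seed(seed)
  total <- burn + T + n_test
  eps <- stats::rnorm(total, 0, sigma)
  z <- stats::rnorm(burn + T)

  x <- numeric(total)
  for (t in seq_len(total)) {
    past <- if (t == 1L) numeric(0) else x[max(1L, t - L):(t - 1L)]
    past <- rev(past)
    xlag <- sum(lags[seq_along(past)] * past)
    x[t] <- mu[1L] + xlag + eps[t]
  }

  if (is.null(garch)) {
    e <- numeric(burn + T)
  } else {
    e <- numeric(burn + T)
    psi2 <- if (a1 + b1 < 1) omega / (1 - a1 - b1) else omega
    for (t in seq_len(burn + T)) {
      e[t] <- sqrt(psi2) * z[t]
      psi2 <- omega + a1 * e[t]^2 + b1 * psi2
    }
  }

  train_idx <- (burn + 1L):(burn + T)
  y <- x[train_idx] + e[train_idx]
  .new_dataset("ar_garch", y,
               list(mu = mu, sigma = sigma, garch = garch, L = L, burn = burn),
               seed,
               extra = list(
                 x = x[train_idx],
                 test_series = x[(burn + T + 1L):total],
                 test_history = x[(burn + T - L + 1L):(burn + T)]))
}
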