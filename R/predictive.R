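# Posterior predictives: mixture-averaged densities on a grid, regression
# predictive means/variances, and one-step-ahead time-series predictions.

#' Posterior predictive density on a grid
#'
#' The mixture average `(1/S) sum_s f(x; theta^(s))` over posterior draws
#' of a location-scale model, evaluated on a grid.  Integrates to one up to
#' grid truncation.
#'
#' @param samples A `posterior_samples` object for a [gaussian_model()].
#' @param grid Evaluation grid (should cover the data range).
#' @return Object of class `predictive_density`: `grid`, `density`.
#' @export
predictive_density <- function(samples, grid) {
  draws <- samples$draws
  if (nrow(draws) < 1L) stop("no post burn-in draws", call. = FALSE)
  dens <- numeric(length(grid))
  S <- nrow(draws)
  for (start in seq(1L, S, by = 256L)) {
    idx <- start:min(start + 255L, S)
    dens <- dens + colSums(
      stats::dnorm(outer(draws[idx, 1L], grid, "-") * -1,
                   sd = draws[idx, 2L]))
  }
  structure(list(grid = grid, density = dens / S), class = "predictive_density")
}

#' Regression posterior predictive means and variances
#'
#' Predictive mean `X m_beta` using the posterior-mean coefficients, and
#' the per-row predictive variance `mean(sigma^2 draws) + Var_s(x' beta^(s))`
#' (draw-to-draw variance of the linear predictor plus the averaged model
#' variance).  For divergences other than KL the variance is that of the
#' divergence-optimal predictive, not an estimate of the response variance.
#'
#' @param samples A `posterior_samples` object whose columns are
#'   coefficients followed by `sigma`.
#' @param X New design matrix (covariates only, matching the coefficients).
#' @return List with `mean` and `var`, one element per row of `X`.
#' @export
predictive_regression <- function(samples, X) {
  X <- as.matrix(X)
  draws <- samples$draws
  p <- ncol(draws) - 1L
  stopifnot(ncol(X) == p)
  B <- draws[, seq_len(p), drop = FALSE]
  lin <- X %*% t(B)                       # rows: new points, cols: draws
  mean_s2 <- mean(draws[, p + 1L]^2)
  list(mean = drop(X %*% colMeans(B)),
       var = apply(lin, 1L, stats::var) + mean_s2)
}

#' One-step-ahead AR predictions over a test series
#'
#' Builds the lagged design of the test continuation (conditioning on the
#' observed test history: lags are previous *test values*, never previous
#' predictions) and returns the posterior-mean one-step prediction and the
#' predictive variance at every test point.
#'
#' @param samples A `posterior_samples` object for an [ar_model()]
#'   (columns `mu0, mu1, ..., muL, sigma`).
#' @param test_series Numeric test series of length `m`.
#' @param history The `L` observed values immediately preceding the test
#'   series.
#' @return List with `mean`, `var` (length `m`) and the lag design used.
#' @export
predictive_ar_onestep <- function(samples, test_series, history) {
  m <- length(test_series)
  if (m == 0L) {
    warning("zero-length test series: nothing to predict")
    return(list(mean = numeric(0), var = numeric(0)))
  }
  L <- length(history)
  full <- c(history, test_series)
  E <- stats::embed(full, L + 1L)        # rows t = L+1 .. L+m
  Xlag <- cbind(1, E[, -1L, drop = FALSE])
  pr <- predictive_regression(samples, Xlag)
  list(mean = pr$mean, var = pr$var, X = Xlag)
}

#' @export
print.predictive_density <- function(x, ...) {
  cat(sprintf("<predictive_density> %d grid points on [%.3g, %.3g], mass = %.4f\n",
              length(x$grid), min(x$grid), max(x$grid),
              sum(x$density) * mean(diff(x$grid))))
  invisible(x)
}
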