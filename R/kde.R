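# Fixed-width kernel density estimation (Gaussian/RBF kernel), marginal and
# conditional.  These supply the g_n plugged into the TV, Hellinger, alpha
# and alpha-beta empirical losses.

#' Silverman rule-of-thumb bandwidth
#'
#' `1.06 * min(sd, IQR/1.34) * n^(-1/5)`.  When the interquartile range is
#' zero (heavily tied data) the standard deviation alone is used; a sample
#' with no spread at all is degenerate and raises an error.
#'
#' @param sample Numeric vector, `n >= 2`.
#' @return A positive bandwidth on the scale of the observations.
#' @export
silverman_bandwidth <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 2L) stop("need at least two observations for a bandwidth", call. = FALSE)
  s <- stats::sd(sample)
  iqr <- stats::IQR(sample) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(spread) || spread <= 0)
    stop("degenerate sample: no spread to set a bandwidth from", call. = FALSE)
  1.06 * spread * n^(-1 / 5)
}

#' Fit a fixed-width kernel density estimate
#'
#' `g_n(x) = (1/n) sum_i K_h(x - x_i)` with a Gaussian (RBF) kernel.  The
#' estimate integrates to one by construction and is invariant to the
#' ordering of the sample.
#'
#' @param sample Numeric observation vector.
#' @param bandwidth Positive bandwidth, or `"auto"` for
#'   [silverman_bandwidth()] (which needs `n >= 2`).
#' @return An object of class `fkde` with fields `sample` and `bandwidth`.
#' @examples
#' est <- fit_kde(rnorm(100))
#' evaluate_density(est, 0)
#' @export
fit_kde <- function(sample, bandwidth = "auto") {
  sample <- as.numeric(sample)
  if (length(sample) < 1L) stop("empty sample", call. = FALSE)
  if (identical(bandwidth, "auto")) {
    bandwidth <- silverman_bandwidth(sample)
  }
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("'bandwidth' must be a single positive number", call. = FALSE)
  structure(list(sample = sample, bandwidth = bandwidth, kernel = "gaussian"),
            class = "fkde")
}

#' Evaluate a kernel density estimate
#'
#' Vectorised evaluation of a fitted [fit_kde()] estimate.  Evaluation at a
#' sample point includes that point's own kernel (plain fixed-width KDE);
#' set `leave_one_out = TRUE` to subtract the self kernel when `x` *is* the
#' fitted sample, a variant useful for sensitivity analysis.
#'
#' @param est An `fkde` object.
#' @param x Evaluation point(s).
#' @param leave_one_out Logical; only meaningful when evaluating at the
#'   fitted sample itself (lengths must match).
#' @param chunk Number of evaluation points processed per block, bounding
#'   memory at `chunk * n` kernel evaluations.
#' @return Numeric vector of density values (non-negative).
#' @export
evaluate_density <- function(est, x, leave_one_out = FALSE, chunk = 512L) {
  stopifnot(inherits(est, "fkde"))
  x <- as.numeric(x)
  n <- length(est$sample)
  h <- est$bandwidth
  out <- numeric(length(x))
  for (start in seq(1L, length(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(x))
    K <- outer(x[idx], est$sample, function(a, b) stats::dnorm(a - b, sd = h))
    out[idx] <- rowMeans(K)
  }
  if (leave_one_out) {
    if (length(x) != n)
      stop("leave-one-out evaluation requires x to be the fitted sample",
           call. = FALSE)
    out <- pmax((n * out - stats::dnorm(0, sd = h)) / (n - 1), 0)
  }
  out
}

#' @export
predict.fkde <- function(object, newdata, ...) evaluate_density(object, newdata)

#' @export
print.fkde <- function(x, ...) {
  cat(sprintf("<fkde> n = %d, gaussian kernel, bandwidth = %.4g\n",
              length(x$sample), x$bandwidth))
  invisible(x)
}

# log-space Nadaraya-Watson weights: rows = evaluation covariates, cols =
# sample covariates; rows sum to one even when all kernels underflow.
.nw_weights <- function(X_sample, hx, X_eval) {
  n <- nrow(X_sample)
  m <- nrow(X_eval)
  lw <- matrix(0, m, n)
  for (j in seq_len(ncol(X_sample))) {
    lw <- lw + outer(X_eval[, j], X_sample[, j],
                     function(a, b) stats::dnorm(a - b, sd = hx[j], log = TRUE))
  }
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx)
  w / rowSums(w)
}

#' Fit a conditional kernel density estimate
#'
#' Nadaraya-Watson style conditional density
#' `g_n(y | x) = sum_i w_i(x) K_hy(y - y_i)` with
#' `w_i(x) proportional to prod_j K_hxj(x_j - x_ij)`, so that
#' `int g_n(y | x) dy = 1` for every `x`.  Bandwidths come from a
#' two-stage rule: stage one sets normal-reference (Silverman) bandwidths
#' for every coordinate; stage two refines the response bandwidth by
#' least-squares cross-validation over a multiplier grid, holding the
#' covariate bandwidths fixed.
#'
#' @param X Covariate matrix (or vector), one row per observation.
#' @param y Response vector.
#' @param bandwidths `"auto"` for the two-stage rule, or a list with
#'   elements `x` (vector, one per covariate) and `y` (scalar).
#' @param refine Logical; skip the stage-two refinement when `FALSE`.
#' @param cv_grid Multipliers applied to the reference response bandwidth
#'   during the cross-validation search.
#' @return Object of class `cond_kde` with fields `X`, `y`, `hx`, `hy`.
#' @export
fit_conditional_kde <- function(X, y, bandwidths = "auto", refine = TRUE,
                                cv_grid = c(0.4, 0.6, 0.8, 1, 1.35, 1.8, 2.4)) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n) stop("rows of X must match length of y", call. = FALSE)
  if (n < max(5L, ncol(X) + 2L))
    stop("too few observations for a conditional density estimate", call. = FALSE)

  if (identical(bandwidths, "auto")) {
    hx <- apply(X, 2L, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s <= 0) {
        warning("degenerate covariate column; using fallback bandwidth 1",
                call. = FALSE)
        1
      } else silverman_bandwidth(col)
    })
    hy <- silverman_bandwidth(y)
    if (refine) {
      W <- .nw_weights(X, hx, X)
      score <- vapply(cv_grid * hy, function(h) .lscv_score(W, y, h), 0)
      hy <- (cv_grid * hy)[which.min(score)]
    }
  } else {
    hx <- as.numeric(bandwidths$x)
    hy <- as.numeric(bandwidths$y)
    if (length(hx) != ncol(X) || any(hx <= 0) || length(hy) != 1L || hy <= 0)
      stop("invalid explicit bandwidths", call. = FALSE)
  }
  structure(list(X = X, y = y, hx = hx, hy = hy), class = "cond_kde")
}

# Least-squares CV score for the response bandwidth: integrated squared
# estimate minus twice the leave-one-out fit, averaged over sample points.
.lscv_score <- function(W, y, h) {
  n <- length(y)
  Phi2 <- outer(y, y, function(a, b) stats::dnorm(a - b, sd = sqrt(2) * h))
  term1 <- rowSums((W %*% Phi2) * W)
  W0 <- W
  diag(W0) <- 0
  rs <- rowSums(W0)
  rs[rs == 0] <- 1
  W0 <- W0 / rs
  Phi1 <- outer(y, y, function(a, b) stats::dnorm(a - b, sd = h))
  term2 <- rowSums(W0 * Phi1)
  mean(term1 - 2 * term2)
}

#' Evaluate a conditional kernel density estimate
#'
#' Returns `g_n(y | x)` at paired evaluation points: row `k` of `X_eval`
#' with element `k` of `y_eval`.
#'
#' @param est A `cond_kde` object.
#' @param X_eval Covariate matrix (or vector) of evaluation points.
#' @param y_eval Response values, one per row of `X_eval`.
#' @return Numeric vector of conditional density values.
#' @export
evaluate_conditional_density <- function(est, X_eval, y_eval) {
  stopifnot(inherits(est, "cond_kde"))
  X_eval <- as.matrix(X_eval)
  y_eval <- as.numeric(y_eval)
  if (nrow(X_eval) != length(y_eval))
    stop("X_eval rows must match length of y_eval", call. = FALSE)
  W <- .nw_weights(est$X, est$hx, X_eval)
  K <- outer(y_eval, est$y, function(a, b) stats::dnorm(a - b, sd = est$hy))
  rowSums(W * K)
}

#' Conditional mean implied by a conditional KDE
#'
#' `E_gn[y | x] = sum_i w_i(x) y_i`, mainly a diagnostic for checking that
#' the smoother tracks the true regression function.
#'
#' @inheritParams evaluate_conditional_density
#' @return Numeric vector of conditional means, one per row of `X_eval`.
#' @export
conditional_mean <- function(est, X_eval) {
  stopifnot(inherits(est, "cond_kde"))
  W <- .nw_weights(est$X, est$hx, as.matrix(X_eval))
  as.numeric(W %*% est$y)
}

#' @export
print.cond_kde <- function(x, ...) {
  cat(sprintf("<cond_kde> n = %d, p = %d, hy = %.4g, hx = %s\n",
              length(x$y), ncol(x$X), x$hy,
              paste(signif(x$hx, 4), collapse = ", ")))
  invisible(x)
}
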