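# Per-observation losses l_d(x, f(.; theta)).  The general Bayesian
# posterior is proportional to  prior * exp(-w * sum_i l_d(x_i, f)).

#' Logarithmic-score loss (Kullback-Leibler target)
#'
#' `-log f(x; theta)`: the negative log-likelihood contribution.  Its
#' expected value under the data generating process differs from the
#' KL-divergence only by the model-free entropy term, so exponentiating its
#' negated sum recovers standard Bayesian updating.
#'
#' @param f_at_x Non-negative model density value(s) at the observation(s).
#' @param cap Optional finite cap returned where `f_at_x == 0`; the default
#'   `Inf` propagates a `-Inf` log-target, i.e. rejection in MCMC.
#' @return Numeric vector of losses.
#' @export
loss_kl <- function(f_at_x, cap = Inf) {
  if (any(f_at_x < 0)) stop("model density must be non-negative", call. = FALSE)
  pmin(-log(f_at_x), cap)
}

.floor_g <- function(g_at_x, floor) {
  if (any(g_at_x < 0)) stop("density estimate must be non-negative", call. = FALSE)
  g <- pmax(g_at_x, floor)
  if (any(g <= 0))
    stop("degenerate density estimate: g_n <= 0 after flooring", call. = FALSE)
  g
}

#' Total-variation loss
#'
#' `0.5 * |1 - f(x; theta) / g_n(x)|`.  Bounded in \[0, 1/2\] and minimised
#' (at 0) where the model matches the density estimate exactly, so it is
#' deliberately not monotone in the predicted probability: over-prediction
#' is penalised just as under-prediction is.  Its expectation under the data
#' generating process is the TV-divergence up to the model-free entropy
#' term.
#'
#' @param f_at_x Model density value(s).
#' @param g_at_x Density-estimate value(s) at the same observation(s).
#' @param floor Density floor applied to `g_at_x` before the ratio.
#' @return Numeric vector of losses in \[0, 1/2\].
#' @export
loss_tv <- function(f_at_x, g_at_x, floor = density_floor()) {
  g <- .floor_g(g_at_x, floor)
  0.5 * abs(1 - f_at_x / g)
}

#' Hellinger loss
#'
#' `-sqrt(f(x; theta) / g_n(x))`, the empirical score whose negated sum
#' exponentiates into the Hellinger-targeting posterior.  Bounded above
#' by 0.
#'
#' @inheritParams loss_tv
#' @return Numeric vector of non-positive losses.
#' @export
loss_hellinger <- function(f_at_x, g_at_x, floor = density_floor()) {
  if (any(f_at_x < 0)) stop("model density must be non-negative", call. = FALSE)
  g <- .floor_g(g_at_x, floor)
  -sqrt(f_at_x / g)
}

#' Alpha-divergence loss
#'
#' `-(1 / (alpha (1 - alpha))) * g_n(x)^(alpha - 1) * f(x; theta)^(1 - alpha)`.
#' The exponent on `g_n` is one lower than in the divergence functional
#' because the remaining power of the data density is supplied by the
#' empirical expectation over observations.  The end points `alpha = 0, 1`
#' are excluded; the KL limit is available through
#' [divergence_functional()].
#'
#' @inheritParams loss_tv
#' @param alpha Alpha-divergence parameter, strictly inside (0, 1).
#' @return Numeric vector of non-positive losses.
#' @export
loss_alpha <- function(f_at_x, g_at_x, alpha, floor = density_floor()) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1)", call. = FALSE)
  if (any(f_at_x < 0)) stop("model density must be non-negative", call. = FALSE)
  g <- .floor_g(g_at_x, floor)
  -(1 / (alpha * (1 - alpha))) * g^(alpha - 1) * f_at_x^(1 - alpha)
}

#' Density-power-divergence loss
#'
#' `-(1/alpha) f(x; theta)^alpha + (1/(1+alpha)) int f(y; theta)^(1+alpha) dy`.
#' The only divergence loss in the menu that needs no estimate of the data
#' generating density; the extra information comes from the model through
#' its power integral, which is taken in closed form for Gaussian families
#' and by adaptive quadrature otherwise.
#'
#' @param x Observation(s); for conditional models a `list(X = , y = )`
#'   pair as accepted by [model_log_density()].
#' @param theta Named parameter vector for `model`.
#' @param alpha DPD parameter, `alpha > 0`.
#' @param model A [gaussian_model()] family object.
#' @return Numeric vector of losses (one per observation).
#' @export
loss_dpd <- function(x, theta, alpha, model) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  f <- exp(model_log_density(model, theta, x))
  pint <- power_integral(model, theta, alpha)
  -(1 / alpha) * f^alpha + pint / (1 + alpha)
}

#' Alpha-beta-divergence loss
#'
#' `-(1/(alpha beta)) g_n(x)^(alpha-1) f(x; theta)^beta
#'   + (1/(alpha (alpha+beta))) int f(z; theta)^(alpha+beta) dz`.
#' Setting `beta = 1 - alpha` recovers the alpha loss up to a
#' theta-independent constant (the integral term becomes `int f = 1`), and
#' `alpha = 1` recovers the DPD loss exactly.
#'
#' @inheritParams loss_dpd
#' @param f_at_x Model density value(s).
#' @param g_at_x Density-estimate value(s).
#' @param beta Second exponent; `alpha, beta > 0`.
#' @param floor Density floor applied to `g_at_x`.
#' @return Numeric vector of losses.
#' @export
loss_alphabeta <- function(f_at_x, g_at_x, alpha, beta, theta, model,
                           floor = density_floor()) {
  if (alpha <= 0 || beta <= 0 || alpha + beta == 0)
    stop("alphabeta loss requires alpha, beta > 0", call. = FALSE)
  g <- .floor_g(g_at_x, floor)
  pint <- power_integral(model, theta, alpha + beta - 1)
  -(1 / (alpha * beta)) * g^(alpha - 1) * f_at_x^beta +
    pint / (alpha * (alpha + beta))
}
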