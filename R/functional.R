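# Divergence functionals d(g, f) between density callables, by quadrature.
# These are diagnostic/testing tools; inference goes through the losses.

.quad <- function(fun, lower, upper, rel_tol) {
  r <- stats::integrate(fun, lower, upper, rel.tol = rel_tol,
                        subdivisions = 1000L, stop.on.error = FALSE)
  if (!r$message %in% c("OK", "roundoff error was detected"))
    stop("ill-posed quadrature: ", r$message, call. = FALSE)
  r$value
}

.quad2 <- function(fun2, support, n = 201L) {
  # tensor-grid trapezoid rule on a rectangle; bivariate densities only
  gx <- seq(support[1, 1], support[1, 2], length.out = n)
  gy <- seq(support[2, 1], support[2, 2], length.out = n)
  wx <- rep(1, n); wx[c(1, n)] <- 0.5
  vals <- outer(gx, gy, fun2)
  hx <- diff(gx[1:2]); hy <- diff(gy[1:2])
  sum((wx %o% wx) * vals) * hx * hy
}

#' Evaluate a divergence between two densities by quadrature
#'
#' Computes the chosen divergence functional `d(g, f)` between two density
#' callables on a stated finite support.  Univariate supports use adaptive
#' quadrature; bivariate densities are supported on tensor (rectangle)
#' grids by passing a 2 x 2 matrix of bounds.  Both densities must
#' integrate to one on the support within tolerance, otherwise an
#' ill-posed-quadrature error is raised.
#'
#' The functionals implemented are the KL divergence, total variation,
#' squared Hellinger `0.5 * int (sqrt(g) - sqrt(f))^2`, the alpha
#' divergence `(1 - int g^a f^(1-a)) / (a (1-a))`, the density power
#' (beta) divergence, the two-parameter alpha-beta divergence and the
#' S-Hellinger divergence `2/(1+a_S) int (g^((1+a_S)/2) - f^((1+a_S)/2))^2`.
#'
#' @param g,f Vectorised density functions (of one argument; of two
#'   arguments when `support` is a 2 x 2 matrix).
#' @param spec A [divergence_spec()].
#' @param support Numeric length-2 vector `c(lower, upper)`, or a 2 x 2
#'   matrix with one row of bounds per coordinate.
#' @param rel_tol Relative quadrature tolerance.
#' @param floor Density floor used inside logarithms and negative powers.
#' @return A single non-negative number (up to quadrature tolerance).
#' @examples
#' g <- function(z) dnorm(z)
#' f <- function(z) dnorm(z, 1, 1)
#' divergence_functional(g, f, divergence_spec("tv"), c(-10, 11))
#' @export
divergence_functional <- function(g, f, spec, support = c(-Inf, Inf),
                                  rel_tol = 1e-8, floor = density_floor()) {
  stopifnot(inherits(spec, "divergence_spec"))
  two_d <- is.matrix(support)
  quad <- if (two_d) {
    function(int) .quad2(int, support)
  } else {
    function(int) .quad(int, support[1], support[2], rel_tol)
  }

  mass_g <- quad(g)
  mass_f <- quad(f)
  if (abs(mass_g - 1) > 1e-3 || abs(mass_f - 1) > 1e-3)
    stop(sprintf(
      "ill-posed quadrature: densities integrate to %.4f and %.4f on the stated support",
      mass_g, mass_f), call. = FALSE)

  gv <- if (two_d) function(x, y) pmax(g(x, y), 0) else function(x) pmax(g(x), 0)
  fv <- if (two_d) function(x, y) pmax(f(x, y), 0) else function(x) pmax(f(x), 0)
  combine <- function(h) {
    if (two_d) function(x, y) h(gv(x, y), fv(x, y)) else function(x) h(gv(x), fv(x))
  }

  a <- spec$alpha; b <- spec$beta
  integrand <- switch(
    spec$name,
    kl = combine(function(gz, fz)
      ifelse(gz <= floor, 0, gz * (log(pmax(gz, floor)) - log(pmax(fz, floor))))),
    tv = combine(function(gz, fz) 0.5 * abs(gz - fz)),
    hellinger = combine(function(gz, fz) 0.5 * (sqrt(gz) - sqrt(fz))^2),
    alpha = combine(function(gz, fz) gz^a * fz^(1 - a)),
    dpd = combine(function(gz, fz)
      fz^(1 + a) / (1 + a) - fz^a * gz / a + gz^(1 + a) / (a * (1 + a))),
    alphabeta = combine(function(gz, fz)
      fz^(a + b) / (a * (a + b)) - gz^a * fz^b / (a * b) +
        gz^(a + b) / (b * (a + b))),
    s_hellinger = {
      s <- (1 + spec$alpha_s) / 2
      combine(function(gz, fz) (gz^s - fz^s)^2)
    })

  val <- quad(integrand)
  switch(spec$name,
         alpha = (1 - val) / (a * (1 - a)),
         s_hellinger = 2 * val / (1 + spec$alpha_s),
         val)
}

#' Hellinger distance between two Gaussian approximations
#'
#' Closed-form Hellinger distance `sqrt(1 - BC)` between two (possibly
#' multivariate) normal distributions, where `BC` is the Bhattacharyya
#' coefficient.  Used as the default posterior-discrepancy metric of the
#' influence diagnostics.
#'
#' @param m1,m2 Mean vectors.
#' @param S1,S2 Covariance matrices (scalars accepted in one dimension).
#' @return Hellinger distance in \[0, 1\].
#' @export
hellinger_gaussian <- function(m1, S1, m2, S2) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  Sb <- (S1 + S2) / 2
  d <- m1 - m2
  ld1 <- determinant(S1, logarithm = TRUE)$modulus
  ld2 <- determinant(S2, logarithm = TRUE)$modulus
  ldb <- determinant(Sb, logarithm = TRUE)$modulus
  log_bc <- 0.25 * (ld1 + ld2) - 0.5 * ldb -
    0.125 * sum(d * solve(Sb, d))
  h2 <- 1 - exp(as.numeric(log_bc))
  sqrt(max(h2, 0))
}
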