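#' Divergence specifications
#'
#' A `divergence_spec` names the statistical divergence whose minimiser the
#' general Bayesian update targets, together with its hyperparameters.  The
#' menu is: Kullback-Leibler (`"kl"`, standard Bayes), total variation
#' (`"tv"`), squared Hellinger (`"hellinger"`), the alpha-divergence family
#' (`"alpha"`, one free parameter `alpha` in (0,1)), the density-power /
#' beta divergence (`"dpd"`, `alpha > 0`), the two-parameter alpha-beta
#' family (`"alphabeta"`) and the S-Hellinger sub-family (`"s_hellinger"`,
#' parametrised by `alpha_s` in \[0,1\]).
#'
#' The TV, Hellinger, alpha and alpha-beta empirical losses require a kernel
#' density estimate of the data generating density; KL and DPD do not.  The
#' S-Hellinger divergence is exposed as a functional only (for limit and
#' identity checks); it is not available as a posterior target because its
#' two implicit hyperparameters trade off against each other in a way that
#' offers no practical advantage over the alpha and DPD sub-families.
#'
#' @param name One of `"kl"`, `"tv"`, `"hellinger"`, `"alpha"`, `"dpd"`,
#'   `"alphabeta"`, `"s_hellinger"` (case-insensitive).
#' @param alpha Dimensionless hyperparameter.  For `"alpha"` it must lie in
#'   (0,1) (values in (0.5, 1) interpolate between Hellinger-like robustness
#'   and KL-like efficiency); for `"dpd"` it must be positive; for
#'   `"alphabeta"` it is the first exponent.
#' @param beta Second exponent of the alpha-beta family; `alpha, beta >= 0`
#'   with `alpha + beta != 0` and `alpha * beta != 0`.
#' @param alpha_s S-Hellinger parameter in \[0,1\]; 0 recovers (twice) the
#'   squared Hellinger divergence, 1 the squared L2 divergence.
#' @param weight_w Positive calibration weight of the general Bayesian
#'   update.  The canonical divergence losses are already on the
#'   likelihood's natural scale, so the default is 1.
#'
#' @return An object of class `divergence_spec` with fields `name`, `alpha`,
#'   `beta`, `alpha_s`, `weight_w` and the derived flag
#'   `requires_density_estimate`.
#' @examples
#' divergence_spec("hellinger")
#' divergence_spec("alpha", alpha = 0.75)
#' divergence_spec("dpd", alpha = 0.5)
#' @export
divergence_spec <- function(name, alpha = NULL, beta = NULL, alpha_s = NULL,
                            weight_w = 1) {
  name <- match.arg(tolower(name),
                    c("kl", "tv", "hellinger", "alpha", "dpd",
                      "alphabeta", "s_hellinger"))
  if (!is.numeric(weight_w) || length(weight_w) != 1L || weight_w <= 0)
    stop("'weight_w' must be a single positive number", call. = FALSE)

  if (name == "alpha") {
    if (is.null(alpha) || alpha <= 0 || alpha >= 1)
      stop("alpha-divergence requires alpha in (0, 1)", call. = FALSE)
  } else if (name == "dpd") {
    if (is.null(alpha) || alpha <= 0)
      stop("density power divergence requires alpha > 0", call. = FALSE)
  } else if (name == "alphabeta") {
    if (is.null(alpha) || is.null(beta))
      stop("alphabeta divergence requires both alpha and beta", call. = FALSE)
    if (alpha < 0 || beta < 0 || alpha + beta == 0)
      stop("alphabeta divergence requires alpha, beta >= 0 and alpha + beta != 0",
           call. = FALSE)
    if (alpha * beta == 0)
      stop("alphabeta loss is undefined at alpha * beta == 0; use the kl or dpd limits",
           call. = FALSE)
  } else if (name == "s_hellinger") {
    if (is.null(alpha_s) || alpha_s < 0 || alpha_s > 1)
      stop("S-Hellinger divergence requires alpha_s in [0, 1]", call. = FALSE)
    ab <- convert_s_hellinger(alpha_s)
    alpha <- ab[["alpha"]]
    beta <- ab[["beta"]]
  }

  structure(
    list(name = name,
         alpha = alpha,
         beta = beta,
         alpha_s = alpha_s,
         weight_w = weight_w,
         requires_density_estimate =
           name %in% c("tv", "hellinger", "alpha", "alphabeta")),
    class = "divergence_spec")
}

#' @export
print.divergence_spec <- function(x, ...) {
  hp <- c(alpha = x$alpha, beta = x$beta, alpha_s = x$alpha_s)
  cat("<divergence_spec> ", x$name,
      if (length(hp)) paste0(" (", paste(names(hp), signif(hp, 4),
                                         sep = " = ", collapse = ", "), ")"),
      if (x$requires_density_estimate) "  [needs density estimate]",
      "\n", sep = "")
  invisible(x)
}

#' Map the S-Hellinger parameter to alpha-beta coordinates
#'
#' The S-Hellinger divergences form the `lambda = -1/2` slice of the
#' S-divergence family; inside the alpha-beta family they sit at
#' `alpha = beta = (1 + alpha_s) / 2`, so `alpha + beta = 1 + alpha_s`.
#' For `alpha_s` in \[0,1\] this gives `alpha < 1` (outlier ratios are
#' down-weighted) and `alpha + beta > 1` (low model density is
#' down-weighted), except at the Hellinger end point `alpha_s = 0`.
#'
#' @param alpha_s S-Hellinger parameter in \[0,1\].
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' convert_s_hellinger(0)    # alpha = beta = 1/2: the Hellinger point
#' convert_s_hellinger(1)    # alpha = beta = 1: the squared L2 point
#' @export
convert_s_hellinger <- function(alpha_s) {
  if (!is.numeric(alpha_s) || length(alpha_s) != 1L ||
      is.na(alpha_s) || alpha_s < 0 || alpha_s > 1)
    stop("'alpha_s' must be a single number in [0, 1]", call. = FALSE)
  a <- (1 + alpha_s) / 2
  c(alpha = a, beta = a)
}

#' Default density floor
#'
#' Density-ratio losses clip the estimated data generating density away from
#' zero before forming ratios `f / g_n`, so that a single extreme
#' observation with vanishing estimated density cannot produce an infinite
#' or undefined loss.
#'
#' @return The floor value, `getOption("divbayes.density_floor", 1e-12)`.
#' @export
density_floor <- function() {
  getOption("divbayes.density_floor", 1e-12)
}
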