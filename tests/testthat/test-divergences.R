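test_that("divergence specs validate their hyperparameters", {
  expect_error(divergence_spec("alpha"), "alpha in \\(0, 1\\)")
  expect_error(divergence_spec("alpha", alpha = 1), "alpha in \\(0, 1\\)")
  expect_error(divergence_spec("dpd", alpha = -0.1), "alpha > 0")
  expect_error(divergence_spec("alphabeta", alpha = 0.5, beta = 0))
  expect_error(divergence_spec("s_hellinger", alpha_s = 1.2), "\\[0, 1\\]")
  expect_error(divergence_spec("kl", weight_w = 0), "positive")

  needs <- vapply(c("tv", "hellinger"), function(nm)
    divergence_spec(nm)$requires_density_estimate, TRUE)
  expect_true(all(needs))
  expect_true(divergence_spec("alpha", alpha = 0.7)$requires_density_estimate)
  expect_true(divergence_spec("alphabeta", alpha = 0.5,
                              beta = 0.7)$requires_density_estimate)
  expect_false(divergence_spec("kl")$requires_density_estimate)
  expect_false(divergence_spec("dpd", alpha = 0.5)$requires_density_estimate)
  expect_identical(divergence_spec("kl")$weight_w, 1)
})

test_that("loss functions match their closed forms and bounds", {
  # logarithmic score
  expect_equal(loss_kl(1), 0)
  expect_equal(loss_kl(exp(-1)), 1)
  expect_equal(loss_kl(dnorm(0)), 0.5 * log(2 * pi), tolerance = 1e-6)
  expect_equal(loss_kl(0), Inf)
  expect_equal(loss_kl(0, cap = 100), 100)
  expect_error(loss_kl(-1), "non-negative")

  # total variation: 0 at f = g, 1/2 at f = 0 and f = 2g
  g <- 0.37
  expect_equal(loss_tv(g, g), 0)
  expect_equal(loss_tv(0, g), 0.5)
  expect_equal(loss_tv(2 * g, g), 0.5)
  expect_error(loss_tv(0.1, -0.1), "non-negative")

  # Hellinger
  expect_equal(loss_hellinger(g, g), -1)
  expect_equal(loss_hellinger(0, g), 0)
  expect_equal(loss_hellinger(4 * g, g), -2)

  # alpha
  expect_equal(loss_alpha(g, g, 0.5), -4)
  expect_equal(loss_alpha(g, g, 0.75), -16 / 3)
  expect_equal(loss_alpha(0, g, 0.6), 0)
  expect_error(loss_alpha(g, g, 1), "strictly in")

  # vectorisation and range invariants; the TV loss stays in [0, 1/2] on
  # f <= 2 g_n (and in particular throughout the tails, where f -> 0)
  set.seed(1)
  gg <- runif(50, 0.2, 2)
  f <- runif(50, 0, 2 * gg)
  expect_true(all(loss_tv(f, gg) >= 0 & loss_tv(f, gg) <= 0.5))
  expect_true(all(loss_hellinger(f, gg) <= 0))
  expect_true(all(loss_alpha(f, gg, 0.75) <= 0))
})

test_that("the TV loss is minimised exactly at f = g_n", {
  g <- 0.8
  fgrid <- seq(0, 3, by = 0.01)
  losses <- loss_tv(fgrid, g)
  expect_equal(fgrid[which.min(losses)], g)
  # not monotone in f: increases again past the match point
  expect_gt(loss_tv(2.5, g), loss_tv(g, g))
})

test_that("the DPD loss uses the Gaussian power integral", {
  model <- gaussian_model()
  theta <- c(0, 1)
  # oracle: adaptive quadrature of phi(y)^(3/2)
  pint_quad <- integrate(function(y) dnorm(y)^1.5, -Inf, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(power_integral(model, theta, 0.5), pint_quad, tolerance = 1e-8)
  expect_equal(pint_quad, 0.5157146, tolerance = 1e-6)

  l0 <- loss_dpd(0, theta, 0.5, model)
  expect_equal(l0, -2 * dnorm(0)^0.5 + (2 / 3) * pint_quad, tolerance = 1e-10)
  expect_equal(l0, -0.9194283, tolerance = 1e-6)

  # vanishing model density leaves only the non-negative integral term
  lfar <- loss_dpd(60, theta, 0.5, model)
  expect_equal(lfar, pint_quad / 1.5, tolerance = 1e-10)
  expect_gte(lfar, 0)
})

test_that("Gaussian power integral closed form agrees with quadrature", {
  for (sigma in c(0.3, 1, 2.7)) {
    for (alpha in c(0.1, 0.5, 1, 2)) {
      quad <- integrate(function(y) dnorm(y, 0, sigma)^(1 + alpha),
                        -Inf, Inf, rel.tol = 1e-12)$value
      expect_equal(gaussian_power_integral(sigma, alpha), quad,
                   tolerance = 1e-8)
    }
  }
})

test_that("the alpha-beta loss nests the alpha and DPD losses", {
  model <- gaussian_model()
  theta <- c(0.3, 1.2)
  x <- seq(-3, 3, length.out = 21)
  f <- exp(model_log_density(model, theta, x))
  g <- dnorm(x, 0, 1.5)

  # beta = 1 - alpha: equal to the alpha loss up to the theta-independent
  # constant 1/alpha (the integral term with int f = 1)
  for (a in c(0.3, 0.5, 0.75)) {
    d <- loss_alphabeta(f, g, a, 1 - a, theta, model) - loss_alpha(f, g, a)
    expect_equal(d, rep(1 / a, length(x)), tolerance = 1e-12)
  }

  # alpha = 1 reproduces the DPD loss exactly
  for (b in c(0.25, 0.5, 1)) {
    expect_equal(loss_alphabeta(f, g, 1, b, theta, model),
                 loss_dpd(x, theta, b, model), tolerance = 1e-12)
  }

  # vanishing model density kills the first term
  expect_equal(loss_alphabeta(0, 0.4, 0.5, 0.7, theta, model),
               gaussian_power_integral(1.2, 0.2) / (0.5 * 1.2))
})

test_that("divergence functionals match Gaussian closed forms", {
  g <- function(z) dnorm(z)
  f <- function(z) dnorm(z, 1, 1)
  sup <- c(-12, 13)
  expect_equal(divergence_functional(g, f, divergence_spec("tv"), sup),
               2 * pnorm(0.5) - 1, tolerance = 1e-6)
  expect_equal(divergence_functional(g, f, divergence_spec("hellinger"), sup),
               1 - exp(-1 / 8), tolerance = 1e-6)
  expect_equal(divergence_functional(g, f, divergence_spec("kl"), sup),
               0.5, tolerance = 1e-6)

  # zero at g = f for every family
  for (spec in list(divergence_spec("kl"), divergence_spec("tv"),
                    divergence_spec("hellinger"),
                    divergence_spec("alpha", alpha = 0.7),
                    divergence_spec("dpd", alpha = 0.5),
                    divergence_spec("alphabeta", alpha = 0.6, beta = 0.8),
                    divergence_spec("s_hellinger", alpha_s = 0.4))) {
    expect_equal(divergence_functional(g, g, spec, sup), 0, tolerance = 1e-6)
  }

  # non-densities on the support are rejected
  expect_error(
    divergence_functional(function(z) dnorm(z, 0, 10), f,
                          divergence_spec("tv"), c(-2, 2)),
    "ill-posed")
})

test_that("divergence inequalities hold on random density pairs", {
  for (seed in 1:20) {
    pair <- random_density_pair(seed)
    tv <- div_of(pair, divergence_spec("tv"))
    h2 <- div_of(pair, divergence_spec("hellinger"))
    kl <- div_of(pair, divergence_spec("kl"))
    tol <- 1e-7

    expect_gte(tv, -tol); expect_lte(tv, 1 + tol)
    expect_gte(h2, -tol); expect_gte(kl, -tol)

    # Hellinger sandwich: h2 <= tv <= sqrt(h2 (2 - h2))
    expect_lte(h2, tv + tol)
    expect_lte(tv, sqrt(h2 * (2 - h2)) + tol)

    # alpha(1-alpha) d_alpha <= tv, over an alpha grid
    for (a in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
      da <- div_of(pair, divergence_spec("alpha", alpha = a))
      expect_lte(a * (1 - a) * da, tv + tol)
    }

    # Pinsker: tv <= sqrt(kl / 2)
    expect_lte(tv, sqrt(kl / 2) + tol)

    # alpha = 0.5 is four times the squared Hellinger divergence
    expect_equal(div_of(pair, divergence_spec("alpha", alpha = 0.5)),
                 4 * h2, tolerance = 1e-6)
  }
})

test_that("alpha and DPD divergences approach KL in their limits", {
  g <- function(z) dnorm(z, 0, 1.3)
  f <- function(z) dnorm(z, 0.8, 1)
  sup <- c(-15, 15)
  kl <- divergence_functional(g, f, divergence_spec("kl"), sup)

  err_a <- vapply(c(0.99, 0.999), function(a)
    abs(divergence_functional(g, f, divergence_spec("alpha", alpha = a), sup) - kl),
    0)
  expect_lt(err_a[2], err_a[1])
  expect_lt(err_a[2], 0.01)

  err_d <- vapply(c(0.01, 0.001), function(a)
    abs(divergence_functional(g, f, divergence_spec("dpd", alpha = a), sup) - kl),
    0)
  expect_lt(err_d[2], err_d[1])
  expect_lt(err_d[2], 0.01)
})

test_that("the S-Hellinger parametrisation maps into the alpha-beta family", {
  expect_equal(convert_s_hellinger(0), c(alpha = 0.5, beta = 0.5))
  expect_equal(convert_s_hellinger(1), c(alpha = 1, beta = 1))
  ab <- convert_s_hellinger(0.5)
  expect_equal(unname(ab["alpha"] + ab["beta"]), 1.5)
  expect_error(convert_s_hellinger(-0.1), "\\[0, 1\\]")

  g <- function(z) dnorm(z)
  f <- function(z) dnorm(z, 1, 1)
  sup <- c(-12, 13)
  h2 <- divergence_functional(g, f, divergence_spec("hellinger"), sup)
  # alpha_s = 0: twice int (sqrt g - sqrt f)^2 = 4 x the (1/2-convention)
  # squared Hellinger divergence
  expect_equal(
    divergence_functional(g, f, divergence_spec("s_hellinger", alpha_s = 0), sup),
    4 * h2, tolerance = 1e-6)
  # alpha_s = 1: the squared L2 divergence
  l2 <- integrate(function(z) (g(z) - f(z))^2, -12, 13,
                  rel.tol = 1e-10)$value
  expect_equal(
    divergence_functional(g, f, divergence_spec("s_hellinger", alpha_s = 1), sup),
    l2, tolerance = 1e-6)
  # posterior construction is refused for the functional-only family
  expect_error(
    build_general_posterior(prior_location_scale(), gaussian_model(),
                            divergence_spec("s_hellinger", alpha_s = 0.3),
                            rnorm(20), g_values = rep(0.3, 20)),
    "functional only")
})

test_that("bivariate divergence functionals work on tensor grids", {
  g2 <- function(x, y) dnorm(x) * dnorm(y)
  f2 <- function(x, y) dnorm(x, 0.5, 1) * dnorm(y)
  sup <- rbind(c(-8, 8.5), c(-8, 8))
  h2 <- divergence_functional(g2, f2, divergence_spec("hellinger"), sup)
  # product structure: 1 - BC_x * BC_y with BC_y = 1
  expect_equal(h2, 1 - exp(-0.5^2 / 8), tolerance = 1e-4)
})
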