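test_that("the log-target reduces to the prior on empty data", {
  post <- build_general_posterior(prior_location_scale(), gaussian_model(),
                                  divergence_spec("kl"), numeric(0))
  for (u in list(c(0, 0), c(1, -0.5), c(-3, 0.7))) {
    manual <- log_prior(prior_location_scale(), u[1], exp(u[2])) + u[2]
    expect_equal(post$log_target(u), manual)
  }
  # a required density estimate cannot be omitted
  expect_error(
    build_general_posterior(prior_location_scale(), gaussian_model(),
                            divergence_spec("tv"), rnorm(10)),
    "requires a density estimate")
})

test_that("the KL log-target matches the conjugate posterior up to a constant", {
  set.seed(21)
  n <- 60
  X <- cbind(rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, -2)) + rnorm(n, sd = 0.7)
  prior <- prior_regression(2)
  post <- build_general_posterior(prior, regression_model(2),
                                  divergence_spec("kl"), list(X = X, y = y))
  cp <- conjugate_regression_posterior(X, y, prior)
  diffs <- replicate(100, {
    u <- c(rnorm(2), rnorm(1, 0, 0.4))
    post$log_target(u) -
      (conjugate_log_density(cp, u[1:2], exp(2 * u[3])) + 2 * u[3])
  })
  expect_lt(max(diffs) - min(diffs), 1e-8)
})

test_that("a TV posterior with f = g_n at every observation is the prior", {
  set.seed(22)
  x <- rnorm(30)
  theta0 <- c(0.3, 1.1)
  g_vals <- dnorm(x, theta0[1], theta0[2])  # pretend g_n is the model itself
  post <- build_general_posterior(prior_location_scale(), gaussian_model(),
                                  divergence_spec("tv"), x, g_values = g_vals)
  prior_only <- build_general_posterior(prior_location_scale(),
                                        gaussian_model(),
                                        divergence_spec("tv"), numeric(0),
                                        g_values = numeric(0))
  u0 <- c(theta0[1], log(theta0[2]))
  expect_equal(post$log_target(u0), prior_only$log_target(u0))
})

test_that("the sampler is calibrated on a known target and is deterministic", {
  tgt <- list(log_target = function(u) dnorm(u, log = TRUE), n_params = 1L,
              to_natural = identity, param_names = "z", init_u = 0)
  s <- sample_posterior(tgt, 50000, 5000, seed = 2)
  expect_lt(abs(mean(s$draws)), 0.03)
  expect_lt(abs(sd(s$draws) - 1), 0.03)
  expect_gt(s$accept_rate, 0.15)
  expect_lt(s$accept_rate, 0.4)

  s2 <- sample_posterior(tgt, 50000, 5000, seed = 2)
  expect_identical(s$draws, s2$draws)
  s3 <- sample_posterior(tgt, 5000, 1000, seed = 3)
  expect_false(identical(s3$draws[1:10], s$draws[1:10]))
})

test_that("KL MCMC matches the conjugate oracle on a regression model", {
  set.seed(23)
  n <- 80
  X <- matrix(rnorm(n), n, 1)
  y <- drop(X * 1.2) + rnorm(n, sd = 0.8)
  prior <- prior_regression(1)
  post <- build_general_posterior(prior, regression_model(1),
                                  divergence_spec("kl"), list(X = X, y = y))
  s <- sample_posterior(post, 15000, 5000, seed = 24)
  cp <- conjugate_regression_posterior(X, y, prior)
  s2_draws <- s$draws[, 2]^2
  mc_se <- sd(s2_draws) / sqrt(min(s$ess[2], length(s2_draws)))
  expect_lt(abs(mean(s2_draws) - cp$sigma2_mean), max(4 * mc_se, 0.02))
  expect_lt(abs(mean(s$draws[, 1]) - cp$beta_mean), 0.03)

  # support constraints respected by every draw
  expect_true(all(s$draws[, 2] > 0))
})

test_that("all five divergence posteriors recover M-closed parameters", {
  set.seed(99)
  x <- rnorm(2000, 1, 2)
  est <- fit_kde(x)
  for (nm in names(default_divergences())) {
    dv <- default_divergences()[[nm]]
    post <- build_general_posterior(prior_location_scale(), gaussian_model(),
                                    dv, x, density_estimate = est)
    s <- sample_posterior(post, 6000, 2500, seed = 3)
    expect_lt(abs(mean(s$draws[, "mu"]) - 1), 0.25)
    expect_lt(abs(mean(s$draws[, "sigma"]) - 2), 0.3)
  }
})

test_that("robust divergences resist epsilon-contamination where KL cannot", {
  res <- run_simple_inference("contaminated_normal", n = 1000,
                              divergences = c("kl", "tv", "alpha", "power"),
                              seed = 5, n_iter = 6000, burn_in = 2500)
  sig <- setNames(res$summary$sigma, res$summary$divergence)
  expect_gt(sig["kl"], sig["power"])
  expect_gt(sig["kl"], sig["tv"])
  expect_gt(sig["kl"], sig["alpha"])
})

test_that("bounded scores leave posterior tails prior-driven", {
  # TV data term is bounded by n/2, so a tight prior far from the data wins
  set.seed(5)
  x <- rnorm(200)
  post <- build_general_posterior(
    prior_location_scale(mu_mean = 50, mu_sd = 1), gaussian_model(),
    divergence_spec("tv"), x, density_estimate = fit_kde(x))
  s <- sample_posterior(post, 6000, 2500, seed = 3)
  expect_gt(mean(s$draws[, "mu"]), 45)
})

test_that("posterior predictives integrate to one and respect point masses", {
  set.seed(25)
  x <- rnorm(300, 2, 1.5)
  post <- build_general_posterior(prior_location_scale(), gaussian_model(),
                                  divergence_spec("kl"), x)
  s <- sample_posterior(post, 4000, 1500, seed = 26)
  grid <- seq(-8, 12, length.out = 801)
  pd <- predictive_density(s, grid)
  expect_equal(sum(pd$density) * diff(grid[1:2]), 1, tolerance = 1e-4)

  # a single draw gives back exactly f(. ; theta^(1))
  s1 <- s
  s1$draws <- s$draws[1, , drop = FALSE]
  pd1 <- predictive_density(s1, grid)
  expect_equal(pd1$density, dnorm(grid, s$draws[1, 1], s$draws[1, 2]))

  # AR(1) point mass at mu = (0, 0.9): one-step mean is 0.9 x previous value
  samp <- structure(list(draws = matrix(c(0, 0.9, 1), 1, 3,
                                        dimnames = list(NULL,
                                                        c("mu0", "mu1", "sigma")))),
                    class = "posterior_samples")
  test_series <- c(1, 2, -1)
  pr <- predictive_ar_onestep(samp, test_series, history = 5)
  expect_equal(pr$mean, 0.9 * c(5, 1, 2))
  expect_warning(pr0 <- predictive_ar_onestep(samp, numeric(0), history = 5),
                 "zero-length")
  expect_length(pr0$mean, 0)
})
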