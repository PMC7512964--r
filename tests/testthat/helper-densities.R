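# Random density pairs (Gaussians and two-component mixtures) for the
# divergence property tests.
random_density_pair <- function(seed) {
  set.seed(seed)
  make <- function() {
    if (runif(1) < 0.5) {
      m <- runif(1, -2, 2); s <- runif(1, 0.5, 2)
      function(z) dnorm(z, m, s)
    } else {
      m1 <- runif(1, -2, 0); m2 <- runif(1, 0, 3)
      s1 <- runif(1, 0.4, 1.5); s2 <- runif(1, 0.4, 1.5)
      w <- runif(1, 0.2, 0.8)
      function(z) w * dnorm(z, m1, s1) + (1 - w) * dnorm(z, m2, s2)
    }
  }
  list(g = make(), f = make(), support = c(-30, 30))
}

div_of <- function(pair, spec) {
  divergence_functional(pair$g, pair$f, spec, pair$support)
}
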