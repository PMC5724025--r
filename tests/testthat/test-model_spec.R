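test_that("mean/concentration and elicitation reparameterizations give the stated shapes", {
  expect_equal(beta_shapes_from_mean_concentration(0.8, 5), c(a = 4, b = 1))
  expect_equal(beta_shapes_from_mean_concentration(0.5, 2), c(a = 1, b = 1))
  expect_equal(beta_shapes_from_mean_concentration(0.1, 25),
               c(a = 2.5, b = 22.5))
  expect_equal(elicit_beta_prior(0.80, 5), c(a = 4, b = 1))
  expect_equal(elicit_beta_prior(0.9, 10), c(a = 9, b = 1))
  # the two parameterizations agree when kappa = n, mu = m
  for (m in c(0.1, 0.5, 0.93)) for (n in c(0.5, 2, 40)) {
    expect_equal(beta_shapes_from_mean_concentration(m, n),
                 elicit_beta_prior(m, n))
  }
  expect_error(beta_shapes_from_mean_concentration(0, 5), "mu")
  expect_error(beta_shapes_from_mean_concentration(0.5, -1), "kappa")
  expect_error(elicit_beta_prior(1.2, 5), "m")
})

test_that("gamma mean/SD re-expression matches the printed prior and inverts exactly", {
  expect_equal(gamma_shape_rate_from_mean_sd(10, 10),
               c(shape = 1.0, rate = 0.1))
  expect_equal(gamma_shape_rate_from_mean_sd(10, sqrt(10)),
               c(shape = 10, rate = 1))
  # inversion: mean = shape/rate, sd = sqrt(shape)/rate
  for (mn in c(0.2, 3.2, 17)) for (s in c(0.4, 1.7, 9)) {
    sr <- gamma_shape_rate_from_mean_sd(mn, s)
    expect_equal(unname(sr["shape"] / sr["rate"]), mn, tolerance = 1e-12)
    expect_equal(unname(sqrt(sr["shape"]) / sr["rate"]), s,
                 tolerance = 1e-12)
  }
  # Monte Carlo moment oracle
  set.seed(42)
  sr <- gamma_shape_rate_from_mean_sd(3.2, 1.7)
  x <- rgamma(1e6, sr["shape"], sr["rate"])
  expect_equal(mean(x), 3.2, tolerance = 0.01)
  expect_equal(sd(x), 1.7, tolerance = 0.01)
  expect_error(gamma_shape_rate_from_mean_sd(-1, 1), "positive")
})

test_that("prior conditions carry the stated shapes", {
  c1 <- prior_condition("C1")
  expect_equal(c(c1$a_mu, c1$b_mu), c(4, 1))
  c2 <- prior_condition("C2")
  expect_equal(c(c2$a_mu, c2$b_mu), c(1, 1))
  expect_error(prior_condition("C3"))
})

test_that("model_spec serializes to JSON and back", {
  spec <- model_spec("B", "C1", kappa_prior(8, 4),
                     b_bounds = c(0.5, 60, 0.5, 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_spec(spec, path)
  spec2 <- read_model_spec(path)
  expect_equal(spec2$family, "B")
  expect_equal(spec2$prior$label, "C1")
  expect_equal(spec2$kappa_prior$shape, spec$kappa_prior$shape)
  expect_equal(spec2$b_bounds, spec$b_bounds)
})

test_that("log_likelihood matches a directly coded binomial pmf", {
  d1 <- visit_dataset(data.frame(treatment = "CT", insect_id = "a",
                                 taxon = "bee", z = 1L, n = 1L))
  expect_equal(log_likelihood(list(theta = 0.5), d1), log(0.5))
  d2 <- visit_dataset(data.frame(treatment = "CT", insect_id = "a",
                                 taxon = "bee", z = 2L, n = 10L))
  hand <- lchoose(10, 2) + 2 * log(0.2) + 8 * log(0.8)
  expect_equal(log_likelihood(list(theta = 0.2), d2), hand)
  # theta = z/n maximizes the likelihood trail-wise
  d <- toy_dataset()
  mle <- d$trails$z / d$trails$n
  mle[mle == 0] <- 1e-9  # boundary handled on the open interval
  base <- log_likelihood(list(theta = mle), d)
  set.seed(1)
  for (k in 1:5) {
    pert <- pmin(pmax(mle + runif(3, -0.1, 0.1), 1e-6), 1 - 1e-6)
    expect_lte(log_likelihood(list(theta = pert), d), base + 1e-12)
  }
  expect_error(log_likelihood(list(theta = c(0.5, 0.5)), d), "length")
})

test_that("log_prior matches a term-by-term hand computation (A2-C1, 3-trail toy)", {
  d <- toy_dataset()
  spec <- model_spec("A2", "C1")
  st <- init_state(spec, d, theta = c(0.1, 0.2, 0.3),
                   mu = c(0.15, 0.25), kappa = c(12, 7))
  hand <- dbeta(0.1, 0.15 * 12, 0.85 * 12, log = TRUE) +
    dbeta(0.2, 0.15 * 12, 0.85 * 12, log = TRUE) +
    dbeta(0.3, 0.25 * 7, 0.75 * 7, log = TRUE) +
    dbeta(0.15, 4, 1, log = TRUE) + dbeta(0.25, 4, 1, log = TRUE) +
    dgamma(12, 1, 0.1, log = TRUE) + dgamma(7, 1, 0.1, log = TRUE)
  expect_equal(log_prior(st, spec, d), hand)
})

test_that("C2 makes the mu prior contribution vanish and supports are enforced", {
  d <- toy_dataset()
  s1 <- model_spec("A2", "C1")
  s2 <- model_spec("A2", "C2")
  st <- init_state(s1, d, theta = c(0.1, 0.2, 0.3), mu = c(0.15, 0.25),
                   kappa = c(12, 7))
  # C1 vs C2 differ exactly by the Beta(4,1) log densities of the mus
  expect_equal(log_prior(st, s1, d) - log_prior(st, s2, d),
               dbeta(0.15, 4, 1, log = TRUE) + dbeta(0.25, 4, 1, log = TRUE))
  # family B: hyperparameters outside their uniform bounds
  sb <- model_spec("B", "C2")
  stb <- init_state(sb, d)
  stb$mu_gamma <- 1000
  expect_identical(log_prior(stb, sb, d), -Inf)
  # theta on the boundary is outside the Beta support
  st0 <- st
  st0$theta[1] <- 0
  expect_identical(log_posterior(st0, s1, d), -Inf)
})

test_that("A1 and A2 priors agree at equal kappas up to the extra gamma terms", {
  d <- simulate_dataset(small_design(), seed = 3)
  sA1 <- model_spec("A1", "C2")
  sA2 <- model_spec("A2", "C2")
  st1 <- init_state(sA1, d, kappa = 14)
  st2 <- init_state(sA2, d, kappa = rep(14, 3))
  st2$theta <- st1$theta
  st2$mu <- st1$mu
  E <- 3
  expect_equal(log_prior(st1, sA1, d),
               log_prior(st2, sA2, d) -
                 (E - 1) * dgamma(14, 1, 0.1, log = TRUE))
})

test_that("log_posterior is additive and continuous in each coordinate", {
  d <- toy_dataset()
  spec <- model_spec("A2", "C2")
  a <- init_state(spec, d, theta = c(0.1, 0.2, 0.3), mu = c(0.15, 0.25),
                  kappa = c(12, 7))
  b <- a
  b$theta[2] <- 0.35
  expect_equal(log_posterior(b, spec, d) - log_posterior(a, spec, d),
               (log_likelihood(b, d) - log_likelihood(a, d)) +
                 (log_prior(b, spec, d) - log_prior(a, spec, d)))
  # finite-difference smoothness along mu_1
  eps <- 1e-6
  grid <- seq(0.05, 0.9, by = 0.05)
  lp <- vapply(grid, function(m) {
    s <- a; s$mu[1] <- m
    log_posterior(s, spec, d)
  }, numeric(1))
  lp_eps <- vapply(grid + eps, function(m) {
    s <- a; s$mu[1] <- m
    log_posterior(s, spec, d)
  }, numeric(1))
  expect_true(all(abs(lp_eps - lp) < 1e-3))
})

test_that("the 1-trail unnormalized posterior integrates to a finite constant", {
  d1 <- visit_dataset(data.frame(treatment = "CT", insect_id = "a",
                                 taxon = "bee", z = 3L, n = 9L))
  spec <- model_spec("A2", "C2")
  th <- seq(0.005, 0.995, length.out = 80)
  mu <- seq(0.005, 0.995, length.out = 80)
  ka <- seq(0.05, 80, length.out = 80)
  # independent term-by-term density product over the grid
  tot <- 0
  for (m in mu) for (k in ka) {
    dens <- dbinom(3, 9, th) * dbeta(th, m * k, (1 - m) * k) *
      dgamma(k, 1, 0.1)
    tot <- tot + sum(dens) * diff(th[1:2]) * diff(mu[1:2]) * diff(ka[1:2])
  }
  expect_true(is.finite(tot) && tot > 0)
  # and exp(log_posterior) agrees with that product at spot-checked nodes
  set.seed(9)
  for (i in 1:20) {
    t0 <- sample(th, 1); m0 <- sample(mu, 1); k0 <- sample(ka, 1)
    st <- list(theta = t0, mu = m0, kappa = k0)
    expect_equal(exp(log_posterior(st, spec, d1)),
                 dbinom(3, 9, t0) * dbeta(t0, m0 * k0, (1 - m0) * k0) *
                   dgamma(k0, 1, 0.1),
                 tolerance = 1e-12)
  }
})
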