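# Shared fixtures, built in code.

toy_trails <- function() {
  data.frame(
    treatment = c("CT", "CT", "MMT"),
    insect_id = c("i1", "i2", "i3"),
    taxon = "bee",
    z = c(1L, 0L, 2L),
    n = c(9L, 5L, 6L),
    stringsAsFactors = FALSE)
}

toy_dataset <- function() visit_dataset(toy_trails())

# Small 3-treatment design for fast sampler tests.
small_design <- function(J = 8, lambda = 6,
                         mu = c(0.12, 0.07, 0.17),
                         kappa = c(20, 15, 18)) {
  simulation_design(labels = c("CT", "MMT", "MFT"),
                    n_trails = rep(J, 3), lambda = rep(lambda, 3),
                    mu = mu, kappa = kappa)
}

quick_config <- function(n_chains = 2, n_iter = 3000, burn_in = 600,
                         master_seed = 1) {
  mcmc_config(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
              master_seed = master_seed)
}

# Hand-rolled chain_set for summary/DIC unit tests that do not need a
# sampler run: `draws` is a named-column matrix (or list of them).
fake_chain_set <- function(draws, theta_mean = NULL,
                           arr = NULL) {
  if (is.matrix(draws)) draws <- list(draws)
  pn <- setdiff(colnames(draws[[1]]), "deviance")
  structure(list(chains = draws,
                 theta_mean = theta_mean,
                 theta_draws = NULL,
                 param_names = pn,
                 spec = NULL, config = NULL, arr = arr,
                 likelihood = TRUE, acceptance_rates = NULL),
            class = "chain_set")
}

# Brute-force HDI: examine every contiguous window of the sorted sample
# holding ceiling(mass * n) draws; smallest width wins, lowest start
# breaks ties.  Kept deliberately naive and independent of hdi().
brute_force_hdi <- function(x, mass = 0.95) {
  s <- sort(x)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    lo <- s[i]
    hi <- s[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}
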