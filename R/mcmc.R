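#' MCMC run configuration
#'
#' Defaults follow the study protocol: 4 chains of 50,000 iterations with a
#' 10,000-iteration burn-in (families A1/A2); family B, whose overarching
#' hyperparameters mix more slowly, uses 100,000 iterations with 40,000
#' burn-in (see [default_mcmc_config()]).  Proposal scales adapt only
#' during the first `adapt_iters` iterations (default: the whole burn-in),
#' so the post-adaptation chain is a fixed-kernel Markov chain with the
#' correct stationary law.
#'
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded, `< n_iter`.
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param master_seed integer; chain c runs under seed `master_seed + c`.
#' @param adapt_iters iterations of proposal adaptation (<= burn_in).
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 50000, burn_in = 10000,
                        thin = 1, master_seed = 1,
                        adapt_iters = burn_in) {
  stopifnot(n_chains >= 1, n_iter >= 1, burn_in >= 0, burn_in < n_iter,
            thin >= 1, adapt_iters <= burn_in)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 master_seed = as.integer(master_seed),
                 adapt_iters = as.integer(adapt_iters)),
            class = "mcmc_config")
}

#' Study-protocol MCMC configuration for a model family
#'
#' @param spec a [model_spec()].
#' @param master_seed master seed.
#' @return [mcmc_config()] with 4 x 50,000 (burn-in 10,000), or
#'   4 x 100,000 (burn-in 40,000) for family B.
#' @export
default_mcmc_config <- function(spec, master_seed = 1) {
  if (spec$family == "B")
    mcmc_config(4, 100000, 40000, master_seed = master_seed)
  else
    mcmc_config(4, 50000, 10000, master_seed = master_seed)
}

# Constants the block updates need, precomputed once per run.
model_consts <- function(spec, likelihood = TRUE) {
  list(A = spec$prior$a_mu, B = spec$prior$b_mu,
       kshape = spec$kappa_prior$shape, krate = spec$kappa_prior$rate,
       family = spec$family, bb = spec$b_bounds, lik = likelihood)
}

# --- block updates ---------------------------------------------------------
# All operate on plain vectors; `arr` is dataset_arrays() output.

step_theta <- function(th, mu, kap, arr, cn) {
  ke <- if (cn$family == "A1") rep.int(kap, arr$E) else kap
  a <- (mu * ke)[arr$e]
  b <- ((1 - mu) * ke)[arr$e]
  if (cn$lik) rbeta(arr$J, arr$z + a, arr$n - arr$z + b)
  else rbeta(arr$J, a, b)
}

step_mu <- function(th, mu, kap, arr, cn, scales) {
  acc <- logical(arr$E)
  for (e in seq_len(arr$E)) {
    k <- if (cn$family == "A1") kap else kap[e]
    the <- th[arr$idx[[e]]]
    m1 <- mu[e]
    l1 <- sum(dbeta(the, m1 * k, (1 - m1) * k, log = TRUE)) +
      dbeta(m1, cn$A, cn$B, log = TRUE)
    z <- log(m1 / (1 - m1)) + rnorm(1, 0, scales[e])
    m2 <- 1 / (1 + exp(-z))
    if (m2 > 0 && m2 < 1) {
      l2 <- sum(dbeta(the, m2 * k, (1 - m2) * k, log = TRUE)) +
        dbeta(m2, cn$A, cn$B, log = TRUE)
      lr <- l2 - l1 + log(m2 * (1 - m2)) - log(m1 * (1 - m1))
      if (is.finite(lr) && log(runif(1)) < lr) {
        mu[e] <- m2
        acc[e] <- TRUE
      }
    }
  }
  list(mu = mu, acc = acc)
}

kappa_log_prior <- function(k, cn, hy) {
  if (cn$family == "B") {
    sr <- c(hy[1]^2 / hy[2]^2, hy[1] / hy[2]^2)
    dgamma(k, sr[1], sr[2], log = TRUE)
  } else {
    dgamma(k, cn$kshape, cn$krate, log = TRUE)
  }
}

step_kappa <- function(th, mu, kap, hy, arr, cn, scales) {
  if (cn$family == "A1") {
    k1 <- kap
    a1 <- (mu * k1)[arr$e]; b1 <- ((1 - mu) * k1)[arr$e]
    l1 <- sum(dbeta(th, a1, b1, log = TRUE)) + kappa_log_prior(k1, cn, hy)
    k2 <- k1 * exp(rnorm(1, 0, scales[1]))
    a2 <- (mu * k2)[arr$e]; b2 <- ((1 - mu) * k2)[arr$e]
    l2 <- sum(dbeta(th, a2, b2, log = TRUE)) + kappa_log_prior(k2, cn, hy)
    lr <- l2 - l1 + log(k2) - log(k1)
    if (is.finite(lr) && log(runif(1)) < lr)
      return(list(kappa = k2, acc = TRUE))
    return(list(kappa = k1, acc = FALSE))
  }
  acc <- logical(arr$E)
  for (e in seq_len(arr$E)) {
    the <- th[arr$idx[[e]]]
    m <- mu[e]
    k1 <- kap[e]
    l1 <- sum(dbeta(the, m * k1, (1 - m) * k1, log = TRUE)) +
      kappa_log_prior(k1, cn, hy)
    k2 <- k1 * exp(rnorm(1, 0, scales[e]))
    l2 <- sum(dbeta(the, m * k2, (1 - m) * k2, log = TRUE)) +
      kappa_log_prior(k2, cn, hy)
    lr <- l2 - l1 + log(k2) - log(k1)
    if (is.finite(lr) && log(runif(1)) < lr) {
      kap[e] <- k2
      acc[e] <- TRUE
    }
  }
  list(kappa = kap, acc = acc)
}

step_hypers <- function(kap, hy, cn, scales) {
  # hy = c(mu_gamma, sd_gamma); log-scale random walk, uniform hyperpriors
  acc <- logical(2)
  for (i in 1:2) {
    h1 <- hy[i]
    lo <- cn$bb[2 * i - 1]; hi <- cn$bb[2 * i]
    l1 <- sum(kappa_log_prior(kap, cn, hy))
    h2 <- h1 * exp(rnorm(1, 0, scales[i]))
    if (h2 >= lo && h2 <= hi) {
      hy2 <- hy
      hy2[i] <- h2
      l2 <- sum(kappa_log_prior(kap, cn, hy2))
      lr <- l2 - l1 + log(h2) - log(h1)
      if (is.finite(lr) && log(runif(1)) < lr) {
        hy <- hy2
        acc[i] <- TRUE
      }
    }
  }
  list(hy = hy, acc = acc)
}

#' Exact conjugate Gibbs update of every trail-level duping probability
#'
#' Given the group parameters, each theta_je has a conjugate Beta full
#' conditional Beta(z_je + a_e, n_je - z_je + b_e) with (a_e, b_e) =
#' [beta_shapes_from_mean_concentration()] of (mu_e, kappa_(e)); the draw
#' is exact, so this block is always accepted.
#'
#' @param state a `parameter_state`.
#' @param spec a [model_spec()].
#' @param data a [visit_dataset()].
#' @param likelihood set `FALSE` to target the prior only (drops the data
#'   terms; used for prior-recovery checks).
#' @return the state with `theta` redrawn.
#' @export
gibbs_update_theta <- function(state, spec, data, likelihood = TRUE) {
  arr <- if (inherits(data, "visit_dataset")) dataset_arrays(data) else data
  cn <- model_consts(spec, likelihood)
  state$theta <- step_theta(state$theta, state$mu, state$kappa, arr, cn)
  state
}

#' One random-walk Metropolis sweep over the group-level parameters
#'
#' Updates each mu_e on the logit scale, kappa (shared or per treatment) on
#' the log scale and, for family B, the hyperparameters mu_gamma/sd_gamma
#' on the log scale, each with the change-of-variable Jacobian, against
#' [log_posterior()] (or the prior when `likelihood = FALSE` — the
#' group-parameter targets only involve theta and the priors, so the flag
#' matters only through theta).
#'
#' @inheritParams gibbs_update_theta
#' @param scales named list of proposal SDs: `mu` (length E), `kappa`
#'   (length 1 or E), `hypers` (length 2, family B).
#' @return list with the updated `state` and logical acceptance flags
#'   `accepted` per block.
#' @export
mh_update_group_params <- function(state, spec, data, scales,
                                   likelihood = TRUE) {
  arr <- if (inherits(data, "visit_dataset")) dataset_arrays(data) else data
  cn <- model_consts(spec, likelihood)
  hy <- if (cn$family == "B") c(state$mu_gamma, state$sd_gamma) else NULL
  up_mu <- step_mu(state$theta, state$mu, state$kappa, arr, cn, scales$mu)
  state$mu <- up_mu$mu
  up_k <- step_kappa(state$theta, state$mu, state$kappa, hy, arr, cn,
                     scales$kappa)
  state$kappa <- up_k$kappa
  accepted <- list(mu = up_mu$acc, kappa = up_k$acc)
  if (cn$family == "B") {
    up_h <- step_hypers(state$kappa, hy, cn, scales$hypers)
    state$mu_gamma <- up_h$hy[1]
    state$sd_gamma <- up_h$hy[2]
    accepted$hypers <- up_h$acc
  }
  list(state = state, accepted = accepted)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Sweep order per iteration: exact Gibbs draw of all theta_je, then
#' random-walk Metropolis updates of mu_e (ascending treatment index),
#' the kappa block, and (family B) the hyperparameters.  Proposal scales
#' adapt toward a 0.25-0.5 acceptance rate during the first
#' `config$adapt_iters` iterations only.  Chain c runs under
#' `set.seed(master_seed + c)`, so results are reproducible given the
#' configuration.
#'
#' @param spec a [model_spec()].
#' @param data a [visit_dataset()].
#' @param config an [mcmc_config()].
#' @param likelihood `FALSE` targets the joint prior (prior-recovery mode).
#' @param fixed optional named list pinning parameters: currently `kappa`
#'   (scalar or per-treatment vector) is supported and skips its update.
#' @param keep_theta store thinned draws of every theta_je (memory grows
#'   with trails x retained draws); running posterior means of theta are
#'   always stored.
#' @return object of class `chain_set`: per-chain draw matrices (columns
#'   `mu[label]`, `kappa` or `kappa[label]`, `mu_gamma`, `sd_gamma`,
#'   `deviance`), per-chain posterior mean of each theta_je, acceptance
#'   rates, and the spec/config/data bookkeeping.
#' @export
run_mcmc <- function(spec, data, config = default_mcmc_config(spec),
                     likelihood = TRUE, fixed = list(),
                     keep_theta = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  arr <- dataset_arrays(data)
  cn <- model_consts(spec, likelihood)
  nk <- if (spec$family == "A1") 1L else arr$E
  kap_names <- if (spec$family == "A1") "kappa"
               else paste0("kappa[", arr$treatments, "]")
  par_names <- c(paste0("mu[", arr$treatments, "]"), kap_names)
  if (spec$family == "B") par_names <- c(par_names, "mu_gamma", "sd_gamma")
  cols <- c(par_names, "deviance")
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  fix_kappa <- !is.null(fixed$kappa)
  if (fix_kappa) stopifnot(length(fixed$kappa) == nk, all(fixed$kappa > 0))

  chains <- vector("list", config$n_chains)
  theta_mean <- matrix(0, config$n_chains, arr$J)
  theta_draws <- if (keep_theta) vector("list", config$n_chains) else NULL
  acc_all <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    set.seed(config$master_seed + ch)
    st <- init_state(spec, data)
    th <- st$theta; mu <- st$mu
    kap <- if (fix_kappa) fixed$kappa else st$kappa
    hy <- if (cn$family == "B") c(st$mu_gamma, st$sd_gamma) else NULL
    sc_mu <- rep(0.5, arr$E); sc_k <- rep(0.5, nk); sc_h <- c(0.3, 0.3)
    # windowed acceptance counters for adaptation
    win <- 50L
    cnt_mu <- numeric(arr$E); cnt_k <- numeric(nk); cnt_h <- numeric(2)
    n_post <- 0L
    draws <- matrix(NA_real_, n_keep, length(cols),
                    dimnames = list(NULL, cols))
    if (keep_theta)
      theta_draws[[ch]] <- matrix(NA_real_, n_keep, arr$J)
    th_sum <- numeric(arr$J)
    row <- 0L
    for (it in seq_len(config$n_iter)) {
      th <- step_theta(th, mu, kap, arr, cn)
      up <- step_mu(th, mu, kap, arr, cn, sc_mu)
      mu <- up$mu; cnt_mu <- cnt_mu + up$acc
      if (!fix_kappa) {
        up <- step_kappa(th, mu, kap, hy, arr, cn, sc_k)
        kap <- up$kappa; cnt_k <- cnt_k + up$acc
      }
      if (cn$family == "B") {
        up <- step_hypers(kap, hy, cn, sc_h)
        hy <- up$hy; cnt_h <- cnt_h + up$acc
      }
      if (it <= config$adapt_iters && it %% win == 0L) {
        bt <- it %/% win
        step <- min(0.5, 1 / sqrt(bt))
        sc_mu <- sc_mu * exp(step * (cnt_mu / win - 0.35))
        sc_k <- sc_k * exp(step * (cnt_k / win - 0.35))
        sc_h <- sc_h * exp(step * (cnt_h / win - 0.35))
        cnt_mu[] <- 0; cnt_k[] <- 0; cnt_h[] <- 0
      }
      if (it == config$burn_in) {
        # acceptance rates are reported for the retained segment only
        cnt_mu[] <- 0; cnt_k[] <- 0; cnt_h[] <- 0
      }
      if (it > config$burn_in) {
        n_post <- n_post + 1L
        th_sum <- th_sum + th
        if ((it - config$burn_in) %% config$thin == 0L) {
          row <- row + 1L
          dev <- -2 * sum(dbinom(arr$z, arr$n, th, log = TRUE))
          draws[row, ] <- c(mu, kap, hy, dev)
          if (keep_theta) theta_draws[[ch]][row, ] <- th
        }
      }
    }
    chains[[ch]] <- draws
    theta_mean[ch, ] <- th_sum / n_post
    acc_all[[ch]] <- list(mu = cnt_mu / n_post, kappa = cnt_k / n_post,
                          hypers = if (cn$family == "B") cnt_h / n_post)
  }
  structure(list(chains = chains, theta_mean = theta_mean,
                 theta_draws = theta_draws,
                 param_names = par_names, spec = spec, config = config,
                 arr = arr, likelihood = likelihood,
                 acceptance_rates = acc_all),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat("<chain_set> ", x$spec$label, ": ", length(x$chains), " chains x ",
      nrow(x$chains[[1]]), " retained draws\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract draws of one parameter, one column per chain
#'
#' @param chains a `chain_set` from [run_mcmc()].
#' @param param parameter name, e.g. `"mu[CT]"` or `"deviance"`.
#' @return numeric matrix, retained iterations x chains.
#' @export
chain_matrix <- function(chains, param) {
  stopifnot(inherits(chains, "chain_set"))
  if (!param %in% colnames(chains$chains[[1]]))
    stop("unknown parameter `", param, "`; available: ",
         paste(colnames(chains$chains[[1]]), collapse = ", "),
         call. = FALSE)
  sapply(chains$chains, function(m) m[, param])
}

#' Pooled draws of one parameter across all chains
#'
#' @inheritParams chain_matrix
#' @return numeric vector (chains concatenated in order).
#' @export
pooled_draws <- function(chains, param) {
  as.vector(chain_matrix(chains, param))
}

#' Persist retained draws as CSV
#'
#' One row per retained iteration: `chain`, `iter`, then the named
#' parameters and the deviance.
#'
#' @inheritParams chain_matrix
#' @param path output path.
#' @export
write_draws <- function(chains, path) {
  stopifnot(inherits(chains, "chain_set"))
  tabs <- lapply(seq_along(chains$chains), function(ch) {
    m <- chains$chains[[ch]]
    data.frame(chain = ch, iter = seq_len(nrow(m)), m, check.names = FALSE)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
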