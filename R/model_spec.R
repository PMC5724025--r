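#' Beta shape parameters from a mean/concentration pair
#'
#' The hierarchical layer places theta_je ~ Beta(a, b) with a = mu * kappa
#' and b = (1 - mu) * kappa, so mu is the mean duping probability of the
#' treatment and kappa = a + b the concentration of individual insects
#' around it.
#'
#' @param mu mean, in (0, 1).
#' @param kappa concentration, > 0.
#' @return named numeric `c(a = , b = )`.
#' @examples
#' beta_shapes_from_mean_concentration(0.8, 5)  # a = 4, b = 1
#' @export
beta_shapes_from_mean_concentration <- function(mu, kappa) {
  if (any(mu <= 0) || any(mu >= 1))
    stop("`mu` must lie strictly in (0, 1)", call. = FALSE)
  if (any(kappa <= 0))
    stop("`kappa` must be positive", call. = FALSE)
  c(a = mu * kappa, b = (1 - mu) * kappa)
}

#' Elicit a Beta prior from a mean and an equivalent number of observations
#'
#' Standard elicitation: a prior belief that the mean success probability is
#' `m`, held with the weight of `n` prior observations, maps to
#' Beta(a = m * n, b = (1 - m) * n).  With m = 0.80 (the expected mimicry
#' success rate if insects are usually duped) and n = 5 (visits needed to
#' confirm the outcome) this yields the informative Beta(4, 1) prior of
#' condition C1.
#'
#' @param m prior mean probability, in (0, 1).
#' @param n equivalent prior observations, > 0.
#' @return named numeric `c(a = , b = )`.
#' @examples
#' elicit_beta_prior(0.80, 5)  # Beta(4, 1)
#' @export
elicit_beta_prior <- function(m, n) {
  if (m <= 0 || m >= 1) stop("`m` must lie in (0, 1)", call. = FALSE)
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  c(a = m * n, b = (1 - m) * n)
}

#' Gamma shape/rate from a mean and standard deviation
#'
#' Re-expresses a Gamma prior in moment form: Gamma(shape, rate) with
#' shape = mean^2 / sd^2 and rate = mean / sd^2 has exactly the requested
#' mean and standard deviation.  The concentration prior kappa ~
#' Gamma(1.0, 0.1) used throughout corresponds to mean 10, SD 10.
#'
#' @param mean positive prior mean.
#' @param sd positive prior standard deviation.
#' @return named numeric `c(shape = , rate = )`.
#' @examples
#' gamma_shape_rate_from_mean_sd(10, 10)  # shape 1.0, rate 0.1
#' @export
gamma_shape_rate_from_mean_sd <- function(mean, sd) {
  if (mean <= 0 || sd <= 0)
    stop("`mean` and `sd` must be positive", call. = FALSE)
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Prior condition on the treatment-level mean duping probability
#'
#' Condition "C1" is the informative Beta(4, 1) prior elicited from an
#' expected 80% mimicry success over 5 confirming visits; condition "C2"
#' is the open-minded uniform Beta(1, 1).
#'
#' @param label `"C1"` or `"C2"`.
#' @return list with `label`, `a_mu`, `b_mu`.
#' @export
prior_condition <- function(label = c("C1", "C2")) {
  label <- match.arg(label)
  shapes <- if (label == "C1") elicit_beta_prior(0.80, 5) else c(a = 1, b = 1)
  list(label = label, a_mu = unname(shapes["a"]), b_mu = unname(shapes["b"]))
}

#' Gamma prior on the concentration parameter, in mean/SD form
#'
#' @param mean_gamma prior mean of kappa (default 10).
#' @param sd_gamma prior SD of kappa (default 10).
#' @return list with `mean_gamma`, `sd_gamma` and the derived `shape`,
#'   `rate`.
#' @export
kappa_prior <- function(mean_gamma = 10, sd_gamma = 10) {
  sr <- gamma_shape_rate_from_mean_sd(mean_gamma, sd_gamma)
  list(mean_gamma = mean_gamma, sd_gamma = sd_gamma,
       shape = unname(sr["shape"]), rate = unname(sr["rate"]))
}

#' Specify a hierarchical visitation model
#'
#' Three families share the trail likelihood z_je ~ Binomial(n_je, theta_je)
#' and the hierarchy theta_je ~ Beta(mu_e * kappa, (1 - mu_e) * kappa),
#' mu_e ~ Beta(a_mu, b_mu), and differ in the concentration structure:
#'
#' * `"A1"` — one kappa shared by all treatments, kappa ~ Gamma(shape, rate)
#'   from `kappa_prior`.
#' * `"A2"` — an independent kappa_e per treatment, each with the same fixed
#'   Gamma prior (naive hierarchical model).
#' * `"B"`  — kappa_e per treatment drawn from an overarching
#'   Gamma(mean = mu_gamma, sd = sd_gamma) distribution whose mean and SD
#'   get uniform hyperpriors on a positive interval, so the treatments
#'   mutually inform each other's concentration.
#'
#' @param family `"A1"`, `"A2"` or `"B"`.
#' @param prior a [prior_condition()] or its label.
#' @param kappa_prior a [kappa_prior()] (families A1/A2).
#' @param b_bounds length-4 numeric `(lo_mean, hi_mean, lo_sd, hi_sd)` for
#'   the family-B uniform hyperpriors; default `c(0.01, 100, 0.01, 100)`.
#' @return object of class `model_spec`.
#' @examples
#' model_spec("A2", "C2")
#' @export
model_spec <- function(family = c("A2", "A1", "B"), prior = "C2",
                       kappa_prior = mimicbayes::kappa_prior(10, 10),
                       b_bounds = c(0.01, 100, 0.01, 100)) {
  family <- match.arg(family)
  if (is.character(prior)) prior <- prior_condition(prior)
  stopifnot(is.list(prior), all(c("a_mu", "b_mu") %in% names(prior)))
  if (family == "B") {
    stopifnot(length(b_bounds) == 4, all(b_bounds > 0),
              b_bounds[1] < b_bounds[2], b_bounds[3] < b_bounds[4])
  }
  structure(list(family = family, prior = prior,
                 kappa_prior = kappa_prior, b_bounds = b_bounds,
                 label = paste0(family, "-", prior$label)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$label, "\n", sep = "")
  cat("  mu_e   ~ Beta(", x$prior$a_mu, ", ", x$prior$b_mu, ")\n", sep = "")
  if (x$family == "B") {
    cat("  kappa_e ~ Gamma(mean = mu_gamma, sd = sd_gamma),",
        "mu_gamma ~ U(", x$b_bounds[1], ",", x$b_bounds[2], "),",
        "sd_gamma ~ U(", x$b_bounds[3], ",", x$b_bounds[4], ")\n")
  } else {
    cat("  kappa", if (x$family == "A2") "_e" else " (shared)",
        " ~ Gamma(", x$kappa_prior$shape, ", ", x$kappa_prior$rate, ")\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize / deserialize a model specification
#'
#' @param spec a [model_spec()].
#' @param path file path (JSON).
#' @return `read_model_spec` returns a [model_spec()].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  jsonlite::write_json(
    list(family = spec$family, prior = spec$prior$label,
         kappa_mean = spec$kappa_prior$mean_gamma,
         kappa_sd = spec$kappa_prior$sd_gamma,
         b_bounds = spec$b_bounds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(family = x$family, prior = x$prior,
             kappa_prior = kappa_prior(x$kappa_mean, x$kappa_sd),
             b_bounds = x$b_bounds)
}

#' Create a parameter state for a model/dataset pair
#'
#' A state bundles every unknown: `theta` (one duping probability per
#' trail, in dataset row order), `mu` (per treatment), `kappa` (scalar for
#' A1, one per treatment otherwise) and, for family B, the hyperparameters
#' `mu_gamma`, `sd_gamma`.
#'
#' @param spec a [model_spec()].
#' @param data a [visit_dataset()].
#' @param theta,mu,kappa,mu_gamma,sd_gamma initial values; defaults are
#'   moment-style starting points (empirical proportions nudged off the
#'   boundary, prior means elsewhere).
#' @return list of class `parameter_state`.
#' @export
init_state <- function(spec, data, theta = NULL, mu = NULL, kappa = NULL,
                       mu_gamma = NULL, sd_gamma = NULL) {
  arr <- dataset_arrays(data)
  if (is.null(theta)) theta <- (arr$z + 0.5) / (arr$n + 1)
  if (is.null(mu)) {
    mu <- vapply(arr$idx, function(i) {
      p <- sum(arr$z[i]) / sum(arr$n[i])
      min(max(p, 0.02), 0.98)
    }, numeric(1))
  }
  if (is.null(kappa))
    kappa <- if (spec$family == "A1") spec$kappa_prior$mean_gamma
             else rep(spec$kappa_prior$mean_gamma, arr$E)
  st <- list(theta = theta, mu = mu, kappa = kappa)
  if (spec$family == "B") {
    st$mu_gamma <- if (is.null(mu_gamma)) spec$kappa_prior$mean_gamma
                   else mu_gamma
    st$sd_gamma <- if (is.null(sd_gamma)) spec$kappa_prior$sd_gamma
                   else sd_gamma
  }
  validate_state(st, spec, arr)
  structure(st, class = "parameter_state")
}

validate_state <- function(state, spec, arr) {
  stopifnot(length(state$theta) == arr$J, length(state$mu) == arr$E)
  nk <- if (spec$family == "A1") 1L else arr$E
  if (length(state$kappa) != nk)
    stop("kappa has length ", length(state$kappa), ", expected ", nk,
         call. = FALSE)
  if (spec$family == "B" &&
      (is.null(state$mu_gamma) || is.null(state$sd_gamma)))
    stop("family B state needs mu_gamma and sd_gamma", call. = FALSE)
  invisible(TRUE)
}

# kappa for trail-level Beta terms, expanded per treatment
kappa_by_treatment <- function(state, spec, E) {
  if (spec$family == "A1") rep(state$kappa, E) else state$kappa
}

#' Log-likelihood of a parameter state
#'
#' Sum over trails of the binomial log pmf of the female-visit count given
#' the trail's duping probability: sum_je log Bin(z_je | n_je, theta_je).
#'
#' @param state a [init_state()] state (or compatible list).
#' @param data a [visit_dataset()].
#' @return scalar log density.
#' @export
log_likelihood <- function(state, data) {
  arr <- if (inherits(data, "visit_dataset")) dataset_arrays(data) else data
  if (length(state$theta) != arr$J)
    stop("state theta length does not match dataset", call. = FALSE)
  sum(dbinom(arr$z, arr$n, state$theta, log = TRUE))
}

#' Log prior density of a parameter state
#'
#' Hierarchical prior: Beta(theta_je | mu_e kappa_(e), (1 - mu_e)
#' kappa_(e)) per trail, Beta(mu_e | a_mu, b_mu) per treatment, the Gamma
#' prior on kappa (shared or per treatment), and for family B the
#' overarching Gamma on each kappa_e plus uniform hyperpriors on its
#' mean and SD.  Returns `-Inf` outside the support.
#'
#' @inheritParams log_likelihood
#' @param spec a [model_spec()].
#' @export
log_prior <- function(state, spec, data) {
  arr <- if (inherits(data, "visit_dataset")) dataset_arrays(data) else data
  validate_state(state, spec, arr)
  th <- state$theta; mu <- state$mu
  if (any(th <= 0) || any(th >= 1) || any(mu <= 0) || any(mu >= 1) ||
      any(state$kappa <= 0))
    return(-Inf)
  ke <- kappa_by_treatment(state, spec, arr$E)
  a <- mu * ke; b <- (1 - mu) * ke
  lp <- sum(dbeta(th, a[arr$e], b[arr$e], log = TRUE)) +
    sum(dbeta(mu, spec$prior$a_mu, spec$prior$b_mu, log = TRUE))
  if (spec$family == "B") {
    mg <- state$mu_gamma; sg <- state$sd_gamma
    bb <- spec$b_bounds
    if (mg < bb[1] || mg > bb[2] || sg < bb[3] || sg > bb[4]) return(-Inf)
    sr <- gamma_shape_rate_from_mean_sd(mg, sg)
    lp <- lp + sum(dgamma(state$kappa, sr["shape"], sr["rate"], log = TRUE)) +
      dunif(mg, bb[1], bb[2], log = TRUE) +
      dunif(sg, bb[3], bb[4], log = TRUE)
  } else {
    lp <- lp + sum(dgamma(state$kappa, spec$kappa_prior$shape,
                          spec$kappa_prior$rate, log = TRUE))
  }
  lp
}

#' Unnormalized log posterior density
#'
#' `log_likelihood + log_prior`; the sampler's target.
#'
#' @inheritParams log_prior
#' @export
log_posterior <- function(state, spec, data) {
  arr <- if (inherits(data, "visit_dataset")) dataset_arrays(data) else data
  lp <- log_prior(state, spec, arr)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(state, arr)
}
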