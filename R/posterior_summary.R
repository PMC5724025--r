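#' Highest density interval of a sample
#'
#' The HDI is the shortest interval containing the stated posterior mass;
#' every point inside has higher density than any point outside.  On a
#' sample it is computed as the shortest contiguous window of the sorted
#' draws containing `ceiling(mass * n)` of them, ties broken by the lowest
#' start index.
#'
#' @param samples numeric draw vector.
#' @param mass interval mass in (0, 1); default 0.95.
#' @return named numeric `c(lower = , upper = )`.
#' @examples
#' hdi(rbeta(10000, 4, 1))
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  need <- ceiling(1 / (1 - mass))
  if (n < need)
    stop("need at least ", need, " samples for mass ", mass, call. = FALSE)
  s <- sort(samples)
  m <- ceiling(mass * n)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)          # first minimum = lowest start index
  c(lower = s[i], upper = s[i + m - 1])
}

# Mode of a (possibly skewed) marginal: peak of a Gaussian KDE with
# Silverman bandwidth. Degenerate samples return their common value.
sample_mode <- function(samples) {
  if (length(unique(samples)) == 1) return(samples[1])
  d <- density(samples, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Posterior summary table in the style of the study's parameter tables
#'
#' Pools the retained draws across chains and reports, per group-level
#' parameter: mean, KDE mode, the HDI at the stated mass and the matching
#' equal-tailed quantile interval.  The HDI is the headline interval; the
#' equal-tailed interval is kept alongside because the two coincide only
#' for symmetric marginals.
#'
#' @param chains a `chain_set` from [run_mcmc()].
#' @param mass interval mass, default 0.95.
#' @param warn_psrf warn if any parameter's PSRF exceeds this (default
#'   1.1); set `NULL` to skip the check.
#' @return data.frame with one row per parameter: `param`, `mean`, `mode`,
#'   `hdi_lower`, `hdi_upper`, `eti_lower`, `eti_upper`, `mass`.
#' @export
summarize_chains <- function(chains, mass = 0.95, warn_psrf = 1.1) {
  stopifnot(inherits(chains, "chain_set"))
  if (nrow(chains$chains[[1]]) == 0)
    stop("chain_set has no retained draws", call. = FALSE)
  if (!is.null(warn_psrf)) {
    psrf <- vapply(chains$param_names,
                   function(p) gelman_rubin(chains, p), numeric(1))
    bad <- chains$param_names[psrf > warn_psrf]
    if (length(bad) > 0)
      warning("summarizing chains with PSRF above ", warn_psrf, " for: ",
              paste(bad, collapse = ", "), call. = FALSE)
  }
  qs <- c((1 - mass) / 2, 1 - (1 - mass) / 2)
  out <- do.call(rbind, lapply(chains$param_names, function(p) {
    x <- pooled_draws(chains, p)
    h <- hdi(x, mass)
    et <- quantile(x, qs, names = FALSE)
    data.frame(param = p, mean = mean(x), mode = sample_mode(x),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]],
               eti_lower = et[1], eti_upper = et[2], mass = mass,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Iteration-paired posterior difference draws
#'
#' Differences `param_a - param_b` are formed within iteration on the
#' pooled chains, preserving the joint posterior correlation between the
#' two parameters (shuffling draws would destroy it and misstate the
#' difference's spread).
#'
#' @param chains a `chain_set`.
#' @param param_a,param_b parameter names.
#' @return numeric vector of paired differences.
#' @examples
#' \dontrun{difference_samples(fit, "mu[MFT]", "mu[CT]")}
#' @export
difference_samples <- function(chains, param_a, param_b) {
  pooled_draws(chains, param_a) - pooled_draws(chains, param_b)
}

#' Fraction of draws strictly exceeding a threshold
#'
#' Used for statements like "13% of the credible values of mu_2 - mu_1
#' are above zero".  The inequality is strict, so draws equal to the
#' threshold do not count.
#'
#' @param samples numeric draw vector.
#' @param threshold scalar.
#' @return fraction in `[0, 1]`.
#' @export
proportion_exceeding <- function(samples, threshold = 0) {
  if (length(samples) == 0) stop("empty sample vector", call. = FALSE)
  mean(samples > threshold)
}
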