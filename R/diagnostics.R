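#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance comparison: with m chains of n
#' draws, W the mean within-chain variance and B/n the variance of the
#' chain means, the PSRF is `sqrt(((n - 1)/n * W + B/n) / W)`.  Values
#' near 1 indicate the chains have mixed into the same distribution;
#' values above ~1.1 are conventionally taken as non-convergence.
#'
#' @param chains a `chain_set` from [run_mcmc()], or a numeric matrix of
#'   draws (iterations x chains).
#' @param param parameter name (ignored when `chains` is already a matrix).
#' @return scalar PSRF.
#' @export
gelman_rubin <- function(chains, param = NULL) {
  m <- if (is.matrix(chains)) chains else chain_matrix(chains, param)
  if (ncol(m) < 2)
    stop("Gelman-Rubin diagnostic needs at least 2 chains", call. = FALSE)
  n <- nrow(m)
  if (n < 10)
    stop("need at least 10 draws per chain", call. = FALSE)
  W <- mean(apply(m, 2, var))
  B_over_n <- var(colMeans(m))       # = B / n
  if (W == 0) return(1)              # degenerate constant chains
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size via the initial-positive-sequence estimator
#'
#' Autocorrelations are estimated per chain and averaged; consecutive
#' lag pairs (Geyer's Gamma_m = rho_{2m} + rho_{2m+1}) are summed while
#' positive, giving the integrated autocorrelation time tau, and ESS =
#' total draws / tau, capped at the total.  A constant (zero-variance)
#' chain returns the total draw count by convention: there is no
#' autocorrelation structure to discount.
#'
#' @inheritParams gelman_rubin
#' @return scalar effective sample size.
#' @export
effective_sample_size <- function(chains, param = NULL) {
  m <- if (is.matrix(chains)) chains else chain_matrix(chains, param)
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  n <- nrow(m)
  total <- n * ncol(m)
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  v <- apply(m, 2, var)
  if (all(v == 0)) return(total)
  max_lag <- min(n - 1, 2000L)
  rho <- rowMeans(sapply(seq_len(ncol(m)), function(j) {
    if (v[j] == 0) return(c(1, rep(0, max_lag)))
    as.vector(acf(m[, j], lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
  }))
  # Geyer initial positive sequence on rho[1] = lag 0, rho[2] = lag 1, ...
  tau <- 0
  k <- 1L
  while (k + 1 <= length(rho)) {
    g <- rho[k] + rho[k + 1]
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2L
  }
  tau <- max(tau - 1, 1e-12)  # tau = -1 + 2 * sum Gamma_m; floor at ~0
  min(total, total / tau)
}

#' Convergence report for every stored parameter
#'
#' @param chains a `chain_set`.
#' @param psrf_warn warn threshold for the PSRF (default 1.1).
#' @return data.frame with `param`, `psrf`, `ess`; emits a warning naming
#'   any parameter whose PSRF exceeds the threshold.
#' @export
convergence_report <- function(chains, psrf_warn = 1.1) {
  stopifnot(inherits(chains, "chain_set"))
  out <- do.call(rbind, lapply(chains$param_names, function(p) {
    data.frame(param = p,
               psrf = gelman_rubin(chains, p),
               ess = effective_sample_size(chains, p),
               stringsAsFactors = FALSE)
  }))
  bad <- out$param[out$psrf > psrf_warn]
  if (length(bad) > 0)
    warning("PSRF above ", psrf_warn, " for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  out
}
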