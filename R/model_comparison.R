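#' Deviance of a parameter state
#'
#' `-2 *` [log_likelihood()]; the scale on which DIC lives.
#'
#' @inheritParams log_likelihood
#' @return scalar deviance.
#' @export
deviance_at <- function(state, data) {
  -2 * log_likelihood(state, data)
}

#' Assemble a DIC result from deviance summaries
#'
#' Low-level constructor used by [dic()]; exposed so the DIC bookkeeping
#' can be exercised on models outside the package's likelihood (e.g. a
#' conjugate Gaussian toy whose effective parameter count is known
#' analytically).
#'
#' @param dbar posterior mean deviance.
#' @param dhat deviance at the plug-in estimate.
#' @return a `dic_result`.
#' @export
dic_from_deviances <- function(dbar, dhat) {
  p_d <- dbar - dhat
  structure(list(dbar = dbar, dhat = dhat, p_d = p_d, dic = dbar + p_d),
            class = "dic_result")
}

#' Deviance information criterion of a fitted model
#'
#' Spiegelhalter's construction: `Dbar` is the posterior mean deviance
#' over the retained draws, `Dhat` the deviance at a plug-in estimate,
#' `pD = Dbar - Dhat` the effective number of parameters and
#' `DIC = Dbar + pD = Dhat + 2 pD`.  The plug-in is the posterior mean of
#' every theta_je — the likelihood depends on the parameters only through
#' theta, so this is the theta-focused conditional deviance (the same
#' focus a JAGS deviance monitor uses; exact numerical parity with other
#' penalty variants is not guaranteed).
#'
#' @param chains a `chain_set` from [run_mcmc()] (per-iteration deviances
#'   and running theta means are stored during the run).
#' @param data the [visit_dataset()] that was fitted.
#' @return object of class `dic_result` with fields `dbar`, `dhat`,
#'   `p_d`, `dic`.
#' @export
dic <- function(chains, data) {
  stopifnot(inherits(chains, "chain_set"))
  if (nrow(chains$chains[[1]]) == 0)
    stop("chain_set has no retained draws", call. = FALSE)
  dbar <- mean(pooled_draws(chains, "deviance"))
  theta_bar <- colMeans(chains$theta_mean)
  dhat <- deviance_at(list(theta = theta_bar), data)
  dic_from_deviances(dbar, dhat)
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (Dbar = %.2f, Dhat = %.2f, pD = %.2f)\n",
              x$dic, x$dbar, x$dhat, x$p_d))
  invisible(x)
}

#' Rank fitted models by DIC
#'
#' @param results named list of `dic_result` objects (names are the model
#'   labels, e.g. `"A2-C2"`).
#' @return data.frame ordered by ascending DIC with `model`, `dbar`,
#'   `p_d`, `dic`, `delta_dic` (difference to the best model); ties keep
#'   input order.
#' @export
rank_models <- function(results) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == ""))
    stop("`results` must be a fully named list", call. = FALSE)
  tab <- data.frame(model = names(results),
                    dbar = vapply(results, `[[`, numeric(1), "dbar"),
                    p_d = vapply(results, `[[`, numeric(1), "p_d"),
                    dic = vapply(results, `[[`, numeric(1), "dic"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$dic), , drop = FALSE]   # stable sort: ties keep order
  tab$delta_dic <- tab$dic - tab$dic[1]
  rownames(tab) <- NULL
  tab
}
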