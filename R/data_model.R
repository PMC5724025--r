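#' mimicbayes: hierarchical Bayesian analysis of floral self-mimicry visitation
#'
#' In monoecious plants with a self-mimicry pollination system, rewardless
#' female flowers ("mimics") resemble pollen-bearing male flowers ("models").
#' Each insect's observed visitation sequence (a "trail") is reduced to the
#' number of visits to female flowers, `z`, out of `n` total visits.  The
#' package models `z` as binomial with a per-insect duping probability
#' `theta`, drawn from a treatment-level Beta(mu * kappa, (1 - mu) * kappa)
#' distribution: `mu` is the treatment's mean duping probability (so
#' `1 - mu` is the group's discrimination ability) and `kappa` is the
#' concentration tying individual insects to the group mean.
#'
#' Three model families differ in how `kappa` is shared across treatments
#' (see [model_spec()]); a custom Metropolis-within-Gibbs sampler
#' ([run_mcmc()]) draws from the joint posterior; [summarize_chains()],
#' [hdi()] and [dic()] produce the headline summaries; [simulate_dataset()]
#' generates data under the same hierarchy for parameter-recovery checks.
#'
#' @keywords internal
#' @importFrom stats acf dbeta dbinom dgamma dnorm dunif density lm median
#'   pf ptukey pt pchisq qbeta qpois ppois quantile rbeta rbinom rgamma
#'   rnorm runif rpois sd setNames var
#' @importFrom utils read.csv write.csv
"_PACKAGE"

TRAIL_COLUMNS <- c("treatment", "insect_id", "taxon", "z", "n")

#' Construct a visitation dataset from trail-level counts
#'
#' A `visit_dataset` holds one row per insect trail: the treatment label,
#' an insect identifier (unique in the dataset), an optional taxon label,
#' the number of female-flower visits `z` and the total number of visits
#' `n`.  Treatments are indexed `e = 1..E` in order of first appearance
#' unless `treatments` overrides the order.
#'
#' @param trails data.frame with columns `treatment`, `insect_id`, `taxon`,
#'   `z`, `n`.
#' @param treatments optional character vector fixing the treatment order;
#'   defaults to first-appearance order.
#' @return An object of class `visit_dataset`: a list with elements
#'   `trails` (validated data.frame) and `treatments` (ordered labels).
#' @examples
#' d <- visit_dataset(data.frame(
#'   treatment = c("CT", "CT", "MMT"),
#'   insect_id = c("i1", "i2", "i3"),
#'   taxon     = "Apis mellifera",
#'   z = c(1, 0, 2), n = c(9, 5, 6)))
#' dataset_summary(d)
#' @export
visit_dataset <- function(trails, treatments = NULL) {
  if (!is.data.frame(trails))
    stop("`trails` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(TRAIL_COLUMNS, names(trails))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  trails <- trails[TRAIL_COLUMNS]
  trails$treatment <- as.character(trails$treatment)
  trails$insect_id <- as.character(trails$insect_id)
  trails$taxon <- as.character(trails$taxon)
  if (nrow(trails) == 0)
    stop("dataset has no trails", call. = FALSE)
  for (col in c("z", "n")) {
    v <- trails[[col]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)))
      stop("column `", col, "` must contain non-missing integers",
           call. = FALSE)
    trails[[col]] <- as.integer(v)
  }
  bad <- which(trails$n < 1L)
  if (length(bad) > 0)
    stop("trail row ", bad[1], " (insect ", trails$insect_id[bad[1]],
         "): total visits n must be >= 1", call. = FALSE)
  bad <- which(trails$z < 0L | trails$z > trails$n)
  if (length(bad) > 0)
    stop("trail row ", bad[1], " (insect ", trails$insect_id[bad[1]],
         "): need 0 <= z <= n, got z=", trails$z[bad[1]],
         ", n=", trails$n[bad[1]], call. = FALSE)
  if (anyDuplicated(trails$insect_id))
    stop("insect_id values must be unique (one trail per insect record)",
         call. = FALSE)
  first_seen <- unique(trails$treatment)
  if (is.null(treatments)) {
    treatments <- first_seen
  } else {
    treatments <- as.character(treatments)
    if (!setequal(treatments, first_seen) ||
        length(treatments) != length(first_seen))
      stop("`treatments` must be a permutation of the labels present in ",
           "`trails`", call. = FALSE)
  }
  structure(list(trails = trails, treatments = treatments),
            class = "visit_dataset")
}

#' @export
print.visit_dataset <- function(x, ...) {
  cat("<visit_dataset> ", nrow(x$trails), " trails, ",
      length(x$treatments), " treatments (",
      paste(x$treatments, collapse = ", "), ")\n", sep = "")
  print(dataset_summary(x))
  invisible(x)
}

#' Read trail-level visitation counts from a delimited text file
#'
#' The file must have a header naming the five columns
#' `treatment,insect_id,taxon,z,n`; `z` is the count of female-flower
#' visits and `n` the trail's total visit count.
#'
#' @param path path to the file.
#' @param sep field delimiter, default comma.
#' @param treatments optional explicit treatment ordering (see
#'   [visit_dataset()]).
#' @return A [visit_dataset()].
#' @export
read_trails <- function(path, sep = ",", treatments = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(raw) == 0)
    stop("no trail rows in ", path, call. = FALSE)
  missing_cols <- setdiff(TRAIL_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("z", "n")) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    if (any(is.na(v)))
      stop("column `", col, "` has a non-integer value at row ",
           which(is.na(v))[1], call. = FALSE)
    raw[[col]] <- v
  }
  visit_dataset(raw, treatments = treatments)
}

#' Write a visitation dataset as CSV
#'
#' Inverse of [read_trails()]: the written file re-reads to an equal
#' dataset (treatment order is first-appearance order, which writing
#' preserves because trails are stored grouped as given).
#'
#' @param dataset a [visit_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trails <- function(dataset, path) {
  stopifnot(inherits(dataset, "visit_dataset"))
  if (nrow(dataset$trails) == 0)
    stop("refusing to write a dataset with no trails", call. = FALSE)
  write.csv(dataset$trails, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-treatment summary of a visitation dataset
#'
#' @param dataset a [visit_dataset()].
#' @return data.frame with one row per treatment (in dataset order):
#'   `treatment`, `n_trails`, `total_visits`, `female_visits`,
#'   `female_share` (= female_visits / total_visits).
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "visit_dataset"))
  tr <- dataset$trails
  out <- do.call(rbind, lapply(dataset$treatments, function(lab) {
    sub <- tr[tr$treatment == lab, , drop = FALSE]
    data.frame(treatment = lab,
               n_trails = nrow(sub),
               total_visits = sum(sub$n),
               female_visits = sum(sub$z),
               stringsAsFactors = FALSE)
  }))
  out$female_share <- out$female_visits / out$total_visits
  out
}

# Flat arrays the likelihood and sampler work from: z, n, integer treatment
# index per trail, per-treatment row index lists.
dataset_arrays <- function(dataset) {
  tr <- dataset$trails
  e <- match(tr$treatment, dataset$treatments)
  list(z = tr$z, n = tr$n, e = e,
       E = length(dataset$treatments),
       J = nrow(tr),
       idx = lapply(seq_along(dataset$treatments), function(k) which(e == k)),
       treatments = dataset$treatments)
}
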