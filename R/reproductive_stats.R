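#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition on per-group value lists; the
#' units are per-plant summaries (e.g. fruit set = fruits formed / marked
#' flowers per plant), so 3 treatments x 10 plants gives the familiar
#' F with (2, 27) degrees of freedom.
#'
#' @param groups named list of numeric vectors, one per group (>= 2
#'   groups, each >= 2 values).
#' @return list with `f`, `df_between`, `df_within`, `p`, plus the
#'   sums-of-squares decomposition (`ss_between`, `ss_within`,
#'   `ms_within`) reused by [tukey_hsd()].
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  k <- length(groups)
  n_i <- vapply(groups, length, integer(1))
  N <- sum(n_i)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- N - k
  if (ss_within == 0 && ss_between == 0)
    stop("degenerate data: no variance between or within groups",
         call. = FALSE)
  ms_w <- ss_within / df_w
  f <- (ss_between / df_b) / ms_w
  list(f = f, df_between = df_b, df_within = df_w,
       p = pf(f, df_b, df_w, lower.tail = FALSE),
       ss_between = ss_between, ss_within = ss_within, ms_within = ms_w,
       means = means, n = n_i)
}

#' Tukey's honestly significant difference test
#'
#' All pairwise comparisons after a one-way ANOVA, using the studentized
#' range: for groups i, j the statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW/2 * (1/n_i + 1/n_j))` (the
#' Tukey-Kramer form for unequal sizes), referred to the studentized
#' range distribution with k groups and the ANOVA's within df.
#'
#' @param groups named list of numeric vectors (as [anova_oneway()]).
#' @param alpha familywise significance level, default 0.05.
#' @return data.frame with one row per pair: `group_a`, `group_b`,
#'   `difference` (mean_a - mean_b), `q`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  a <- anova_oneway(groups)
  k <- length(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    diff <- a$means[i] - a$means[j]
    se <- sqrt(a$ms_within / 2 * (1 / a$n[i] + 1 / a$n[j]))
    q <- abs(diff) / se
    p <- ptukey(q, k, a$df_within, lower.tail = FALSE)
    data.frame(group_a = labs[i], group_b = labs[j], difference = diff,
               q = q, p_adj = p, significant = p < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample t test
#'
#' Pooled-variance (Student) test by default, matching the df = n_a +
#' n_b - 2 rule the study's pollen-limitation comparison reports;
#' `pooled = FALSE` gives Welch's unequal-variance form.  Two samples
#' with zero variance and equal means return t = 0, p = 1 rather than
#' NaN.
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @param pooled use the pooled-variance statistic (default `TRUE`).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_test_two_sample <- function(a, b, pooled = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b)) {
    df <- if (pooled) na + nb - 2 else na + nb - 2
    return(list(t = 0, df = df, p = 1))
  }
  if (pooled) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic of observed counts against expected proportions,
#' with df = cells - 1.  Used for questions like whether a population's
#' floral sex ratio departs from 1:1.
#'
#' @param observed non-negative count vector.
#' @param expected expected proportions (same length, summing to 1);
#'   default uniform.
#' @return list with `chisq`, `df`, `p`.
#' @export
chi_square_gof <- function(observed,
                           expected = rep(1 / length(observed),
                                          length(observed))) {
  stopifnot(length(observed) == length(expected), all(observed >= 0))
  if (abs(sum(expected) - 1) > 1e-8)
    stop("`expected` proportions must sum to 1", call. = FALSE)
  E <- sum(observed) * expected
  if (any(E == 0))
    stop("expected count of 0 in some cell", call. = FALSE)
  chisq <- sum((observed - E)^2 / E)
  df <- length(observed) - 1
  list(chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Read per-plant fruit records
#'
#' Expects columns `plant_id,treatment,flowers,fruits`; adds the derived
#' `fruit_set = fruits / flowers`.
#'
#' @param path CSV path.
#' @return data.frame of validated records.
#' @export
read_fruit_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "treatment", "flowers", "fruits")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(x$flowers < 1)) stop("flowers must be >= 1", call. = FALSE)
  if (any(x$fruits < 0 | x$fruits > x$flowers))
    stop("need 0 <= fruits <= flowers", call. = FALSE)
  x$fruit_set <- x$fruits / x$flowers
  x
}

#' Read fruit dry-weight records
#'
#' Expects columns `group,weight` (grams, positive); groups are the field
#' treatments plus hand cross-/self-pollination controls.
#'
#' @param path CSV path.
#' @return data.frame of validated records.
#' @export
read_weight_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("group", "weight"), names(x))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(x$weight <= 0)) stop("weights must be positive", call. = FALSE)
  x
}
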