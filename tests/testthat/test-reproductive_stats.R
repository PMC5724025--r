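make_groups <- function(seed = 1, k = 3, n = 10, shift = c(0, 0, 1)) {
  set.seed(seed)
  setNames(lapply(seq_len(k), function(i) rnorm(n, shift[i])),
           paste0("g", seq_len(k)))
}

test_that("anova_oneway matches the stats::lm decomposition", {
  g <- make_groups(seed = 2)
  a <- anova_oneway(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g))))
  oracle <- anova(lm(y ~ grp, df))
  expect_equal(a$f, oracle$`F value`[1])
  expect_equal(a$p, oracle$`Pr(>F)`[1])
  expect_equal(c(a$df_between, a$df_within), oracle$Df)
  # 3 x 10 layout gives the familiar (2, 27) degrees of freedom
  expect_equal(c(a$df_between, a$df_within), c(2, 27))
  # equal group means: F ~ 0
  g0 <- list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1))
  expect_lt(anova_oneway(g0)$f, 1e-10)
  expect_error(anova_oneway(list(a = 1:3)), "2")
  expect_error(anova_oneway(list(a = rep(1, 3), b = rep(1, 3))),
               "degenerate")
})

test_that("two-group ANOVA reproduces the pooled t-test: F = t^2", {
  set.seed(7)
  a <- rnorm(8, 1); b <- rnorm(12, 0.4)
  f <- anova_oneway(list(a = a, b = b))
  t <- t_test_two_sample(a, b, pooled = TRUE)
  expect_equal(f$f, t$t^2, tolerance = 1e-10)
  expect_equal(f$p, t$p, tolerance = 1e-10)
})

test_that("tukey_hsd agrees with stats::TukeyHSD and behaves at the extremes", {
  g <- make_groups(seed = 9, shift = c(0, 0, 10))
  tk <- tukey_hsd(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g))))
  oracle <- TukeyHSD(aov(y ~ grp, df))$grp
  # match pairs by label (TukeyHSD reports "g2-g1" style rows)
  for (i in seq_len(nrow(tk))) {
    key <- paste0(tk$group_b[i], "-", tk$group_a[i])
    key2 <- paste0(tk$group_a[i], "-", tk$group_b[i])
    row <- if (key %in% rownames(oracle)) oracle[key, ] else oracle[key2, ]
    expect_equal(unname(tk$p_adj[i]), unname(row["p adj"]),
                 tolerance = 1e-8)
  }
  # the +10 SD group separates from both others; the other pair does not
  expect_equal(tk$significant[tk$group_a == "g1" & tk$group_b == "g2"],
               FALSE)
  expect_true(all(tk$significant[tk$group_b == "g3" | tk$group_a == "g3"]))
  # identical groups are never significant
  tk0 <- tukey_hsd(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                        c = c(4, 3, 2, 1)))
  expect_false(any(tk0$significant))
})

test_that("t_test_two_sample matches stats::t.test in both variants", {
  set.seed(12)
  a <- rnorm(9, 1, 1); b <- rnorm(7, 0, 2)
  ours <- t_test_two_sample(a, b, pooled = TRUE)
  oracle <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(oracle$statistic))
  expect_equal(ours$df, unname(oracle$parameter))
  expect_equal(ours$p, oracle$p.value)
  w <- t_test_two_sample(a, b, pooled = FALSE)
  ow <- t.test(a, b)
  expect_equal(w$t, unname(ow$statistic))
  expect_equal(w$df, unname(ow$parameter))
  expect_equal(w$p, ow$p.value)
  # pooled df rule: n_a + n_b - 2 (the study's df = 14 with 16 plants)
  expect_equal(t_test_two_sample(rnorm(10), rnorm(6))$df, 14)
  # degenerate equal constants: t = 0, p = 1 rather than NaN
  z <- t_test_two_sample(rep(2, 3), rep(2, 4))
  expect_equal(c(z$t, z$p), c(0, 1))
  # identical samples
  same <- t_test_two_sample(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("chi_square_gof is the Pearson statistic with df = cells - 1", {
  expect_equal(chi_square_gof(c(50, 50), c(0.5, 0.5))$chisq, 0)
  expect_equal(chi_square_gof(c(50, 50), c(0.5, 0.5))$p, 1)
  expect_equal(chi_square_gof(c(60, 40), c(0.5, 0.5))$chisq, 4)
  set.seed(21)
  obs <- rpois(6, 30)
  prop <- c(0.1, 0.3, 0.2, 0.15, 0.15, 0.1)
  ours <- chi_square_gof(obs, prop)
  oracle <- chisq.test(obs, p = prop)
  expect_equal(ours$chisq, unname(oracle$statistic))
  expect_equal(ours$df, unname(oracle$parameter))
  expect_equal(ours$p, oracle$p.value)
  expect_error(chi_square_gof(c(5, 5), c(0.9, 0.2)), "sum to 1")
  expect_error(chi_square_gof(c(5, 5), c(1, 0)), "expected count")
})

test_that("p-values stay in [0, 1] across random inputs", {
  set.seed(31)
  for (i in 1:10) {
    g <- make_groups(seed = i, shift = rnorm(3))
    expect_true(anova_oneway(g)$p >= 0 && anova_oneway(g)$p <= 1)
    tt <- t_test_two_sample(g[[1]], g[[2]])
    expect_true(tt$p >= 0 && tt$p <= 1)
  }
})

test_that("CSV readers validate the reproductive inputs", {
  fr <- read_fruit_records(system.file("extdata", "synthetic_fruit_set.csv",
                                       package = "mimicbayes"))
  expect_true(all(fr$fruit_set >= 0 & fr$fruit_set <= 1))
  expect_equal(sort(unique(fr$treatment)), c("CT", "HCP", "MFT", "MMT"))
  w <- read_weight_records(system.file("extdata",
                                       "synthetic_fruit_weight.csv",
                                       package = "mimicbayes"))
  expect_true(all(w$weight > 0))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plant_id,treatment,flowers", "a,CT,10"), bad)
  expect_error(read_fruit_records(bad), "fruits")
})
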