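test_that("median/IQR follow the interpolated quartile convention", {
  expect_equal(median_iqr(c(1, 2, 3))[["median"]], 2)
  mi <- median_iqr(c(1, 2, 3, 4))
  expect_equal(mi[["median"]], 2.5)
  expect_equal(mi[["iqr"]], 1.5)   # type-7: Q1 = 1.75, Q3 = 3.25
  expect_equal(median_iqr(rep(4, 6))[["iqr"]], 0)
  expect_error(median_iqr(numeric(0)), "empty")
})

test_that("Wilcoxon p matches exhaustive enumeration on small samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- wilcoxon_rank_sum(a, b)
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)                    # 2 of 20 assignments
  expect_equal(res$p_value, wilcoxon_enum_p(a, b))
  set.seed(91)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, wilcoxon_enum_p(x, y))
  }
})

test_that("Wilcoxon is symmetric, signed, and matches the reference approximation", {
  x <- rnorm(60, 0, 1); y <- rnorm(55, 0.4, 1)
  set.seed(92); x <- rnorm(60); y <- rnorm(55, 0.4)
  r1 <- wilcoxon_rank_sum(x, y); r2 <- wilcoxon_rank_sum(y, x)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$z_stat, -r2$z_stat)
  expect_false(r1$exact)
  expect_lt(r1$z_stat, 0)  # x ranks below y under a positive shift
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r1$p_value, ref$p.value, tolerance = 1e-12)
  ident <- wilcoxon_rank_sum(1:5, 1:5)
  expect_equal(ident$z_stat, 0)
  expect_equal(ident$p_value, 1)
  expect_error(wilcoxon_rank_sum(1, 1:4), "at least 2")
})

test_that("Wilcoxon p decreases with the shift between groups", {
  set.seed(93)
  base <- rnorm(80)
  ps <- vapply(c(0.2, 0.6, 1.2), function(s)
    wilcoxon_rank_sum(base, rnorm(80, s))$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("p-values are uniform under the null", {
  set.seed(94)
  ps <- replicate(300, wilcoxon_rank_sum(rnorm(30), rnorm(30))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Kruskal-Wallis agrees with hand ranking and the two-group identity", {
  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$h_stat, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
  # hand-ranked tie-free case: ranks {1,3} vs {2,4} -> H = 0.6
  hand <- kruskal_wallis(list(c(10, 30), c(20, 40)))
  expect_equal(hand$h_stat, 0.6, tolerance = 1e-12)
  # two groups: H ~ Z^2, p agrees with the rank-sum chi-squared route
  set.seed(95); a <- rnorm(40); b <- rnorm(40, 0.3)
  expect_lt(abs(kruskal_wallis(list(a, b))$p_value -
                  wilcoxon_rank_sum(a, b)$p_value), 0.02)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("KS normality gate routes heavy-tailed and degenerate samples", {
  set.seed(96)
  heavy <- replicate(20, ks_normality(rcauchy(500))$decision)
  expect_gte(mean(heavy == "nonparametric"), 0.95)
  expect_equal(ks_normality(rep(2, 10))$decision, "nonparametric")
  # estimated-parameter caveat: null rejections stay at or below nominal
  rej <- mean(replicate(100, ks_normality(rnorm(100))$decision ==
                          "nonparametric"))
  expect_lte(rej, 0.06)
  expect_error(ks_normality(1:3), "at least 5")
})

test_that("cohort summaries compare the 8 metrics between cell types", {
  set.seed(97)
  mk <- function(ct, shift) {
    d <- as.data.frame(matrix(rnorm(8 * 20, shift), 20, 8))
    names(d) <- metric_columns()
    d$cell_type <- ct
    d
  }
  tab <- rbind(mk("nucleated", 0), mk("cytoplast", 0.2))
  sums <- summarize_cohorts(tab)
  expect_length(sums, 8)
  expect_equal(vapply(sums, `[[`, character(1), "metric_name"),
               metric_columns())
  expect_true(all(vapply(sums, function(s) s$p_value, numeric(1)) >= 0))
  # identical cohorts: all comparisons null
  same <- rbind(mk("nucleated", 0), mk("nucleated", 0))
  same$cell_type <- rep(c("nucleated", "cytoplast"), each = 20)
  same[same$cell_type == "cytoplast", metric_columns()] <-
    same[same$cell_type == "nucleated", metric_columns()]
  ps <- vapply(summarize_cohorts(same), `[[`, numeric(1), "p_value")
  expect_true(all(ps > 0.9))
  bad <- tab[, setdiff(names(tab), "apen")]
  expect_error(summarize_cohorts(bad), "apen")
})
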