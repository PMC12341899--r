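#' Median and interquartile range
#'
#' The nonparametric location/spread pair used for all cohort reporting.
#' Quartiles use linear interpolation between order statistics
#' (R's default type-7 rule); the convention matters because IQR values
#' are convention-sensitive for small samples.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric: `median`, `iqr`.
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty value list", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(median = stats::median(values), iqr = q[2] - q[1])
}

#' Two-sided Wilcoxon rank-sum test with signed Z
#'
#' Compares two groups by ranks.  For small tie-free samples
#' (`n1 + n2 <= 20`) the p-value is computed by exhaustive enumeration
#' of rank assignments (exact); otherwise by the normal approximation
#' with tie and continuity corrections -- the regime of cohort-sized
#' comparisons (n ~ 50-400), where the signed standardized statistic Z
#' is also the reported effect direction (positive when group `a` ranks
#' above expectation).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list: `p_value`, `z_stat` (continuity-corrected, signed by
#'   group `a`'s rank sum relative to expectation), `w` (rank sum of
#'   `a`), `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  sigma <- sqrt(sigma2)
  z <- if (sigma == 0) 0 else {
    dev <- w - mu
    if (dev == 0) 0 else (dev - 0.5 * sign(dev)) / sigma
  }
  has_ties <- any(ties > 1)
  exact <- !has_ties && n <= 20
  p <- if (exact) {
    combos <- utils::combn(n, n1)
    ws <- colSums(matrix(sort(r)[combos], nrow = n1))
    mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(p_value = p, z_stat = z, w = w, exact = exact)
}

#' Kruskal-Wallis test across multiple groups
#'
#' Rank-based one-way comparison of k groups; H is referred to a
#' chi-squared distribution with k - 1 degrees of freedom (with tie
#' correction).  Delegates to [stats::kruskal.test()].
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list: `p_value`, `h_stat`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values", call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(p_value = kt$p.value, h_stat = unname(kt$statistic),
       df = unname(kt$parameter))
}

#' One-sample Kolmogorov-Smirnov normality gate
#'
#' Tests the sample against a normal distribution with the sample's own
#' mean and SD, and routes the analysis to nonparametric statistics when
#' normality is rejected at the 5% level.  Because the reference
#' parameters are estimated from the same sample, the nominal p-value is
#' conservative (the Lilliefors caveat); the test is used only as a
#' routing gate, not for inference.
#'
#' @param values numeric vector, length >= 5.
#' @param alpha rejection level (default 0.05).
#' @return list: `p_value`, `decision` (`"nonparametric"` or
#'   `"parametric"`).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    return(list(p_value = 0, decision = "nonparametric"))
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s))
  list(p_value = kt$p.value,
       decision = if (kt$p.value < alpha) "nonparametric" else "parametric")
}

#' The standard per-trajectory metric columns
#' @return character vector of the 8 metric column names.
#' @export
metric_columns <- function() {
  c("rmsf_alpha", "corr_time_min", "msd_beta", "dfa_gamma", "apen",
    "IR_mm", "DR", "AS_um_s")
}

#' Cohort comparison of per-trajectory metrics
#'
#' For each metric column, compares the two cohorts (by default
#' nucleated vs cytoplast) with a two-sided Wilcoxon rank-sum test and
#' reports per-group median/IQR with the signed Z -- the layout of the
#' headline results table.
#'
#' @param metrics data.frame with one row per trajectory, a grouping
#'   column and the metric columns.
#' @param metric_cols metric column names (default [metric_columns()]).
#' @param group_col grouping column name (default `"cell_type"`).
#' @param groups the two group labels to compare, in reporting order.
#' @return list of `cohort_summary` objects (one per metric), each with
#'   `metric_name`, `group_values`, `medians`, `iqrs`, `p_value`,
#'   `z_stat`, `test`.
#' @export
summarize_cohorts <- function(metrics, metric_cols = metric_columns(),
                              group_col = "cell_type",
                              groups = c("nucleated", "cytoplast")) {
  stopifnot(is.data.frame(metrics))
  missing_cols <- setdiff(c(group_col, metric_cols), names(metrics))
  if (length(missing_cols) > 0)
    stop("missing metric column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  lapply(metric_cols, function(mc) {
    gv <- lapply(groups, function(g) {
      v <- metrics[[mc]][metrics[[group_col]] == g]
      v[!is.na(v)]
    })
    names(gv) <- groups
    if (any(vapply(gv, length, integer(1)) == 0))
      stop("empty group for metric ", mc, call. = FALSE)
    mi <- lapply(gv, median_iqr)
    wt <- wilcoxon_rank_sum(gv[[1]], gv[[2]])
    structure(list(metric_name = mc, group_values = gv,
                   medians = vapply(mi, `[[`, numeric(1), "median"),
                   iqrs = vapply(mi, `[[`, numeric(1), "iqr"),
                   p_value = wt$p_value, z_stat = wt$z_stat,
                   test = "wilcoxon"),
              class = "cohort_summary")
  })
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary %s> %s %.3g/%.3g vs %s %.3g/%.3g, p = %.3g, Z = %.2f\n",
              x$metric_name,
              names(x$group_values)[1], x$medians[1], x$iqrs[1],
              names(x$group_values)[2], x$medians[2], x$iqrs[2],
              x$p_value, x$z_stat))
  invisible(x)
}
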