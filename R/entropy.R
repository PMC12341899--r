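#' Approximate entropy (ApEn) of a series
#'
#' Pincus' regularity statistic `ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r)`,
#' where `Phi^m(r)` is the mean over template positions of the natural
#' log of the fraction of length-`m` templates within Chebyshev distance
#' `r` (self-matches included -- classic ApEn, not sample entropy).  Low
#' values indicate repetitive, predictable dynamics; shuffled or random
#' series score high.
#'
#' @param series numeric vector or `step_series`, length >= `10^m`.
#' @param m embedding (template) length, default 2.
#' @param r tolerance: a fraction of the series SD when
#'   `r_mode = "sd_fraction"` (default 0.2, the Pincus convention) or an
#'   absolute value when `r_mode = "absolute"`.
#' @param r_mode `"sd_fraction"` or `"absolute"`.
#' @return a single nonnegative value (up to floating tolerance).
#' @examples
#' apen(rep(1, 200), r = 0.1, r_mode = "absolute")  # 0: perfectly regular
#' @export
apen <- function(series, m = 2, r = 0.2,
                 r_mode = c("sd_fraction", "absolute")) {
  r_mode <- match.arg(r_mode)
  x <- series_values(series)
  n <- length(x)
  stopifnot(m >= 1, r > 0)
  if (n < 10^m)
    stop(sprintf("series too short for ApEn: need >= 10^m = %d points, got %d",
                 10^m, n), call. = FALSE)
  r_abs <- resolve_apen_r(x, r, r_mode)
  apen_cpp(x, as.integer(m), r_abs)
}

resolve_apen_r <- function(x, r, r_mode) {
  if (r_mode == "absolute") return(r)
  s <- stats::sd(x)
  if (s == 0)
    stop("tolerance undefined: zero-SD series with SD-fractional r; ",
         "use r_mode = \"absolute\"", call. = FALSE)
  r * s
}

#' Growing-window ApEn profile of a series
#'
#' Evaluates ApEn on nested prefixes of the series whose length grows by
#' `step` frames (25 s at 2 Hz) per window -- 82 windows for the
#' 4,100-frame recording protocol.  Windows shorter than 300 points are
#' computed but flagged invalid, reflecting the `10^m` minimum-length
#' requirement for meaningful ApEn (series of <= 200 points are
#' unreliable).  The SD-fractional tolerance is resolved per window.
#' The final (full-length) value is the series' summary ApEn.
#'
#' @inheritParams apen
#' @param step window growth in frames (default 50).
#' @param min_valid minimum window length flagged as valid (default 300).
#' @return an `apen_profile`: `window_lengths`, `values`, `valid`,
#'   and the parameters used.
#' @export
apen_profile <- function(series, m = 2, r = 0.2,
                         r_mode = c("sd_fraction", "absolute"),
                         step = 50, min_valid = 300) {
  r_mode <- match.arg(r_mode)
  x <- series_values(series)
  n <- length(x)
  stopifnot(step >= 1, n >= step, m >= 1, r > 0)
  lens <- seq(step, n, by = step)
  # the profile always ends with the full series, so the final window is
  # the series' summary ApEn (a 4,099-step series still gives 82 windows)
  if (lens[length(lens)] < n) lens <- c(lens, n)
  vals <- vapply(lens, function(L) {
    w <- x[seq_len(L)]
    if (L < m + 2) return(NA_real_)
    if (r_mode == "sd_fraction" && stats::sd(w) == 0) return(0)
    apen_cpp(w, as.integer(m), resolve_apen_r(w, r, r_mode))
  }, numeric(1))
  structure(list(window_lengths = lens, values = vals,
                 valid = lens >= min_valid,
                 m = m, r = r, r_mode = r_mode, step = step),
            class = "apen_profile")
}

#' @export
print.apen_profile <- function(x, ...) {
  cat(sprintf(
    "<apen_profile> %d windows of %d-frame increments, %d valid; full-length ApEn %.4g\n",
    length(x$window_lengths), x$step, sum(x$valid),
    x$values[length(x$values)]))
  invisible(x)
}

#' ApEn profile matrix for a set of series
#'
#' Stacks per-series [apen_profile()] values into a matrix (rows =
#' series, columns = growing windows), the plot-ready form of the ApEn
#' heatmaps.  Series are truncated/aligned to the shortest profile.
#'
#' @param series_list list of numeric vectors or `step_series`.
#' @param ... passed to [apen_profile()].
#' @return numeric matrix with one row per series; attribute
#'   `window_lengths` gives the column window sizes, attribute `valid`
#'   the per-column validity flags.
#' @export
apen_profile_matrix <- function(series_list, ...) {
  profs <- lapply(series_list, apen_profile, ...)
  ncol <- min(vapply(profs, function(p) length(p$values), integer(1)))
  mat <- do.call(rbind, lapply(profs, function(p) p$values[seq_len(ncol)]))
  rownames(mat) <- vapply(series_list, function(s) {
    if (inherits(s, "step_series")) s$source_id else ""
  }, character(1))
  attr(mat, "window_lengths") <- profs[[1]]$window_lengths[seq_len(ncol)]
  attr(mat, "valid") <- profs[[1]]$valid[seq_len(ncol)]
  mat
}
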