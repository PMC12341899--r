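#' Log-spaced integer scales
#'
#' Helper to build strictly increasing, approximately log-spaced integer
#' scale/lag/box-size grids for the fluctuation analyses.
#'
#' @param from,to inclusive integer bounds (`from >= 2`).
#' @param n_points requested number of points before deduplication.
#' @return increasing integer vector.
#' @export
log_spaced_scales <- function(from, to, n_points = 25) {
  stopifnot(from >= 2, to > from)
  unique(round(10^seq(log10(from), log10(to), length.out = n_points)))
}

#' Construct a scaling curve
#'
#' Container for a fluctuation/dispersion curve: strictly increasing
#' scales (lags, window or box sizes, in frames) and the nonnegative
#' curve values at each scale.  Normally produced by [rmsf_curve()],
#' [msd_curve()] or [dfa_curve()]; the constructor is exported so exact
#' synthetic curves can be fitted directly.
#'
#' @param scales increasing numeric scales (>= 2 entries).
#' @param values nonnegative values, same length as `scales`.
#' @param kind `"rmsf"`, `"msd"` or `"dfa"`.
#' @param n_series length of the series the curve was computed from
#'   (`NULL` when not applicable; enables finite-size corrections).
#' @return a `scaling_curve`.
#' @export
scaling_curve <- function(scales, values, kind = c("rmsf", "msd", "dfa"),
                          n_series = NULL) {
  kind <- match.arg(kind)
  scales <- as.numeric(scales)
  values <- as.numeric(values)
  stopifnot(length(scales) >= 2, length(scales) == length(values),
            all(diff(scales) > 0), all(values >= 0))
  structure(list(scales = scales, values = values, kind = kind,
                 n_series = n_series),
            class = "scaling_curve")
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat(sprintf("<scaling_curve %s> %d scales in [%g, %g]\n",
              x$kind, length(x$scales), min(x$scales), max(x$scales)))
  invisible(x)
}

series_values <- function(series) {
  if (inherits(series, "step_series")) series$values else as.numeric(series)
}

#' Root-mean-square-fluctuation (rmsf) curve of a series
#'
#' Builds the cumulative profile `y(k) = sum(x - mean(x))[1:k]` and, for
#' each scale `l`, measures the standard deviation of the profile
#' increments `y(k + l) - y(k)` over all admissible (overlapping)
#' windows.  A power law `F(l) ~ l^alpha` signals long-range
#' correlation: `alpha ~ 0.5` for uncorrelated data, `alpha > 0.5` for
#' persistent series.
#'
#' @param series a `step_series` or numeric vector, length >= 64.
#' @param scales increasing integer scales in `[4, length/4]`
#'   (default: ~40 log-spaced points in `[8, length/4]`, wide enough for
#'   both exponent fitting and correlation-time estimation).
#' @return a `scaling_curve` with `kind = "rmsf"`.
#' @export
rmsf_curve <- function(series, scales = NULL) {
  x <- series_values(series)
  n <- length(x)
  if (n < 64) stop("rmsf needs a series of length >= 64", call. = FALSE)
  if (is.null(scales)) scales <- log_spaced_scales(8, floor(n / 4), 40)
  stopifnot(min(scales) >= 4, max(scales) <= n - 2)
  y <- cumsum(x - mean(x))
  f <- vapply(scales, function(l) {
    stats::sd(y[(1 + l):n] - y[1:(n - l)])
  }, numeric(1))
  if (all(f == 0))
    stop("degenerate curve: constant series has zero fluctuation",
         call. = FALSE)
  scaling_curve(scales, f, "rmsf", n_series = n)
}

#' Time-averaged mean squared displacement curve
#'
#' `MSD(tau) = mean over t of |r(t + tau) - r(t)|^2` with overlapping
#' windows.  The log-log slope is the anomalous diffusion exponent beta:
#' 1 for normal diffusion, 2 for ballistic motion, between the two for
#' superdiffusion.
#'
#' @param traj a [trajectory()].
#' @param lags increasing integer lags in `[1, n/4]` (default: every
#'   integer lag in `[1, n/10]`).
#' @return a `scaling_curve` with `kind = "msd"` (values in um^2).
#' @export
msd_curve <- function(traj, lags = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$positions
  n <- nrow(p)
  if (is.null(lags)) lags <- seq_len(max(2, floor(n / 10)))
  stopifnot(min(lags) >= 1, max(lags) <= n - 1)
  msd <- vapply(lags, function(l) {
    dx <- p[(1 + l):n, 1] - p[1:(n - l), 1]
    dy <- p[(1 + l):n, 2] - p[1:(n - l), 2]
    mean(dx^2 + dy^2)
  }, numeric(1))
  if (all(msd == 0))
    stop("degenerate curve: stationary trajectory has zero MSD",
         call. = FALSE)
  scaling_curve(lags, msd, "msd", n_series = n)
}

#' Detrended fluctuation analysis (DFA) curve
#'
#' Canonical DFA: integrate the mean-subtracted series, partition the
#' profile into non-overlapping boxes of each size (walking the series
#' forward and reversed, both contributing), remove the per-box
#' least-squares polynomial trend of order `detrend_order` (default 1,
#' DFA-1), and report `F(n)` as the root-mean-square residual.
#' `F(n) ~ n^gamma`: for noise-like input gamma ~ 0.5 means no
#' long-range correlation; for Brownian-class input the neutral value
#' is 1.5 and `1.5 < gamma < 2` indicates trend-reinforcing persistence.
#'
#' @param series numeric vector or `step_series`, length >= 64.
#' @param box_sizes increasing integer box sizes in `[4, length/4]`
#'   (default: log-spaced in `[8, length/8]`).
#' @param detrend_order polynomial order of the local trend (>= 0).
#' @return a `scaling_curve` with `kind = "dfa"`.
#' @export
dfa_curve <- function(series, box_sizes = NULL, detrend_order = 1) {
  x <- series_values(series)
  n <- length(x)
  if (n < 64) stop("DFA needs a series of length >= 64", call. = FALSE)
  if (is.null(box_sizes)) box_sizes <- log_spaced_scales(8, floor(n / 8), 25)
  if (max(box_sizes) > floor(n / 4))
    stop("box sizes must not exceed length/4", call. = FALSE)
  stopifnot(min(box_sizes) >= 4, detrend_order >= 0)
  y <- cumsum(x - mean(x))
  f <- vapply(box_sizes, function(s) {
    tt <- seq_len(s)
    X <- stats::poly(tt, degree = max(1, detrend_order), raw = TRUE)
    X <- cbind(1, if (detrend_order >= 1) X[, seq_len(detrend_order),
                                            drop = FALSE])
    qrX <- qr(X)
    nb <- floor(n / s)
    res2 <- 0
    for (prof in list(y, rev(y))) {
      Y <- matrix(prof[seq_len(nb * s)], nrow = s)
      R <- qr.resid(qrX, Y)
      res2 <- res2 + sum(R^2)
    }
    sqrt(res2 / (2 * nb * s))
  }, numeric(1))
  if (all(f < .Machine$double.eps * 100))
    stop("degenerate curve: zero detrended fluctuation at all box sizes",
         call. = FALSE)
  scaling_curve(box_sizes, f, "dfa", n_series = n)
}

#' DFA exponent of a 2D trajectory
#'
#' Applies [dfa_curve()] to each Cartesian coordinate series separately
#' and averages the two fitted exponents -- the trajectory-level DFA
#' gamma, a Brownian-class quantity (neutral value 1.5).
#'
#' @param traj a [trajectory()].
#' @param box_sizes,detrend_order passed to [dfa_curve()].
#' @param fit_range passed to [fit_scaling_exponent()].
#' @return average of the x- and y-coordinate DFA exponents.
#' @export
dfa_trajectory <- function(traj, box_sizes = NULL, detrend_order = 1,
                           fit_range = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  g <- vapply(1:2, function(j) {
    cv <- dfa_curve(traj$positions[, j], box_sizes, detrend_order)
    fit_scaling_exponent(cv, fit_range)$exponent
  }, numeric(1))
  mean(g)
}

#' Fit a power-law scaling exponent on a curve
#'
#' Ordinary least-squares slope of `log10(value)` against `log10(scale)`
#' restricted to `fit_range` -- the standard estimator of rmsf alpha,
#' MSD beta and DFA gamma.
#'
#' For rmsf curves a finite-size correction is applied by default:
#' subtracting the sample mean from the steps pins the cumulative
#' profile to zero at both ends (a bridge), which suppresses the
#' expected squared fluctuation at scale `l` by the factor
#' `1 - (l/n)^(2 - 2*alpha)`.  Left uncorrected this biases the fitted
#' exponent downward, increasingly so for strongly persistent series.
#' The correction divides the curve by the square root of that factor
#' and iterates the fit to self-consistency in alpha; it requires the
#' curve to carry `n_series` and is skipped (with no effect on exact
#' synthetic curves) otherwise.
#'
#' @param curve a `scaling_curve`.
#' @param fit_range optional `c(min_scale, max_scale)`; default spans
#'   the whole curve.
#' @param finite_size apply the bridge correction (default: `TRUE` for
#'   rmsf curves that know their series length, `FALSE` otherwise).
#' @return a `scaling_fit`: `exponent`, `intercept` (log10 scale),
#'   `fit_range`, `r_squared`, `kind`.
#' @export
fit_scaling_exponent <- function(curve, fit_range = NULL,
                                 finite_size = NULL) {
  stopifnot(inherits(curve, "scaling_curve"))
  if (is.null(finite_size))
    finite_size <- curve$kind == "rmsf" && !is.null(curve$n_series)
  if (finite_size && is.null(curve$n_series))
    stop("finite-size correction needs a curve with n_series", call. = FALSE)
  if (is.null(fit_range)) fit_range <- range(curve$scales)
  keep <- curve$scales >= fit_range[1] & curve$scales <= fit_range[2]
  if (sum(keep) < 4)
    stop("need at least 4 curve points inside fit_range", call. = FALSE)
  v <- curve$values[keep]
  if (any(v <= 0))
    stop("nonpositive curve values in fit range: handle the degenerate ",
         "curve before fitting", call. = FALSE)
  l <- curve$scales[keep]
  lx <- log10(l)
  ols <- function(ly) {
    slope <- stats::cov(lx, ly) / stats::var(lx)
    intercept <- mean(ly) - slope * mean(lx)
    ss_res <- sum((ly - intercept - slope * lx)^2)
    ss_tot <- sum((ly - mean(ly))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    list(slope = slope, intercept = intercept, r2 = max(0, min(1, r2)))
  }
  fit <- ols(log10(v))
  if (finite_size) {
    for (it in 1:20) {
      w <- pmax(1 - (l / curve$n_series)^(2 - 2 * min(fit$slope, 0.99)),
                0.05)
      new_fit <- ols(log10(v / sqrt(w)))
      done <- abs(new_fit$slope - fit$slope) < 1e-6
      fit <- new_fit
      if (done) break
    }
  }
  structure(list(exponent = fit$slope, intercept = fit$intercept,
                 fit_range = fit_range, r_squared = fit$r2,
                 kind = curve$kind),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit %s> exponent %.3f (R^2 %.3f) on [%g, %g]\n",
              x$kind, x$exponent, x$r_squared,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Correlation time of the rmsf power-law regime
#'
#' Estimates how long past movement influences the current move-step:
#' local log-log slopes of the rmsf curve are measured in sliding
#' half-decade windows at scales on a 50-frame (25-s at 2 Hz) grid, and
#' the crossover scale is the largest grid scale up to which every local
#' slope stays above `0.5 + margin` (i.e. the series still looks
#' persistent).  The correlation time is the crossover scale converted
#' to minutes, snapped to the 25-s grid by construction.
#'
#' @param curve a `scaling_curve` of kind `"rmsf"`, with scales
#'   extending well beyond the expected crossover.
#' @param dt sampling interval in seconds.
#' @param margin slope excess over 0.5 required to call a scale
#'   correlated (default 0.05).
#' @param grid_step grid increment in frames (default 50).
#' @return a `correlation_time` list: `minutes`, `crossover_scale`
#'   (frames), `no_correlated_regime` flag.
#' @export
correlation_time <- function(curve, dt = 0.5, margin = 0.05,
                             grid_step = 50) {
  stopifnot(inherits(curve, "scaling_curve"), curve$kind == "rmsf")
  grid <- seq(grid_step, max(curve$scales), by = grid_step)
  if (length(grid) == 0) grid <- grid_step
  half <- 10^0.25                       # half-decade window: factor sqrt(10)
  slopes <- vapply(grid, function(s) {
    keep <- curve$scales >= s / half & curve$scales <= s * half
    if (sum(keep) < 3) {                # widen to the 3 nearest points
      keep <- rank(abs(log10(curve$scales / s))) <= 3
    }
    lx <- log10(curve$scales[keep])
    ly <- log10(pmax(curve$values[keep], .Machine$double.xmin))
    stats::cov(lx, ly) / stats::var(lx)
  }, numeric(1))
  good <- slopes > 0.5 + margin
  if (!good[1]) {
    return(structure(list(minutes = grid[1] * dt / 60,
                          crossover_scale = grid[1],
                          no_correlated_regime = TRUE),
                     class = "correlation_time"))
  }
  last <- if (all(good)) length(grid) else which(!good)[1] - 1L
  structure(list(minutes = grid[last] * dt / 60,
                 crossover_scale = grid[last],
                 no_correlated_regime = FALSE),
            class = "correlation_time")
}

#' @export
print.correlation_time <- function(x, ...) {
  cat(sprintf("<correlation_time> %.2f min (crossover %g frames)%s\n",
              x$minutes, x$crossover_scale,
              if (x$no_correlated_regime) " [no correlated regime]" else ""))
  invisible(x)
}

#' Classify a DFA exponent into a correlation regime
#'
#' For noise-like input the neutral exponent is 0.5 (below:
#' antipersistent; above: persistent); for Brownian-class input the
#' neutral value is 1.5.  A band of +/- 0.05 around the neutral value is
#' reported as `"uncorrelated"`.
#'
#' @param fit a `scaling_fit` of kind `"dfa"`, or a bare gamma value.
#' @param input_class `"noise_like"` or `"brownian_like"`.
#' @param band half-width of the uncorrelated band (default 0.05).
#' @return one of `"antipersistent"`, `"uncorrelated"`, `"persistent"`,
#'   or `"out_of_range"` for gamma outside (0, 2).
#' @export
classify_dfa_regime <- function(fit,
                                input_class = c("brownian_like",
                                                "noise_like"),
                                band = 0.05) {
  input_class <- match.arg(input_class)
  g <- if (inherits(fit, "scaling_fit")) {
    stopifnot(fit$kind == "dfa")
    fit$exponent
  } else as.numeric(fit)
  if (g <= 0 || g >= 2) return("out_of_range")
  neutral <- if (input_class == "noise_like") 0.5 else 1.5
  if (abs(g - neutral) <= band) "uncorrelated"
  else if (g < neutral) "antipersistent"
  else "persistent"
}
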