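#' Configuration for a synthetic walker
#'
#' Parameters of the synthetic motion models used for calibration and for
#' emulating experimental cohorts.  Defaults mirror the recording
#' protocol (4,100 frames at 2 Hz) and the observed kinematics of
#' free-crawling amoebae: median speeds around 1.3-1.7 um/s and
#' directional persistence on the order of 8-10 min.
#'
#' @param model one of `"ballistic"`, `"brownian"`, `"persistent"`,
#'   `"fgn_steps"`.
#' @param speed_mean mean speed in um/s (>= 0).
#' @param speed_sd speed standard deviation in um/s (>= 0).
#' @param persistence_time relaxation time of heading and speed
#'   fluctuations in seconds (persistent model; > 0).
#' @param hurst Hurst exponent in (0, 1) (fgn_steps model).
#' @param bias_strength directional drift amplitude in rad/s (>= 0);
#'   0 means an unbiased walk.
#' @param bias_axis length-2 direction of the stimulus bias.
#' @param n_frames number of recorded frames (>= 2).
#' @param dt sampling interval in seconds.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `walker_config` list.
#' @export
walker_config <- function(model = c("persistent", "ballistic", "brownian",
                                    "fgn_steps"),
                          speed_mean = 1.5, speed_sd = 0.5,
                          persistence_time = 540, hurst = 0.75,
                          bias_strength = 0, bias_axis = c(1, 0),
                          n_frames = 4100, dt = 0.5, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_frames >= 2, dt > 0, speed_mean >= 0, speed_sd >= 0,
            bias_strength >= 0, length(bias_axis) == 2)
  if (model == "fgn_steps" && (hurst <= 0 || hurst >= 1))
    stop("hurst must lie strictly inside (0, 1)", call. = FALSE)
  if (model == "persistent" && persistence_time <= 0)
    stop("persistence_time must be positive", call. = FALSE)
  structure(list(model = model, speed_mean = speed_mean, speed_sd = speed_sd,
                 persistence_time = persistence_time, hurst = hurst,
                 bias_strength = bias_strength, bias_axis = bias_axis,
                 n_frames = as.integer(n_frames), dt = dt, seed = seed),
            class = "walker_config")
}

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Generate a ballistic (constant-velocity) trajectory
#'
#' Noise-free straight-line motion along the bias axis; the calibration
#' limit for superdiffusion (MSD exponent exactly 2, directionality
#' ratio exactly 1).
#'
#' @param cfg a [walker_config()] with `model = "ballistic"`.
#' @param ... cohort labels passed to [trajectory()].
#' @return a [trajectory()].
#' @export
gen_ballistic <- function(cfg, ...) {
  stopifnot(cfg$model == "ballistic")
  if (cfg$speed_mean == 0 && cfg$n_frames > 1)
    warning("speed_mean = 0: stationary (degenerate) trajectory")
  u <- cfg$bias_axis / sqrt(sum(cfg$bias_axis^2))
  t <- (seq_len(cfg$n_frames) - 1) * cfg$dt
  trajectory(x = cfg$speed_mean * t * u[1], y = cfg$speed_mean * t * u[2],
             dt = cfg$dt, ...)
}

#' Generate a 2D Brownian trajectory
#'
#' Independent Gaussian displacements each frame with per-axis step
#' standard deviation `speed_mean * dt / sqrt(2)`, so the mean frame
#' displacement magnitude is of order `speed_mean * dt`.  The normal
#' diffusion calibration (MSD exponent ~ 1; uncorrelated step series).
#'
#' @inheritParams gen_ballistic
#' @param cfg a [walker_config()] with `model = "brownian"`.
#' @return a [trajectory()].
#' @export
gen_brownian <- function(cfg, ...) {
  stopifnot(cfg$model == "brownian")
  maybe_seed(cfg$seed)
  s <- cfg$speed_mean * cfg$dt / sqrt(2)
  n <- cfg$n_frames
  trajectory(x = c(0, cumsum(rnorm(n - 1, 0, s))),
             y = c(0, cumsum(rnorm(n - 1, 0, s))),
             dt = cfg$dt, ...)
}

#' Generate a persistent correlated-walk trajectory
#'
#' The heading performs rotational diffusion with relaxation time
#' `persistence_time` (velocity autocorrelation decays as
#' `exp(-t / persistence_time)`), optionally with a restoring drift of
#' amplitude `bias_strength * sin(heading - bias_angle)` toward the bias
#' axis, giving a von-Mises-like stationary heading distribution of
#' concentration `bias_strength * persistence_time`.  Speed follows an
#' Ornstein-Uhlenbeck process with the same relaxation time (mean
#' `speed_mean`, stationary SD `speed_sd`, truncated at 0), so the
#' move-step series carries the same persistence as the heading --
#' the statistical structure (rmsf alpha > 0.5, finite correlation time,
#' superdiffusive MSD, low ApEn) that the analysis stages measure.
#'
#' @inheritParams gen_ballistic
#' @param cfg a [walker_config()] with `model = "persistent"`.
#' @return a [trajectory()].
#' @export
gen_persistent <- function(cfg, ...) {
  stopifnot(cfg$model == "persistent")
  if (cfg$persistence_time <= 0)
    stop("persistence_time must be positive", call. = FALSE)
  maybe_seed(cfg$seed)
  n <- cfg$n_frames
  dt <- cfg$dt
  tau <- cfg$persistence_time
  bias_angle <- atan2(cfg$bias_axis[2], cfg$bias_axis[1])

  theta <- numeric(n - 1)
  theta[1] <- if (cfg$bias_strength > 0) bias_angle else runif(1, -pi, pi)
  sig_th <- sqrt(2 * dt / tau)
  noise_th <- rnorm(n - 2, 0, sig_th)
  for (i in seq_len(n - 2)) {
    drift <- -cfg$bias_strength * sin(theta[i] - bias_angle) * dt
    theta[i + 1] <- theta[i] + drift + noise_th[i]
  }

  speed <- numeric(n - 1)
  speed[1] <- max(0, rnorm(1, cfg$speed_mean, cfg$speed_sd))
  sig_s <- cfg$speed_sd * sqrt(2 * dt / tau)
  noise_s <- rnorm(n - 2, 0, sig_s)
  for (i in seq_len(n - 2)) {
    speed[i + 1] <- max(0, speed[i] +
                          (cfg$speed_mean - speed[i]) * dt / tau + noise_s[i])
  }

  dx <- speed * dt * cos(theta)
  dy <- speed * dt * sin(theta)
  trajectory(x = c(0, cumsum(dx)), y = c(0, cumsum(dy)), dt = dt, ...)
}

#' Standard fractional Gaussian noise by circulant embedding
#'
#' Exact (Davies-Harte) generation of zero-mean, unit-variance fGn with
#' autocovariance `rho(k) = ((k+1)^(2H) - 2 k^(2H) + |k-1|^(2H)) / 2`.
#'
#' @param n series length (>= 2).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric vector of length `n`.
#' @export
fgn <- function(n, hurst, seed = NULL) {
  stopifnot(n >= 2)
  if (hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly inside (0, 1)", call. = FALSE)
  maybe_seed(seed)
  H2 <- 2 * hurst
  k <- 0:n
  r <- 0.5 * ((k + 1)^H2 - 2 * k^H2 + abs(k - 1)^H2)
  circ <- c(r, rev(r[2:n]))            # length 2n
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam))
    stop("circulant embedding not positive definite; increase n",
         call. = FALSE)
  lam <- pmax(lam, 0)
  m <- 2 * n
  v <- complex(length.out = m)
  v[1] <- sqrt(lam[1]) * rnorm(1)
  v[n + 1] <- sqrt(lam[n + 1]) * rnorm(1)
  a <- rnorm(n - 1); b <- rnorm(n - 1)
  v[2:n] <- sqrt(lam[2:n] / 2) * complex(real = a, imaginary = b)
  v[m:(n + 2)] <- Conj(v[2:n])
  Re(fft(v))[1:n] / sqrt(m)
}

#' Generate a move-step series with fractional-Gaussian-noise structure
#'
#' A stationary step-length series whose autocorrelation is exactly that
#' of fGn with the configured Hurst exponent (before the nonnegativity
#' shift): ground truth for rmsf exponent recovery.  Raw fGn is scaled to
#' mean `speed_mean * dt` and SD `speed_sd * dt`, then shifted up by any
#' deficit so the minimum is 0 and clipped at 0; the shift slightly
#' biases the marginal at very low Hurst but leaves autocorrelation
#' untouched.
#'
#' @param cfg a [walker_config()] with `model = "fgn_steps"` and
#'   `n_frames >= 65` (series length is `n_frames - 1`, >= 64).
#' @return a `step_series`.
#' @export
gen_fgn_steps <- function(cfg) {
  stopifnot(cfg$model == "fgn_steps")
  n <- cfg$n_frames - 1L
  if (n < 64) stop("fgn_steps needs n_frames - 1 >= 64", call. = FALSE)
  z <- fgn(n, cfg$hurst, cfg$seed)
  v <- cfg$speed_mean * cfg$dt + cfg$speed_sd * cfg$dt * z
  v <- v + max(0, -min(v))
  v[v < 0] <- 0
  structure(list(values = v, dt = cfg$dt, source_id = "fgn_steps"),
            class = "step_series")
}

#' Scenario preset for cohort simulation
#'
#' Encodes the four experimental scenarios as walker distributions:
#' * `Sc1` -- no stimulus: unbiased persistent walk (cohort cosine
#'   median ~ 0);
#' * `Sc2` -- galvanotaxis: strong bias toward the cathode (+x; cosine
#'   median ~ +0.97);
#' * `Sc3` -- chemotaxis: moderate bias toward the peptide source (-x;
#'   cosine median ~ -0.70);
#' * `Sc4` -- both stimuli: a mixture, 58% biased toward the peptide
#'   (-x) and 42% toward the cathode (+x).
#'
#' @param scenario `"Sc1"`..`"Sc4"`.
#' @param speed_mean,speed_sd,persistence_time,n_frames,dt as in
#'   [walker_config()].
#' @param bias_strength drift amplitude (rad/s) applied when the
#'   scenario is biased; scenario-specific default if `NULL`.
#' @param mixture_weights for `Sc4`, fractions of walkers biased toward
#'   the peptide (-x) and the cathode (+x); must sum to 1.
#' @return a `scenario_preset` list.
#' @export
scenario_preset <- function(scenario = c("Sc1", "Sc2", "Sc3", "Sc4"),
                            speed_mean = 1.5, speed_sd = 0.5,
                            persistence_time = 540,
                            n_frames = 4100, dt = 0.5,
                            bias_strength = NULL,
                            mixture_weights = c(peptide = 0.58,
                                                cathode = 0.42)) {
  scenario <- match.arg(scenario)
  if (abs(sum(mixture_weights) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (is.null(bias_strength))
    bias_strength <- switch(scenario,
                            Sc1 = 0, Sc2 = 0.004, Sc3 = 5e-4, Sc4 = 0.004)
  structure(list(scenario = scenario, speed_mean = speed_mean,
                 speed_sd = speed_sd, persistence_time = persistence_time,
                 n_frames = as.integer(n_frames), dt = dt,
                 bias_strength = bias_strength,
                 mixture_weights = mixture_weights),
            class = "scenario_preset")
}

#' Generate a synthetic cohort of trajectories for one scenario
#'
#' Draws `n_cells` persistent walkers from the preset.  A master seed
#' fans out to per-walker child seeds, so cohorts are reproducible and
#' individual walkers are stable under reordering.  In `Sc4` each walker
#' is first assigned a bias direction (peptide -x vs cathode +x) by the
#' mixture weights.
#'
#' @param preset a [scenario_preset()].
#' @param n_cells number of walkers (>= 1).
#' @param seed master integer seed.
#' @param cell_type cohort label applied to all walkers.
#' @return list of [trajectory()] objects.
#' @export
gen_cohort <- function(preset, n_cells, seed,
                       cell_type = c("nucleated", "cytoplast")) {
  cell_type <- match.arg(cell_type)
  stopifnot(inherits(preset, "scenario_preset"), n_cells >= 1)
  set.seed(as.integer(seed))
  child <- sample.int(.Machine$integer.max - 1L, n_cells)
  toward_peptide <- switch(preset$scenario,
    Sc1 = rep(FALSE, n_cells),                    # unbiased anyway
    Sc2 = rep(FALSE, n_cells),                    # cathode, +x
    Sc3 = rep(TRUE, n_cells),                     # peptide, -x
    Sc4 = runif(n_cells) < preset$mixture_weights[["peptide"]])
  lapply(seq_len(n_cells), function(i) {
    axis <- if (toward_peptide[i]) c(-1, 0) else c(1, 0)
    cfg <- walker_config(model = "persistent",
                         speed_mean = preset$speed_mean,
                         speed_sd = preset$speed_sd,
                         persistence_time = preset$persistence_time,
                         bias_strength = preset$bias_strength,
                         bias_axis = axis, n_frames = preset$n_frames,
                         dt = preset$dt, seed = child[i])
    gen_persistent(cfg,
                   track_id = sprintf("%s_%s_%03d", preset$scenario,
                                      cell_type, i),
                   cell_type = cell_type, scenario = preset$scenario)
  })
}
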