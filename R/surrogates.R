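#' Surrogate (shuffling) specification
#'
#' Controls the construction of shuffled nulls.  Each surrogate is a
#' uniform random permutation of the time order of the recorded samples;
#' `n_shuffle_ops` records the nominal count of elementary random
#' transpositions such a randomization corresponds to (a uniform
#' permutation is the distributional fixed point of repeated
#' transposition, so the op count is retained as a configuration echo
#' rather than executed literally).
#'
#' @param n_surrogates surrogates per input (>= 1).
#' @param n_shuffle_ops nominal elementary shuffle operations
#'   (default 2e5).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `surrogate_spec` list.
#' @export
surrogate_spec <- function(n_surrogates = 1, n_shuffle_ops = 2e5,
                           seed = NULL) {
  stopifnot(n_surrogates >= 1, n_shuffle_ops >= 1)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 n_shuffle_ops = n_shuffle_ops, seed = seed),
            class = "surrogate_spec")
}

#' Shuffled-trajectory surrogates
#'
#' Permutes the time order of the recorded positions uniformly at
#' random, preserving the position multiset exactly.  The surrogate
#' destroys all temporal structure: its MSD is flat (exponent ~ 0), its
#' coordinate-series DFA exponent drops to ~ 0.5, and its kinematics are
#' those of spatial noise -- the null against which the experimental
#' metrics are compared.
#'
#' @param traj a [trajectory()] with at least 3 frames.
#' @param spec a [surrogate_spec()].
#' @return list of `spec$n_surrogates` trajectories; track ids carry a
#'   `_shuffled` suffix.
#' @export
shuffle_trajectory <- function(traj, spec = surrogate_spec()) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj$positions)
  if (n < 3)
    stop("degenerate input: need >= 3 positions to shuffle", call. = FALSE)
  maybe_seed(spec$seed)
  lapply(seq_len(spec$n_surrogates), function(k) {
    idx <- sample.int(n)
    trajectory(x = traj$positions[idx, 1], y = traj$positions[idx, 2],
               dt = traj$dt, t0 = traj$t0,
               track_id = paste0(traj$track_id, "_shuffled",
                                 if (spec$n_surrogates > 1) k else ""),
               cell_type = traj$cell_type, scenario = traj$scenario)
  })
}

#' Shuffled step-series surrogates
#'
#' Uniform random permutation of the move-step values; the value
#' multiset (hence mean and SD) is preserved exactly while all serial
#' correlation is destroyed, turning a persistent series into white
#' noise (rmsf alpha ~ 0.5, high ApEn).
#'
#' @param series a `step_series` of length >= 3 (see [step_series()]).
#' @param spec a [surrogate_spec()].
#' @return list of `step_series` surrogates.
#' @export
shuffle_series <- function(series, spec = surrogate_spec()) {
  stopifnot(inherits(series, "step_series"))
  n <- length(series$values)
  if (n < 3)
    stop("degenerate input: need >= 3 values to shuffle", call. = FALSE)
  maybe_seed(spec$seed)
  lapply(seq_len(spec$n_surrogates), function(k) {
    structure(list(values = series$values[sample.int(n)], dt = series$dt,
                   source_id = paste0(series$source_id, "_shuffled",
                                      if (spec$n_surrogates > 1) k else "")),
              class = "step_series")
  })
}
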