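#' Displacement cosine of a trajectory
#'
#' Cosine of the angle between the net displacement vector
#' `r_final - r_initial` and the stimulus axis.  With the chamber
#' convention (+x toward the cathode), values near +1 indicate
#' cathode-directed (rightward) migration and values near -1
#' peptide-directed (leftward) migration.
#'
#' @param traj a [trajectory()].
#' @param frame a [stimulus_frame()].
#' @return cosine in `[-1, 1]`, or `NA` with a warning when the net
#'   displacement is zero (direction undefined; such tracks are excluded
#'   from cosine statistics).
#' @export
displacement_cosine <- function(traj, frame = stimulus_frame()) {
  stopifnot(inherits(traj, "trajectory"), inherits(frame, "stimulus_frame"))
  d <- net_displacement(traj)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) {
    warning("zero net displacement: direction undefined")
    return(NA_real_)
  }
  sum(d * frame$axis) / nrm
}

net_displacement <- function(traj) {
  p <- traj$positions
  unname(p[nrow(p), ] - p[1, ])
}

#' Displacement angle of a trajectory
#'
#' Angle of the net displacement measured counterclockwise from the
#' stimulus axis, in degrees in `[0, 360)`.
#'
#' @inheritParams displacement_cosine
#' @return angle in degrees, or `NA` for zero net displacement.
#' @export
displacement_angle <- function(traj, frame = stimulus_frame()) {
  d <- net_displacement(traj)
  if (sum(d^2) == 0) return(NA_real_)
  ax <- frame$axis
  # rotate so the stimulus axis is angle 0
  ang <- atan2(d[2], d[1]) - atan2(ax[2], ax[1])
  (ang * 180 / pi) %% 360
}

#' Sector histogram of final displacement directions
#'
#' Percentage of trajectories whose net-displacement angle falls in each
#' of 8 half-open 45-degree sectors `[k*45, (k+1)*45)` measured from the
#' stimulus axis (sector 0 starts at the axis; a boundary angle of
#' exactly 45 degrees belongs to sector 1).  Zero-displacement
#' trajectories are excluded; percentages sum to 100 over the included
#' tracks.
#'
#' @param trajs list of [trajectory()] objects.
#' @param frame a [stimulus_frame()].
#' @return named numeric vector of 8 percentages; attribute `n_excluded`
#'   counts zero-displacement tracks.
#' @export
sector_histogram <- function(trajs, frame = stimulus_frame()) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  angles <- vapply(trajs, displacement_angle, numeric(1), frame = frame)
  excluded <- sum(is.na(angles))
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0)
    stop("empty histogram: all trajectories have zero net displacement",
         call. = FALSE)
  sector <- floor(angles / 45) %% 8
  counts <- tabulate(sector + 1L, nbins = 8)
  out <- 100 * counts / sum(counts)
  names(out) <- sprintf("[%d,%d)", 0:7 * 45L, 1:8 * 45L)
  attr(out, "n_excluded") <- excluded
  out
}

#' Intensity of response (net displacement magnitude, mm)
#'
#' The modulus of the vector connecting the first and last recorded
#' positions, converted from micrometres to millimetres.
#'
#' @param traj a [trajectory()].
#' @return displacement magnitude in mm (>= 0).
#' @examples
#' intensity_of_response(trajectory(c(0, 3000), c(0, 4000)))  # 5 mm
#' @export
intensity_of_response <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sqrt(sum(net_displacement(traj)^2)) / 1000
}

#' Directionality ratio of a trajectory
#'
#' Net displacement divided by total path length: 1 for a perfectly
#' straight path, 0 for a closed loop.
#'
#' @param traj a [trajectory()].
#' @return value in `[0, 1]`, or `NA` with a warning for a stationary
#'   trajectory (zero path length).
#' @export
directionality_ratio <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  path <- sum(step_series(traj)$values)
  if (path == 0) {
    warning("stationary trajectory: directionality ratio undefined")
    return(NA_real_)
  }
  sqrt(sum(net_displacement(traj)^2)) / path
}

#' Average speed of a trajectory (um/s)
#'
#' Total path length divided by total duration; identical to the mean of
#' the instantaneous frame speeds under uniform sampling.
#'
#' @param traj a [trajectory()].
#' @return speed in um/s (>= 0).
#' @export
average_speed <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  sum(step_series(traj)$values) / duration(traj)
}

#' Per-trajectory kinematic summary row
#'
#' @param traj a [trajectory()].
#' @param frame a [stimulus_frame()].
#' @return one-row data.frame: `track_id`, `cell_type`, `scenario`,
#'   `cosine`, `angle_deg`, `sector`, `IR_mm`, `DR`, `AS_um_s`.
#' @export
kinematic_summary <- function(traj, frame = stimulus_frame()) {
  ang <- displacement_angle(traj, frame)
  data.frame(
    track_id = traj$track_id, cell_type = traj$cell_type,
    scenario = traj$scenario,
    cosine = if (is.na(ang)) NA_real_ else
      suppressWarnings(displacement_cosine(traj, frame)),
    angle_deg = ang,
    sector = if (is.na(ang)) NA_integer_ else as.integer(floor(ang / 45) %% 8),
    IR_mm = intensity_of_response(traj),
    DR = suppressWarnings(directionality_ratio(traj)),
    AS_um_s = average_speed(traj))
}
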