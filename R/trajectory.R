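#' Construct a cell migration trajectory
#'
#' A trajectory is a uniformly sampled, time-ordered sequence of 2D
#' positions (in micrometres) for one tracked cell, together with its
#' sampling interval and cohort labels.  The default sampling interval of
#' 0.5 s corresponds to recording at two images per second.
#'
#' @param x,y numeric vectors of equal length (>= 2), positions in um.
#' @param dt sampling interval in seconds (> 0).
#' @param t0 time of the first frame in seconds.
#' @param track_id character label for the track.
#' @param cell_type `"nucleated"` or `"cytoplast"`.
#' @param scenario experimental scenario label `"Sc1"`..`"Sc4"`
#'   (no stimulus, electric field, peptide gradient, both).
#' @return An object of class `trajectory` with elements `positions`
#'   (n x 2 matrix, um), `dt`, `t0`, `track_id`, `cell_type`, `scenario`.
#' @examples
#' tr <- trajectory(x = c(0, 1, 2), y = c(0, 0, 0))
#' duration(tr)  # (n - 1) * dt = 1 s
#' @export
trajectory <- function(x, y, dt = 0.5, t0 = 0, track_id = "track",
                       cell_type = c("nucleated", "cytoplast"),
                       scenario = c("Sc1", "Sc2", "Sc3", "Sc4")) {
  cell_type <- match.arg(cell_type)
  scenario <- match.arg(scenario)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2)
    stop("degenerate input: a trajectory needs at least 2 positions",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number (seconds)", call. = FALSE)
  structure(
    list(positions = cbind(x = x, y = y), dt = dt, t0 = t0,
         track_id = as.character(track_id), cell_type = cell_type,
         scenario = scenario),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> %d frames, dt = %g s (%s, %s)\n",
              x$track_id, nrow(x$positions), x$dt, x$cell_type, x$scenario))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$positions)

#' Total duration of a trajectory in seconds
#'
#' Defined as `(n_frames - 1) * dt`: the elapsed time between the first
#' and the last recorded position.
#' @param traj a [trajectory()].
#' @return duration in seconds.
#' @export
duration <- function(traj) (nrow(traj$positions) - 1) * traj$dt

#' Per-frame move-step series of a trajectory
#'
#' The move-step series is the sequence of Euclidean distances between
#' consecutive recorded positions -- the scalar "move-step migratory
#' fluctuations" analysed by rmsf and approximate entropy.
#'
#' @param traj a [trajectory()].
#' @return An object of class `step_series`: list with `values`
#'   (length `n_frames - 1`, um per frame), `dt` (s), `source_id`.
#' @examples
#' tr <- trajectory(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' step_series(tr)$values  # 1, 1, 1
#' @export
step_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  d <- diff(traj$positions)
  structure(
    list(values = sqrt(d[, 1]^2 + d[, 2]^2), dt = traj$dt,
         source_id = traj$track_id),
    class = "step_series")
}

#' @export
print.step_series <- function(x, ...) {
  cat(sprintf("<step_series %s> %d steps, dt = %g s\n",
              x$source_id, length(x$values), x$dt))
  invisible(x)
}

#' Stimulus reference frame of the experimental chamber
#'
#' Defines the axis against which displacement cosines and sector
#' histograms are measured.  The chamber convention is that +x points
#' toward the cathode (right side); in the chemotaxis scenarios the
#' peptide source lies toward -x.
#'
#' @param axis numeric length-2 direction of the stimulus axis
#'   (normalised internally; must be nonzero).
#' @param positive_sense documentation tag, `"cathode_right"` or
#'   `"peptide_left"`.
#' @return An object of class `stimulus_frame`.
#' @export
stimulus_frame <- function(axis = c(1, 0),
                           positive_sense = c("cathode_right", "peptide_left")) {
  positive_sense <- match.arg(positive_sense)
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 2, all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("stimulus axis must be nonzero", call. = FALSE)
  structure(list(axis = axis / nrm, positive_sense = positive_sense),
            class = "stimulus_frame")
}

#' Read cell tracks from a delimited text file
#'
#' Supports two dialects: `"generic"` (header `track_id,frame,x,y`,
#' comma-separated) and `"trackmate"` (a TrackMate spots-table export with
#' columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`; the extra
#' human-readable header rows TrackMate inserts are skipped).  Frame
#' indices must be consecutive within each track: a missing frame is an
#' error, not an interpolation target, because gap-filling would silently
#' alter the very dynamics being quantified.
#'
#' @param path file to read.
#' @param dialect `"generic"` or `"trackmate"`.
#' @param calibration micrometres per coordinate unit (default 1);
#'   coordinates are multiplied by this factor on ingest.
#' @param dt sampling interval in seconds.
#' @param cell_type,scenario cohort labels applied to every track in the
#'   file.
#' @return A list of [trajectory()] objects, one per track id, ordered by
#'   track id.
#' @export
read_tracks <- function(path, dialect = c("generic", "trackmate"),
                        calibration = 1, dt = 0.5,
                        cell_type = "nucleated", scenario = "Sc1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.numeric(calibration), calibration > 0)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty input: no track rows in ", path, call. = FALSE)
  cols <- switch(dialect,
    generic   = c(id = "track_id", frame = "frame", x = "x", y = "y"),
    trackmate = c(id = "TRACK_ID", frame = "FRAME",
                  x = "POSITION_X", y = "POSITION_Y"))
  missing_cols <- setdiff(unname(cols), names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, unname(cols)]
  names(df) <- names(cols)
  if (dialect == "trackmate") {
    # TrackMate writes up to 3 extra header rows (nice names, units, ...)
    keep <- suppressWarnings(!is.na(as.numeric(df$frame)))
    df <- df[keep, , drop = FALSE]
    if (nrow(df) == 0)
      stop("empty input: no numeric spot rows in ", path, call. = FALSE)
  }
  df$frame <- as.numeric(df$frame)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$frame))
    stop("format error: non-numeric frame or coordinate values",
         call. = FALSE)
  out <- lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    gaps <- which(diff(tr$frame) != 1)
    if (length(gaps) > 0) {
      where <- paste(sprintf("%g->%g", tr$frame[gaps], tr$frame[gaps + 1]),
                     collapse = ", ")
      stop(sprintf("validation error: non-consecutive frames in track %s (%s)",
                   tr$id[1], where), call. = FALSE)
    }
    trajectory(x = tr$x * calibration, y = tr$y * calibration, dt = dt,
               t0 = tr$frame[1] * dt, track_id = as.character(tr$id[1]),
               cell_type = cell_type, scenario = scenario)
  })
  out[order(names(out))]
}

#' Write trajectories in the generic track format
#'
#' @param trajs a list of [trajectory()] objects.
#' @param path output file; columns `track_id,frame,x,y`, coordinates in
#'   micrometres.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(track_id = tr$track_id,
               frame = seq_len(nrow(tr$positions)) - 1L,
               x = tr$positions[, 1], y = tr$positions[, 2])
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort results table
#'
#' One row per metric: metric name, nucleated median and IQR, cytoplast
#' median and IQR, Wilcoxon P-value and signed Z.  Re-reading the file
#' with [read_results_table()] recovers the written values.
#'
#' @param summaries a list of `cohort_summary` objects (see
#'   [summarize_cohorts()]), possibly empty.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(summaries, path) {
  header <- data.frame(metric = character(),
                       nucleated_median = numeric(), nucleated_iqr = numeric(),
                       cytoplast_median = numeric(), cytoplast_iqr = numeric(),
                       p_value = numeric(), z = numeric())
  rows <- if (length(summaries) == 0) header else
    do.call(rbind, lapply(summaries, function(s) {
      data.frame(metric = s$metric_name,
                 nucleated_median = s$medians[1], nucleated_iqr = s$iqrs[1],
                 cytoplast_median = s$medians[2], cytoplast_iqr = s$iqrs[2],
                 p_value = s$p_value, z = s$z_stat)
    }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a cohort results table written by [write_results_table()]
#' @param path file to read.
#' @return a data.frame with one row per metric.
#' @export
read_results_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
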