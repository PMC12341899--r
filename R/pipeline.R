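#' Metric parameters shared across the pipeline
#'
#' @param apen_m,apen_r ApEn embedding length and SD-fractional
#'   tolerance.
#' @param dfa_order DFA detrending polynomial order.
#' @param ct_margin slope margin above 0.5 for the correlation-time
#'   crossover.
#' @param rmsf_fit_frac,dfa_fit_frac upper fit bound as a fraction of
#'   series length for rmsf and DFA (default 1/8).
#' @param msd_fit_frac upper MSD lag as a fraction of trajectory length
#'   (default 1/10).
#' @return a list of metric parameters.
#' @export
metric_params <- function(apen_m = 2, apen_r = 0.2, dfa_order = 1,
                          ct_margin = 0.05, rmsf_fit_frac = 1 / 8,
                          dfa_fit_frac = 1 / 8, msd_fit_frac = 1 / 10) {
  list(apen_m = apen_m, apen_r = apen_r, dfa_order = dfa_order,
       ct_margin = ct_margin, rmsf_fit_frac = rmsf_fit_frac,
       dfa_fit_frac = dfa_fit_frac, msd_fit_frac = msd_fit_frac)
}

#' All migration metrics for one trajectory
#'
#' Computes the eight per-trajectory metrics -- rmsf alpha, correlation
#' time (min), MSD beta, DFA gamma (coordinate series, averaged), full
#' length step-series ApEn, intensity of response (mm), directionality
#' ratio, average speed (um/s) -- plus the directional descriptors
#' (cosine, angle, sector).  A metric that fails on a degenerate input
#' is reported as `NA` and its error message recorded in the
#' `"failures"` attribute, so one bad track never aborts a cohort run.
#'
#' @param traj a [trajectory()].
#' @param frame a [stimulus_frame()].
#' @param params a [metric_params()] list.
#' @return one-row data.frame of labels, directional descriptors and the
#'   8 metrics.
#' @export
trajectory_metrics <- function(traj, frame = stimulus_frame(),
                               params = metric_params()) {
  n <- n_frames(traj)
  ss <- step_series(traj)
  failures <- character()
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }

  rmsf_pack <- grab("rmsf", {
    cv <- rmsf_curve(ss)
    fit <- fit_scaling_exponent(cv, c(8, floor((n - 1) * params$rmsf_fit_frac)))
    ct <- correlation_time(cv, dt = traj$dt, margin = params$ct_margin)
    c(fit$exponent, ct$minutes)
  })
  if (length(rmsf_pack) == 1) rmsf_pack <- c(NA_real_, NA_real_)

  beta <- grab("msd", {
    cv <- msd_curve(traj, seq_len(max(2, floor(n * params$msd_fit_frac))))
    fit_scaling_exponent(cv)$exponent
  })
  gamma <- grab("dfa", dfa_trajectory(
    traj, log_spaced_scales(8, floor(n * params$dfa_fit_frac), 25),
    detrend_order = params$dfa_order))
  ap <- grab("apen", apen(ss, m = params$apen_m, r = params$apen_r))

  km <- kinematic_summary(traj, frame)
  out <- cbind(km[c("track_id", "cell_type", "scenario", "cosine",
                    "angle_deg", "sector")],
               data.frame(rmsf_alpha = rmsf_pack[1],
                          corr_time_min = rmsf_pack[2],
                          msd_beta = beta, dfa_gamma = gamma, apen = ap,
                          IR_mm = km$IR_mm, DR = km$DR,
                          AS_um_s = km$AS_um_s))
  attr(out, "failures") <- failures
  out
}

#' Run configuration for an end-to-end analysis
#'
#' Either `input` (a track file read with [read_tracks()]) or simulation
#' settings (`scenarios` x cell types via [scenario_preset()] /
#' [gen_cohort()]) define the cohort.
#'
#' @param input optional path to a track file; `NULL` simulates.
#' @param dialect,calibration,dt passed to [read_tracks()].
#' @param scenarios scenario labels to simulate.
#' @param n_cells walkers per scenario and cell type when simulating.
#' @param n_frames frames per simulated trajectory.
#' @param n_surrogates shuffled surrogates per trajectory (0 disables
#'   the null).
#' @param seed master seed; fans out to per-trajectory child seeds.
#' @param params a [metric_params()] list.
#' @param out_dir optional directory for result tables and the run log.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, dialect = "generic", calibration = 1,
                       dt = 0.5, scenarios = c("Sc1", "Sc2", "Sc3", "Sc4"),
                       n_cells = 10, n_frames = 4100, n_surrogates = 1,
                       seed = 1, params = metric_params(), out_dir = NULL) {
  structure(list(input = input, dialect = dialect,
                 calibration = calibration, dt = dt, scenarios = scenarios,
                 n_cells = n_cells, n_frames = as.integer(n_frames),
                 n_surrogates = n_surrogates, seed = as.integer(seed),
                 params = params, out_dir = out_dir),
            class = "run_config")
}

#' End-to-end analysis run
#'
#' Ingests (or simulates) a cohort, computes the per-trajectory metric
#' table, builds shuffled surrogates (position order for the
#' trajectory-level metrics, step-value order for rmsf/ApEn) and their
#' metric table, and compares cohorts nonparametrically.  Deterministic
#' given `cfg$seed`; failed metrics are reported per trajectory in the
#' run log, never silently dropped.
#'
#' @param cfg a [run_config()].
#' @return (invisibly if writing) a list: `metrics` (data.frame),
#'   `surrogate_metrics`, `summaries` (nucleated-vs-cytoplast),
#'   `exp_vs_shuffled` (per-metric Wilcoxon of experimental vs surrogate
#'   values), `log` (character vector), `config`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  frame <- stimulus_frame()
  log <- c(sprintf("run_analysis seed=%d n_surrogates=%g", cfg$seed,
                   cfg$n_surrogates),
           sprintf("config: %s", paste(
             sprintf("%s=%s", names(cfg)[1:8],
                     vapply(cfg[1:8], function(v)
                       paste(format(v), collapse = ","), character(1))),
             collapse = " ")))

  trajs <- if (!is.null(cfg$input)) {
    read_tracks(cfg$input, cfg$dialect, cfg$calibration, cfg$dt)
  } else {
    set.seed(cfg$seed)
    cohort_seeds <- sample.int(.Machine$integer.max - 1L,
                               2 * length(cfg$scenarios))
    i <- 0
    unlist(lapply(cfg$scenarios, function(sc) {
      pre <- scenario_preset(sc, n_frames = cfg$n_frames, dt = cfg$dt)
      lapply(c("nucleated", "cytoplast"), function(ct) {
        i <<- i + 1
        gen_cohort(pre, cfg$n_cells, seed = cohort_seeds[i], cell_type = ct)
      })
    }), recursive = FALSE)
  }
  if (is.list(trajs[[1]]) && !inherits(trajs[[1]], "trajectory"))
    trajs <- unlist(trajs, recursive = FALSE)
  log <- c(log, sprintf("trajectories: %d", length(trajs)))

  collect <- function(tr_list) {
    rows <- lapply(tr_list, function(tr) {
      m <- trajectory_metrics(tr, frame, cfg$params)
      fails <- attr(m, "failures")
      if (length(fails) > 0)
        log <<- c(log, sprintf("track %s: %s failed (%s)", tr$track_id,
                               paste(names(fails), collapse = ","),
                               paste(fails, collapse = "; ")))
      m
    })
    do.call(rbind, rows)
  }
  metrics <- collect(trajs)

  surrogate_metrics <- NULL
  if (cfg$n_surrogates >= 1) {
    set.seed(cfg$seed + 1L)
    child <- sample.int(.Machine$integer.max - 2L, length(trajs))
    surrogate_metrics <- do.call(rbind, lapply(seq_along(trajs), function(i) {
      tr <- trajs[[i]]
      spec <- surrogate_spec(n_surrogates = 1, seed = child[i])
      sh_tr <- shuffle_trajectory(tr, spec)[[1]]
      sh_ss <- shuffle_series(step_series(tr),
                              surrogate_spec(seed = child[i] + 1L))[[1]]
      m <- trajectory_metrics(sh_tr, frame, cfg$params)
      # rmsf/ApEn surrogates act on step-value order, not position order
      m$rmsf_alpha <- tryCatch({
        cv <- rmsf_curve(sh_ss)
        fit_scaling_exponent(
          cv, c(8, floor((n_frames(tr) - 1) *
                           cfg$params$rmsf_fit_frac)))$exponent
      }, error = function(e) NA_real_)
      m$corr_time_min <- tryCatch(
        correlation_time(rmsf_curve(sh_ss), dt = tr$dt,
                         margin = cfg$params$ct_margin)$minutes,
        error = function(e) NA_real_)
      m$apen <- tryCatch(
        apen(sh_ss, m = cfg$params$apen_m, r = cfg$params$apen_r),
        error = function(e) NA_real_)
      m
    }))
  }

  summaries <- if (length(unique(metrics$cell_type)) == 2)
    summarize_cohorts(metrics) else NULL

  exp_vs_shuffled <- NULL
  if (!is.null(surrogate_metrics)) {
    exp_vs_shuffled <- lapply(metric_columns(), function(mc) {
      a <- metrics[[mc]][!is.na(metrics[[mc]])]
      b <- surrogate_metrics[[mc]][!is.na(surrogate_metrics[[mc]])]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      wt <- wilcoxon_rank_sum(a, b)
      structure(list(metric_name = mc,
                     group_values = list(experimental = a, shuffled = b),
                     medians = c(median(a), median(b)),
                     iqrs = c(median_iqr(a)[["iqr"]], median_iqr(b)[["iqr"]]),
                     p_value = wt$p_value, z_stat = wt$z_stat,
                     test = "wilcoxon"),
                class = "cohort_summary")
    })
    exp_vs_shuffled <- Filter(Negate(is.null), exp_vs_shuffled)
  }

  bundle <- list(metrics = metrics, surrogate_metrics = surrogate_metrics,
                 summaries = summaries, exp_vs_shuffled = exp_vs_shuffled,
                 log = log, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
    if (!is.null(surrogate_metrics))
      write.csv(surrogate_metrics,
                file.path(cfg$out_dir, "surrogate_metrics.csv"),
                row.names = FALSE)
    if (!is.null(summaries))
      write_results_table(summaries,
                          file.path(cfg$out_dir, "results_table.csv"))
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
    return(invisible(bundle))
  }
  bundle
}

#' Frames recorded by the acquisition protocol
#'
#' Number of samples collected at a fixed rate over a recording period
#' (e.g. 2 Hz for 34 min 10 s gives 4,100 frames).
#'
#' @param rate_hz acquisition rate in frames per second.
#' @param duration_s recording duration in seconds.
#' @return integer frame count.
#' @export
protocol_frames <- function(rate_hz = 2, duration_s = 34 * 60 + 10) {
  as.integer(round(rate_hz * duration_s))
}
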