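#' Published cohort statistics regenerated by the default simulation
#'
#' The four cohort-level statistics reported for the 21-track simulated
#' cohort of this tug-of-war model (mean +/- SD across tracks): fitted
#' forward velocity 10.83 +/- 0.76 nm/s, fitted backward velocity magnitude
#' 6.77 +/- 0.38 nm/s, forward run duration 30.76 +/- 1.66 s, backward run
#' duration 25.91 +/- 1.40 s.  [reproduce_cohort()] prints these next to the
#' freshly simulated values.
#'
#' @return A `data.frame` with columns `statistic`, `reference_mean`,
#'   `reference_sd`.
#' @export
reference_cohort_values <- function() {
  data.frame(
    statistic = c("forward_v_nm_s", "backward_v_nm_s", "forward_run_s",
                  "backward_run_s"),
    reference_mean = c(10.83, 6.77, 30.76, 25.91),
    reference_sd = c(0.76, 0.38, 1.66, 1.40))
}

#' Motor-number robustness sweep
#'
#' Re-runs the simulated cohort at several total motor counts and summarizes
#' each: the transport pattern (forward-dominant saltatory motion with net
#' apexward displacement) should not depend on the unknown motor number.
#'
#' @param n_motors Motor counts to sweep, default `c(30, 50, 70, 100)`.
#' @inheritParams simulate_cohort
#' @inheritParams track_stats
#' @return A `data.frame`, one row per motor count: cohort mean forward and
#'   backward fitted velocities (nm/s), mean run durations (s), mean net
#'   velocity (nm/s) and the fraction of tracks with positive net
#'   displacement.
#' @export
motor_number_sweep <- function(n_motors = c(30, 50, 70, 100), n_tracks = 21,
                               duration = 3600, frame_interval = 5, seed = 1,
                               threshold = 1, bin_width = 1) {
  rows <- lapply(n_motors, function(nn) {
    cohort <- simulate_cohort(default_tow_params(n_motors = nn),
                              n_tracks = n_tracks, duration = duration,
                              frame_interval = frame_interval, seed = seed)
    st <- cohort_stats(cohort, threshold = threshold, bin_width = bin_width)
    data.frame(n_motors = nn,
               forward_v_nm_s = mean(st$forward_v_nm_s, na.rm = TRUE),
               backward_v_nm_s = mean(st$backward_v_nm_s, na.rm = TRUE),
               forward_run_s = mean(st$forward_run_s, na.rm = TRUE),
               backward_run_s = mean(st$backward_run_s, na.rm = TRUE),
               net_v_nm_s = mean(st$net_v_nm_s),
               frac_net_forward = mean(st$net_v_nm_s > 0))
  })
  do.call(rbind, rows)
}

#' Regenerate the simulated cohort results end to end
#'
#' Runs the full pipeline at the default study conditions: a 21-track
#' simulated cohort (N = 70 motors, 3600 s per track, 5 s frames), run/pause
#' segmentation and displacement-weighted Gaussian velocity fits per track,
#' cohort means +/- SD side by side with the published reference values, the
#' paired forward-vs-backward tests, and the motor-number robustness sweep.
#'
#' @param params A [tow_params()]; default the standard KCH set.
#' @inheritParams simulate_cohort
#' @inheritParams track_stats
#' @param test Paired test passed to [cohort_compare()].
#' @param sweep_n Motor counts for the robustness sweep; `NULL` skips it.
#' @return A list of class `tow_report`: `cohort_summary` (model vs
#'   reference), `p_velocity`, `p_run_duration`, `stats` (per track),
#'   `sweep`, `config` (resolved settings incl. seed).
#' @export
#' @examples
#' \donttest{
#' rep <- reproduce_cohort(seed = 1)
#' print(rep)
#' }
reproduce_cohort <- function(params = default_tow_params(), n_tracks = 21,
                             duration = 3600, frame_interval = 5, seed = 1,
                             threshold = 1, bin_width = 1, test = "t",
                             sweep_n = c(30, 50, 70, 100)) {
  cohort <- simulate_cohort(params, n_tracks = n_tracks, duration = duration,
                            frame_interval = frame_interval, seed = seed)
  st <- cohort_stats(cohort, threshold = threshold, bin_width = bin_width)
  cmp <- cohort_compare(st, test = test)
  summary <- merge(cmp$summary, reference_cohort_values(), by = "statistic",
                   sort = FALSE)
  sweep <- if (!is.null(sweep_n)) {
    motor_number_sweep(sweep_n, n_tracks = n_tracks, duration = duration,
                       frame_interval = frame_interval, seed = seed,
                       threshold = threshold, bin_width = bin_width)
  }
  structure(list(
    cohort_summary = summary,
    p_velocity = cmp$p_velocity,
    p_run_duration = cmp$p_run_duration,
    stats = st,
    sweep = sweep,
    config = list(n_motors = params$n_motors, n_tracks = n_tracks,
                  duration_s = duration, frame_interval_s = frame_interval,
                  threshold_nm_s = threshold, bin_width_nm_s = bin_width,
                  test = test, seed = seed)),
    class = "tow_report")
}

#' @export
print.tow_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "simulated cohort: %d tracks x %g s, N = %d motors, dt = %g s, seed %s\n",
    cfg$n_tracks, cfg$duration_s, cfg$n_motors, cfg$frame_interval_s,
    format(cfg$seed)))
  s <- x$cohort_summary
  cat(sprintf("  %-16s %10s %14s\n", "statistic", "model", "reference"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %5.2f +/- %4.2f %7.2f +/- %4.2f\n", s$statistic[i],
                s$mean[i], s$sd[i], s$reference_mean[i], s$reference_sd[i]))
  }
  cat(sprintf("  paired p: velocity %.3g, run duration %.3g (%s test)\n",
              x$p_velocity, x$p_run_duration, cfg$test))
  if (!is.null(x$sweep)) {
    cat("motor-number sweep:\n")
    print(x$sweep, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
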