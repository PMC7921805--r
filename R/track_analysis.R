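#' Point-to-point displacements of a sampled track
#'
#' One record per consecutive frame pair: signed displacement, frame
#' velocity, and a movement class.  Positive displacements are forward
#' (apexward) movement, negative ones backward movement; frame intervals
#' whose speed does not exceed the velocity threshold count as pauses
#' (a speed exactly at the threshold is a pause).
#'
#' @param track A [sampled_track()] (or data frame with `time_s`,
#'   `position_um`), at least 2 frames, strictly increasing times.
#' @param threshold Pause threshold (nm/s), default 1.
#' @return A `data.frame` with columns `t_start`, `t_end`, `dt_s`, `dx_um`,
#'   `v_nm_s` and `class` (factor: forward / backward / pause).  The
#'   displacements sum exactly to the end-to-end displacement.
#' @export
#' @examples
#' trk <- sampled_track(c(0, 5, 10), c(0, 0.05, 0.05), 5)
#' point_displacements(trk)  # v = 10, 0 nm/s
point_displacements <- function(track, threshold = 1) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "position_um") %in% names(track)))
  if (nrow(track) < 2) stop("track needs at least 2 frames")
  tt <- track$time_s
  xx <- track$position_um
  if (any(diff(tt) <= 0)) stop("track times must be strictly increasing")
  if (!is.finite(threshold) || threshold < 0) stop("threshold must be >= 0")
  n <- length(tt)
  dt <- diff(tt)
  dx <- diff(xx)
  v <- dx / dt * 1000  # nm/s
  cls <- ifelse(v > threshold, "forward",
                ifelse(v < -threshold, "backward", "pause"))
  data.frame(t_start = tt[-n], t_end = tt[-1], dt_s = dt, dx_um = dx,
             v_nm_s = v,
             class = factor(cls, levels = c("forward", "backward", "pause")))
}

#' Merge classified frame intervals into runs and pauses
#'
#' Maximal blocks of consecutive same-class intervals become one run (or
#' pause).  The output tiles the track with no gaps or overlaps, so run
#' durations sum to the track duration and run displacements to the
#' end-to-end displacement.  By default a single supra-threshold interval
#' already constitutes a run; `min_intervals = 2` implements the stricter
#' reading in which a directed run needs more than one displacement, shorter
#' directed blocks being reclassified as pause and merged with their
#' neighbours.
#'
#' @param intervals Output of [point_displacements()].
#' @param min_intervals Minimum number of frame intervals for a directed
#'   block to count as a run (default 1).
#' @return A `data.frame` with one row per run: `class`, `t_start`, `t_end`,
#'   `duration_s`, `displacement_um`, `mean_v_nm_s`, `n_intervals`.
#' @export
#' @examples
#' trk <- sampled_track(seq(0, 25, 5), cumsum(c(0, 10, 15, -2.5, -10, -10)) / 1000, 5)
#' segment_runs(point_displacements(trk))
segment_runs <- function(intervals, min_intervals = 1) {
  stopifnot(is.data.frame(intervals),
            all(c("t_start", "t_end", "dx_um", "class") %in% names(intervals)))
  if (min_intervals < 1) stop("min_intervals must be >= 1")
  cls <- as.character(intervals$class)
  if (min_intervals > 1) {
    r <- rle(cls)
    short <- r$values != "pause" & r$lengths < min_intervals
    r$values[short] <- "pause"
    cls <- inverse.rle(r)
  }
  r <- rle(cls)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1
  duration <- intervals$t_end[idx_end] - intervals$t_start[idx_start]
  displacement <- vapply(seq_along(idx_start), function(i) {
    sum(intervals$dx_um[idx_start[i]:idx_end[i]])
  }, numeric(1))
  data.frame(
    class = factor(r$values, levels = c("forward", "backward", "pause")),
    t_start = intervals$t_start[idx_start],
    t_end = intervals$t_end[idx_end],
    duration_s = duration,
    displacement_um = displacement,
    mean_v_nm_s = displacement / duration * 1000,
    n_intervals = r$lengths)
}

#' Displacement-weighted velocity distribution with Gaussian fit
#'
#' Histogram of the frame-interval velocities of one movement direction in
#' which each interval contributes weight `|dx|`, i.e. the distance covered
#' in that interval, so fast intervals count in proportion to the path they
#' explain.  A three-parameter Gaussian `a * exp(-(v - mu)^2 / (2 sigma^2))`
#' is least-squares fitted to bin centres versus weights; with fewer than 4
#' populated bins (or a failed fit) the fit is marked unavailable and the
#' displacement-weighted moments remain as the fallback summary.
#'
#' @param intervals Output of [point_displacements()].
#' @param direction `"forward"` or `"backward"`.
#' @param bin_width Histogram bin width (nm/s), default 1.
#' @return A list of class `velocity_distribution`: `direction`, `bins`
#'   (data frame `mid`, `weight`), `fit_mean`, `fit_sd`, `fit_ok`,
#'   `weighted_mean`, `weighted_sd`, `total_weight` (um).  Velocities in
#'   nm/s.
#' @export
weighted_velocity_distribution <- function(intervals,
                                           direction = c("forward",
                                                         "backward"),
                                           bin_width = 1) {
  direction <- match.arg(direction)
  stopifnot(bin_width > 0)
  sel <- intervals[intervals$class == direction, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no ", direction, " intervals in this track")
  }
  v <- sel$v_nm_s
  w <- abs(sel$dx_um)
  wm <- sum(w * v) / sum(w)
  wsd <- sqrt(sum(w * (v - wm)^2) / sum(w))

  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  weight <- vapply(seq_len(length(edges) - 1),
                   function(i) sum(w[idx == i]), numeric(1))
  mids <- edges[-length(edges)] + bin_width / 2

  fit_ok <- FALSE
  fit_mean <- NA_real_
  fit_sd <- NA_real_
  if (sum(weight > 0) >= 4) {
    dat <- data.frame(mid = mids, weight = weight)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        weight ~ a * exp(-(mid - mu)^2 / (2 * sig^2)), data = dat,
        start = list(a = max(weight), mu = wm, sig = max(wsd, bin_width / 2)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- stats::coef(fit)
      mu <- unname(est[["mu"]])
      sig <- abs(unname(est[["sig"]]))
      # a least-squares Gaussian on a flat or monotone histogram can run away;
      # accept the fit only if its center and width describe the observed data
      if (is.finite(mu) && is.finite(sig) && sig > 0 &&
          mu >= lo - bin_width && mu <= hi + bin_width && sig <= (hi - lo)) {
        fit_ok <- TRUE
        fit_mean <- mu
        fit_sd <- sig
      }
    }
  }
  structure(list(direction = direction,
                 bins = data.frame(mid = mids, weight = weight),
                 fit_mean = fit_mean, fit_sd = fit_sd, fit_ok = fit_ok,
                 weighted_mean = wm, weighted_sd = wsd,
                 total_weight = sum(w)),
            class = "velocity_distribution")
}

#' @export
print.velocity_distribution <- function(x, ...) {
  cat(sprintf("%s displacement-weighted velocity distribution\n", x$direction))
  if (x$fit_ok) {
    cat(sprintf("  Gaussian fit: %.2f +/- %.2f nm/s\n", x$fit_mean, x$fit_sd))
  } else {
    cat("  Gaussian fit unavailable (too few populated bins)\n")
  }
  cat(sprintf("  weighted moments: %.2f +/- %.2f nm/s over %.3f um\n",
              x$weighted_mean, x$weighted_sd, x$total_weight))
  invisible(x)
}

# fitted velocity with weighted-moment fallback
.direction_velocity <- function(intervals, direction, bin_width) {
  vd <- weighted_velocity_distribution(intervals, direction, bin_width)
  if (vd$fit_ok) vd$fit_mean else vd$weighted_mean
}

#' Per-track movement statistics
#'
#' The per-track summary used for cohort comparison: Gaussian-fitted mean
#' velocities of the displacement-weighted distributions (forward signed +,
#' backward reported as a magnitude with its sign convention noted below),
#' mean run durations per direction, and the net velocity
#' (end-to-end displacement over track duration).  Directions with no
#' qualifying run yield `NA`, never zero.  Backward interval velocities are
#' negative internally; `backward_v_nm_s` is their fitted mean magnitude.
#'
#' @inheritParams point_displacements
#' @param bin_width Histogram bin width for the velocity distributions
#'   (nm/s).
#' @param min_intervals Passed to [segment_runs()].
#' @return A one-row `data.frame`: `forward_v_nm_s`, `backward_v_nm_s`,
#'   `forward_run_s`, `backward_run_s`, `net_v_nm_s`, `n_forward_runs`,
#'   `n_backward_runs`.
#' @export
track_stats <- function(track, threshold = 1, bin_width = 1,
                        min_intervals = 1) {
  intervals <- point_displacements(track, threshold)
  runs <- segment_runs(intervals, min_intervals)
  fwd_runs <- runs[runs$class == "forward", , drop = FALSE]
  bwd_runs <- runs[runs$class == "backward", , drop = FALSE]

  fwd_v <- if (any(intervals$class == "forward")) {
    .direction_velocity(intervals, "forward", bin_width)
  } else NA_real_
  bwd_v <- if (any(intervals$class == "backward")) {
    abs(.direction_velocity(intervals, "backward", bin_width))
  } else NA_real_

  span <- track$time_s[nrow(track)] - track$time_s[1]
  data.frame(
    forward_v_nm_s = fwd_v,
    backward_v_nm_s = bwd_v,
    forward_run_s = if (nrow(fwd_runs)) mean(fwd_runs$duration_s) else NA_real_,
    backward_run_s = if (nrow(bwd_runs)) mean(bwd_runs$duration_s) else NA_real_,
    net_v_nm_s = (track$position_um[nrow(track)] - track$position_um[1]) /
      span * 1000,
    n_forward_runs = nrow(fwd_runs),
    n_backward_runs = nrow(bwd_runs))
}

#' Per-track statistics for a whole cohort
#'
#' Applies [track_stats()] to every track of a list or [simulate_cohort()]
#' result and binds the rows with a `track_id` column.
#'
#' @param tracks A `tow_cohort` or (named) list of [sampled_track()]s.
#' @inheritParams track_stats
#' @return A `data.frame`, one row per track.
#' @export
cohort_stats <- function(tracks, threshold = 1, bin_width = 1,
                         min_intervals = 1) {
  stopifnot(length(tracks) >= 1)
  ids <- names(tracks)
  if (is.null(ids)) ids <- sprintf("track%02d", seq_along(tracks))
  rows <- lapply(seq_along(tracks), function(i) {
    cbind(data.frame(track_id = ids[i]),
          track_stats(tracks[[i]], threshold, bin_width, min_intervals))
  })
  do.call(rbind, rows)
}

#' Paired cohort comparison of forward versus backward movement
#'
#' Cohort means and SDs of the four per-track statistics, plus paired
#' two-sided tests of forward versus backward magnitude for fitted velocity
#' and for run duration across tracks.  A paired t-test is the default; a
#' Wilcoxon signed-rank test is available as the distribution-free
#' alternative.  Tracks missing either direction are dropped from the pairs.
#'
#' @param stats Output of [cohort_stats()].
#' @param test `"t"` (paired t-test) or `"wilcoxon"` (signed rank).
#' @return A list of class `cohort_comparison`: `summary` (mean, sd, n per
#'   statistic), `p_velocity`, `p_run_duration`, `n_pairs`, `test`.
#' @export
cohort_compare <- function(stats, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  cols <- c("forward_v_nm_s", "backward_v_nm_s", "forward_run_s",
            "backward_run_s")
  stopifnot(all(cols %in% names(stats)))
  complete <- stats[stats$n_forward_runs > 0 & stats$n_backward_runs > 0, ,
                    drop = FALSE]
  if (nrow(complete) < 3) {
    stop("need at least 3 tracks with both forward and backward runs")
  }
  pair_test <- function(a, b) {
    if (test == "t") {
      t.test(a, b, paired = TRUE, alternative = "two.sided")$p.value
    } else {
      wilcox.test(a, b, paired = TRUE, alternative = "two.sided",
                  exact = FALSE)$p.value
    }
  }
  summary <- data.frame(
    statistic = cols,
    mean = vapply(cols, function(cc) mean(stats[[cc]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(cols, function(cc) sd(stats[[cc]], na.rm = TRUE), numeric(1)),
    n = vapply(cols, function(cc) sum(is.finite(stats[[cc]])), integer(1)),
    row.names = NULL)
  structure(list(
    summary = summary,
    p_velocity = pair_test(complete$forward_v_nm_s, complete$backward_v_nm_s),
    p_run_duration = pair_test(complete$forward_run_s,
                               complete$backward_run_s),
    n_pairs = nrow(complete), test = test),
    class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("paired forward-vs-backward comparison (%s test, %d pairs)\n",
              if (x$test == "t") "paired t" else "Wilcoxon signed-rank",
              x$n_pairs))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-16s %7.2f +/- %5.2f (n = %d)\n", s$statistic[i],
                s$mean[i], s$sd[i], s$n[i]))
  }
  cat(sprintf("  p (velocity)     = %.3g\n  p (run duration) = %.3g\n",
              x$p_velocity, x$p_run_duration))
  invisible(x)
}
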