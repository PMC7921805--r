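#' Segment list for a synthetic track
#'
#' Validated building block of the synthetic generator: an ordered list of
#' piecewise-constant-velocity segments (forward run, backward run, pause)
#' with durations in seconds and velocities in nm/s (0 for pauses).
#'
#' @param class Character vector: `"forward"`, `"backward"` or `"pause"`.
#' @param duration_s Segment durations (s), `> 0`.
#' @param velocity_nm_s Segment velocities (nm/s); sign must match the class
#'   and exceed `threshold` in magnitude for directed segments, 0 for pauses.
#' @param threshold Pause threshold the segments must respect (nm/s).
#' @return A `data.frame` of class `track_segments`.
#' @export
#' @examples
#' track_segments(c("forward", "pause", "backward"), c(100, 40, 60),
#'                c(12, 0, -8))
track_segments <- function(class, duration_s, velocity_nm_s, threshold = 1) {
  class <- as.character(class)
  stopifnot(length(class) == length(duration_s),
            length(class) == length(velocity_nm_s))
  if (length(class) == 0) stop("empty segment list")
  if (!all(class %in% c("forward", "backward", "pause"))) {
    stop("segment class must be forward, backward or pause")
  }
  if (any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop("segment durations must be finite and > 0")
  }
  ok <- (class == "forward" & velocity_nm_s > threshold) |
    (class == "backward" & velocity_nm_s < -threshold) |
    (class == "pause" & velocity_nm_s == 0)
  if (!all(ok)) {
    stop("segment velocities must match their class and exceed the threshold")
  }
  structure(data.frame(class = factor(class, levels = c("forward", "backward",
                                                        "pause")),
                       duration_s = duration_s,
                       velocity_nm_s = velocity_nm_s),
            class = c("track_segments", "data.frame"))
}

#' Build one synthetic track from labelled segments
#'
#' Samples the piecewise-linear position implied by the segments on a uniform
#' frame grid and adds i.i.d. Gaussian localization noise per frame,
#' emulating sub-pixel tracker output.  The exact segment boundaries come
#' back as ground truth, so analysis results can be checked against what the
#' generator actually put in.
#'
#' @param segments A [track_segments()] data frame (total duration at least
#'   two frame intervals).
#' @param frame_interval Frame interval (s), default 5.
#' @param noise_sd Localization noise SD (nm) added per frame, default 0.
#' @param seed Optional integer seed for the noise draw.
#' @return A list with `track` (a [sampled_track()], provenance
#'   `"synthetic"`) and `truth` (segments with `t_start`, `t_end`,
#'   `displacement_um` added).
#' @export
#' @examples
#' seg <- track_segments(c("forward", "pause"), c(100, 50), c(10, 0))
#' out <- make_track(seg, frame_interval = 5)
#' head(out$track)
make_track <- function(segments, frame_interval = 5, noise_sd = 0,
                       seed = NULL) {
  if (!inherits(segments, "track_segments")) {
    segments <- track_segments(segments$class, segments$duration_s,
                               segments$velocity_nm_s)
  }
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  total <- sum(segments$duration_s)
  if (total < 2 * frame_interval) {
    stop("total duration must cover at least two frame intervals")
  }
  if (!is.null(seed)) set.seed(seed)
  t_end <- cumsum(segments$duration_s)
  t_start <- c(0, t_end[-length(t_end)])
  dx <- segments$velocity_nm_s / 1000 * segments$duration_s  # um
  x_break <- c(0, cumsum(dx))
  grid <- seq(0, floor(total / frame_interval + 1e-9)) * frame_interval
  grid[length(grid)] <- min(grid[length(grid)], total)
  pos <- approx(c(0, t_end), x_break, xout = grid, method = "linear",
                ties = "ordered")$y
  if (noise_sd > 0) pos <- pos + rnorm(length(pos), 0, noise_sd / 1000)
  truth <- cbind(as.data.frame(segments), t_start = t_start, t_end = t_end,
                 displacement_um = dx)
  list(track = sampled_track(grid, pos, frame_interval,
                             provenance = "synthetic"),
       truth = truth)
}

#' Specification of a synthetic saltatory cohort
#'
#' Distributional description of a cohort of tracked cells moving in
#' alternating runs and pauses.  Defaults emulate the in vivo regime of
#' sperm-cell transport in pollen tubes: forward runs around 10.85 +/- 1.93
#' nm/s lasting 44.89 +/- 39.69 s, backward runs around 9.06 +/- 4.45 nm/s
#' (magnitude) lasting 32.03 +/- 25.15 s, with pauses in between.  These are
#' generator regimes for validating the analysis pipeline, not reproduction
#' targets.  Run and pause durations are drawn from normal distributions
#' truncated at one frame interval (`duration_dist = "exponential"` switches
#' to truncated exponentials with the same means); run speeds are truncated
#' at the pause threshold.
#'
#' @param n_tracks Number of tracks, default 21.
#' @param duration_s Track duration (s), default 3600.
#' @param frame_interval Frame interval (s), default 5.
#' @param forward_v_mean,forward_v_sd Forward run speed distribution (nm/s).
#' @param backward_v_mean,backward_v_sd Backward run speed magnitude
#'   distribution (nm/s).
#' @param forward_run_mean,forward_run_sd Forward run duration distribution
#'   (s).
#' @param backward_run_mean,backward_run_sd Backward run duration
#'   distribution (s).
#' @param pause_mean,pause_sd Pause duration distribution (s).
#' @param p_forward Probability that a run goes forward, default 0.5.
#' @param noise_sd Localization noise SD (nm), default 10.
#' @param threshold Pause threshold (nm/s) run speeds must exceed.
#' @param duration_dist `"truncnorm"` (default) or `"exponential"`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tracks = 21, duration_s = 3600, frame_interval = 5,
                        forward_v_mean = 10.85, forward_v_sd = 1.93,
                        backward_v_mean = 9.06, backward_v_sd = 4.45,
                        forward_run_mean = 44.89, forward_run_sd = 39.69,
                        backward_run_mean = 32.03, backward_run_sd = 25.15,
                        pause_mean = 20, pause_sd = 15, p_forward = 0.5,
                        noise_sd = 10, threshold = 1,
                        duration_dist = c("truncnorm", "exponential")) {
  duration_dist <- match.arg(duration_dist)
  spec <- list(n_tracks = n_tracks, duration_s = duration_s,
               frame_interval = frame_interval,
               forward_v_mean = forward_v_mean, forward_v_sd = forward_v_sd,
               backward_v_mean = backward_v_mean,
               backward_v_sd = backward_v_sd,
               forward_run_mean = forward_run_mean,
               forward_run_sd = forward_run_sd,
               backward_run_mean = backward_run_mean,
               backward_run_sd = backward_run_sd,
               pause_mean = pause_mean, pause_sd = pause_sd,
               p_forward = p_forward, noise_sd = noise_sd,
               threshold = threshold, duration_dist = duration_dist)
  sds <- c(forward_v_sd, backward_v_sd, forward_run_sd, backward_run_sd,
           pause_sd, noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stop("all SDs must be >= 0")
  if (n_tracks < 1 || duration_s <= 0 || frame_interval <= 0) {
    stop("invalid cohort dimensions")
  }
  if (p_forward <= 0 || p_forward >= 1) {
    stop("p_forward must be strictly between 0 and 1")
  }
  structure(spec, class = "cohort_spec")
}

# rejection sampler for a lower-truncated normal (or exponential); errors
# out if the distribution cannot reach the bound
.rtrunc <- function(n, mean, sd, lower, dist = "truncnorm",
                    max_tries = 10000) {
  if (dist == "exponential") {
    draw <- function(k) rexp(k, rate = 1 / mean)
  } else {
    if (sd == 0) {
      if (mean < lower) {
        stop("degenerate distribution (sd = 0) lies below its truncation bound")
      }
      return(rep(mean, n))
    }
    draw <- function(k) rnorm(k, mean, sd)
  }
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    cand <- draw(n)
    out <- c(out, cand[cand >= lower])
    tries <- tries + 1
    if (tries > max_tries) {
      stop("cannot satisfy truncation bound: distribution mass below ", lower)
    }
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws, for each track, an alternating sequence of directed runs and pauses
#' (run direction Bernoulli with `p_forward`, durations and speeds from the
#' spec's truncated distributions), trims the last segment to the track
#' duration, and renders each track with [make_track()].  Fully reproducible
#' from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Cohort seed, default 1.
#' @return A list with `tracks` (named list of [sampled_track()]s, class
#'   `tow_cohort`-like plain list), `truth` (named list of ground-truth
#'   segment tables), `spec`, `seed`.
#' @export
#' @examples
#' syn <- make_cohort(cohort_spec(n_tracks = 3, duration_s = 600), seed = 7)
#' names(syn$tracks)
make_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  track_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_tracks)
  dt <- spec$frame_interval
  one_track <- function(ts) {
    set.seed(ts)
    cls <- character(0)
    dur <- numeric(0)
    vel <- numeric(0)
    total <- 0
    make_run <- TRUE
    while (total < spec$duration_s) {
      if (make_run) {
        fwd <- runif(1) < spec$p_forward
        d <- .rtrunc(1, if (fwd) spec$forward_run_mean else
                          spec$backward_run_mean,
                     if (fwd) spec$forward_run_sd else spec$backward_run_sd,
                     lower = dt, dist = spec$duration_dist)
        sp <- .rtrunc(1, if (fwd) spec$forward_v_mean else
                           spec$backward_v_mean,
                      if (fwd) spec$forward_v_sd else spec$backward_v_sd,
                      lower = spec$threshold * 1.000001, dist = "truncnorm")
        cls <- c(cls, if (fwd) "forward" else "backward")
        vel <- c(vel, if (fwd) sp else -sp)
      } else {
        d <- .rtrunc(1, spec$pause_mean, spec$pause_sd, lower = dt,
                     dist = spec$duration_dist)
        cls <- c(cls, "pause")
        vel <- c(vel, 0)
      }
      dur <- c(dur, d)
      total <- total + d
      make_run <- !make_run
    }
    # trim the final segment so the track spans exactly duration_s; if the
    # remnant is shorter than one frame, fold it into the previous segment
    excess <- total - spec$duration_s
    dur[length(dur)] <- dur[length(dur)] - excess
    if (dur[length(dur)] < dt && length(dur) > 1) {
      leftover <- dur[length(dur)]
      cls <- cls[-length(cls)]
      dur <- dur[-length(dur)]
      vel <- vel[-length(vel)]
      dur[length(dur)] <- dur[length(dur)] + leftover
    }
    seg <- track_segments(cls, dur, vel, threshold = spec$threshold)
    make_track(seg, frame_interval = dt, noise_sd = spec$noise_sd)
  }
  built <- lapply(track_seeds, one_track)
  ids <- sprintf("track%02d", seq_len(spec$n_tracks))
  tracks <- stats::setNames(lapply(built, `[[`, "track"), ids)
  truth <- stats::setNames(lapply(built, `[[`, "truth"), ids)
  list(tracks = tracks, truth = truth, spec = spec, seed = seed)
}
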