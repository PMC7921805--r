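#' @useDynLib kchtow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx rexp rnorm runif sd t.test wilcox.test
#' @importFrom utils read.csv write.csv
NULL

#' Reaction-channel propensities for one motor occupancy state
#'
#' The motor-binding dynamics form a continuous-time Markov chain over
#' `(n_plus, n_minus)` with four channels.  Both bind channels draw on the
#' single shared free pool of `n_motors - n_plus - n_minus` motors; each
#' unbind channel is the per-motor load-dependent unbinding rate times the
#' number of bound motors of that team, evaluated at the per-motor share
#' `F_c / n` of the cargo force.
#'
#' @inheritParams cargo_mechanics
#' @return A list with `bind_plus`, `bind_minus`, `unbind_plus`,
#'   `unbind_minus` and their sum `total` (all 1/s).
#' @export
#' @examples
#' event_rates(0, 0, default_tow_params())  # bind-only: 49 + 42 = 91 /s
event_rates <- function(n_plus, n_minus, params) {
  mech <- cargo_mechanics(n_plus, n_minus, params)
  free <- params$n_motors - n_plus - n_minus
  bind_plus <- free * params$forward$binding_rate
  bind_minus <- free * params$backward$binding_rate
  unbind_plus <- if (n_plus > 0) {
    n_plus * unbinding_rate(mech$force / n_plus, params$forward)
  } else 0
  unbind_minus <- if (n_minus > 0) {
    n_minus * unbinding_rate(mech$force / n_minus, params$backward)
  } else 0
  list(bind_plus = bind_plus, bind_minus = bind_minus,
       unbind_plus = unbind_plus, unbind_minus = unbind_minus,
       total = bind_plus + bind_minus + unbind_plus + unbind_minus)
}

#' One Gillespie step from a motor occupancy state
#'
#' Draws an exponential waiting time at the total propensity and picks one of
#' the four channels with probability proportional to its rate.  This R-level
#' step exists for inspection and testing; [simulate_trajectory()] runs the
#' same scheme in compiled code.
#'
#' @inheritParams cargo_mechanics
#' @return A list with `tau` (waiting time, s), `n_plus`, `n_minus` (the new
#'   state) and `channel` (which event fired).
#' @export
ssa_step <- function(n_plus, n_minus, params) {
  r <- event_rates(n_plus, n_minus, params)
  if (r$total <= 0) stop("total event rate is zero: corrupt motor state")
  tau <- rexp(1, rate = r$total)
  channel <- sample(c("bind_plus", "bind_minus", "unbind_plus",
                      "unbind_minus"), size = 1,
                    prob = c(r$bind_plus, r$bind_minus, r$unbind_plus,
                             r$unbind_minus))
  switch(channel,
         bind_plus = n_plus <- n_plus + 1,
         bind_minus = n_minus <- n_minus + 1,
         unbind_plus = n_plus <- n_plus - 1,
         unbind_minus = n_minus <- n_minus - 1)
  list(tau = tau, n_plus = n_plus, n_minus = n_minus, channel = channel)
}

#' Simulate one cargo trajectory with the exact SSA
#'
#' Starts from the fully unbound state, iterates Gillespie steps until the
#' requested duration is reached, and advances the cargo position linearly at
#' the pre-event cargo velocity over each waiting time.  Event epochs are
#' non-uniform in time; use [downsample()] to obtain a uniform frame grid.
#'
#' Relaxation from the unbound start to the binding/unbinding steady state
#' takes a few seconds (rates of order 1/s), negligible against hour-long
#' tracks; an optional `burn_in` discards an initial stretch and re-zeroes
#' clock and position if a strictly stationary start is wanted.
#'
#' @param params A [tow_params()].
#' @param duration Track duration (s), `> 0` (`0` returns the initial epoch
#'   only).
#' @param seed Integer seed; the same `(params, duration, seed)` gives a
#'   bit-identical trajectory.  `NULL` uses the current RNG state.
#' @param burn_in Discarded initial stretch (s), default 0.
#' @param max_events Optional cap on the number of simulated events (mainly
#'   for long stationary-distribution runs); `Inf` for no cap.
#' @return A `data.frame` of class `tow_trajectory` with columns `time_s`
#'   (strictly increasing event epochs starting at 0), `position_um` (cargo
#'   position, + = apexward, 0 at start), `n_plus`, `n_minus`.  Attributes:
#'   `params`, `seed`, `n_events`, `truncated`.
#' @export
#' @examples
#' traj <- simulate_trajectory(default_tow_params(), duration = 60, seed = 1)
#' head(traj)
simulate_trajectory <- function(params, duration, seed = NULL, burn_in = 0,
                                max_events = Inf) {
  stopifnot(inherits(params, "tow_params"))
  if (!is.finite(duration) || duration < 0) {
    stop("duration must be finite and >= 0")
  }
  if (!is.finite(burn_in) || burn_in < 0) stop("burn_in must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  team_vec <- function(tm) {
    c(tm$stall_force, tm$detachment_force, tm$binding_rate,
      tm$unbinding_rate, tm$forward_speed, tm$backslip_speed)
  }
  if (duration == 0) {
    out <- data.frame(time_s = 0, position_um = 0, n_plus = 0L, n_minus = 0L)
    attr(out, "n_events") <- 0
    attr(out, "truncated") <- FALSE
  } else {
    raw <- .ssa_simulate_cpp(params$n_motors, team_vec(params$forward),
                             team_vec(params$backward), duration, burn_in,
                             if (is.finite(max_events)) max_events else 0)
    out <- data.frame(time_s = raw$time_s, position_um = raw$position_um,
                      n_plus = raw$n_plus, n_minus = raw$n_minus)
    attr(out, "n_events") <- raw$n_events
    attr(out, "truncated") <- raw$truncated
  }
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("tow_trajectory", "data.frame")
  out
}

#' Construct a uniformly sampled track
#'
#' The common currency of the analysis pipeline: positions on a uniform time
#' grid, whether produced by downsampling a simulated trajectory, by the
#' synthetic generator, or read from tracker output.
#'
#' @param time_s Uniform time grid (s), starting at its first frame.
#' @param position_um Positions (um), same length as `time_s`.
#' @param frame_interval Frame interval (s).
#' @param provenance One of `"simulated"`, `"synthetic"`, `"experimental"`.
#' @return A `data.frame` of class `sampled_track`.
#' @export
sampled_track <- function(time_s, position_um, frame_interval,
                          provenance = c("experimental", "simulated",
                                         "synthetic")) {
  provenance <- match.arg(provenance)
  if (length(time_s) != length(position_um)) {
    stop("time_s and position_um must have equal length")
  }
  if (!all(is.finite(time_s)) || !all(is.finite(position_um))) {
    stop("times and positions must be finite")
  }
  if (length(time_s) >= 2) {
    dts <- diff(time_s)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (max(abs(dts - frame_interval)) > 1e-6 * frame_interval) {
      stop("time grid is not uniform at the stated frame interval")
    }
  }
  out <- data.frame(time_s = time_s, position_um = position_um)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "provenance") <- provenance
  class(out) <- c("sampled_track", "data.frame")
  out
}

#' Downsample an event-time trajectory to a uniform frame grid
#'
#' Evaluates the piecewise-linear cargo path at multiples of the frame
#' interval by linear interpolation between the bracketing event epochs,
#' emulating a camera sampling the process at a fixed frame rate.  No
#' extrapolation: the grid stops at the last epoch.
#'
#' @param traj A [simulate_trajectory()] result (or any data frame with
#'   strictly increasing `time_s` and `position_um`).
#' @param frame_interval Frame interval `dt` (s), `> 0` and no longer than
#'   the trajectory span.
#' @return A [sampled_track()] with provenance `"simulated"`.
#' @export
#' @examples
#' traj <- simulate_trajectory(default_tow_params(), duration = 100, seed = 1)
#' trk <- downsample(traj, frame_interval = 5)
downsample <- function(traj, frame_interval) {
  stopifnot(is.data.frame(traj), all(c("time_s", "position_um") %in%
                                       names(traj)))
  if (!is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  span <- traj$time_s[nrow(traj)] - traj$time_s[1]
  if (span < frame_interval) {
    stop("frame_interval is longer than the trajectory span")
  }
  grid <- traj$time_s[1] +
    seq(0, floor(span / frame_interval)) * frame_interval
  pos <- approx(traj$time_s, traj$position_um, xout = grid,
                method = "linear", ties = "ordered")$y
  sampled_track(grid, pos, frame_interval, provenance = "simulated")
}

#' Simulate a cohort of downsampled tracks
#'
#' Runs [simulate_trajectory()] + [downsample()] for `n_tracks` independent
#' tracks.  Per-track seeds are drawn once from the cohort seed, so both the
#' cohort and each individual track are reproducible.
#'
#' @inheritParams simulate_trajectory
#' @param n_tracks Number of tracks (default 21).
#' @param duration Track duration (s), default 3600.
#' @param frame_interval Frame interval (s), default 5.
#' @param seed Cohort seed.
#' @return A named list of [sampled_track()] objects, class `tow_cohort`,
#'   with attributes `params`, `seed`, `track_seeds`, `duration`,
#'   `frame_interval`.
#' @export
simulate_cohort <- function(params = default_tow_params(), n_tracks = 21,
                            duration = 3600, frame_interval = 5, seed = 1,
                            burn_in = 0) {
  stopifnot(n_tracks >= 1)
  set.seed(seed)
  track_seeds <- sample.int(.Machine$integer.max - 1L, n_tracks)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    traj <- simulate_trajectory(params, duration, seed = track_seeds[i],
                                burn_in = burn_in)
    downsample(traj, frame_interval)
  })
  names(tracks) <- sprintf("track%02d", seq_len(n_tracks))
  structure(tracks, params = params, seed = seed, track_seeds = track_seeds,
            duration = duration, frame_interval = frame_interval,
            class = "tow_cohort")
}

#' @export
print.tow_cohort <- function(x, ...) {
  cat(sprintf(
    "tug-of-war cohort: %d tracks, %g s each at dt = %g s (N = %d motors, seed %s)\n",
    length(x), attr(x, "duration"), attr(x, "frame_interval"),
    attr(x, "params")$n_motors, format(attr(x, "seed"))))
  invisible(x)
}
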