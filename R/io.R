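#' Read tracked trajectories from CSV
#'
#' Reads FIESTA-style tracker output: a long CSV with columns `track_id`,
#' `time_s`, `position_um` and one block of rows per particle (blocks may
#' appear in any order; tracks are keyed by `track_id`).  Rows must be
#' numeric and times strictly increasing within a track; offending rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param provenance Provenance tag stamped on the tracks (default
#'   `"experimental"`).
#' @return Named list of [sampled_track()]s (one per `track_id`).
#' @export
read_tracks <- function(path, provenance = "experimental") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "time_s", "position_um")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (nrow(df) == 0) stop("no track rows in ", path)
  tnum <- suppressWarnings(as.numeric(df$time_s))
  pnum <- suppressWarnings(as.numeric(df$position_um))
  bad <- which(!is.finite(tnum) | !is.finite(pnum))
  if (length(bad)) {
    stop("non-numeric track rows at line(s) ",
         paste(bad + 1, collapse = ", "))  # +1 for the header line
  }
  df$time_s <- tnum
  df$position_um <- pnum
  ids <- unique(df$track_id)
  tracks <- lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    if (any(diff(sub$time_s) <= 0)) {
      stop("non-increasing times within track ", id)
    }
    dt <- if (nrow(sub) >= 2) sub$time_s[2] - sub$time_s[1] else 1
    sampled_track(sub$time_s, sub$position_um, frame_interval = dt,
                  provenance = provenance)
  })
  stats::setNames(tracks, as.character(ids))
}

#' Write tracks to CSV
#'
#' Long format with columns `track_id`, `time_s`, `position_um`; the
#' write-read round trip preserves positions to well below 1e-9 um.
#'
#' @param tracks Named list of [sampled_track()]s (a [simulate_cohort()]
#'   result works directly).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(length(tracks) >= 1)
  ids <- names(tracks)
  if (is.null(ids)) ids <- sprintf("track%02d", seq_along(tracks))
  long <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    data.frame(track_id = ids[i],
               time_s = format(tracks[[i]]$time_s, digits = 15,
                               scientific = FALSE, trim = TRUE),
               position_um = format(tracks[[i]]$position_um, digits = 15,
                                    trim = TRUE))
  }))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a statistics or run table to CSV
#'
#' @param x A data frame ([cohort_stats()] output, [segment_runs()] output,
#'   a report table, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stats <- function(x, path) {
  stopifnot(is.data.frame(x))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Export run segmentations for a set of tracks
#'
#' One row per run across all tracks: `track_id`, `class`, `t_start`,
#' `duration_s`, `displacement_um`, `mean_v_nm_s`.
#'
#' @param tracks Named list of [sampled_track()]s.
#' @inheritParams track_stats
#' @return A `data.frame`.
#' @export
cohort_runs <- function(tracks, threshold = 1, min_intervals = 1) {
  ids <- names(tracks)
  if (is.null(ids)) ids <- sprintf("track%02d", seq_along(tracks))
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    runs <- segment_runs(point_displacements(tracks[[i]], threshold),
                         min_intervals)
    cbind(data.frame(track_id = ids[i]),
          runs[, c("class", "t_start", "duration_s", "displacement_um",
                   "mean_v_nm_s")])
  }))
}

# flat YAML keys <-> tow_params fields, one-to-one with the model constants
.team_keys <- c(stall_force_pN = "stall_force",
                detachment_force_pN = "detachment_force",
                binding_rate_per_s = "binding_rate",
                unbinding_rate_per_s = "unbinding_rate",
                forward_velocity_um_s = "forward_speed",
                backward_velocity_um_s = "backslip_speed")

#' Write a flat YAML run configuration
#'
#' Serializes a parameter set plus run settings as a flat key-value YAML file
#' (keys like `forward_stall_force_pN`, `n_motors`, `duration_s`, ...), the
#' package's single config dialect.
#'
#' @param params A [tow_params()].
#' @param path Output YAML path.
#' @param duration_s,frame_interval_s,n_tracks,seed Run settings stored
#'   alongside the model constants.
#' @return `path`, invisibly.
#' @export
write_tow_config <- function(params, path, duration_s = 3600,
                             frame_interval_s = 5, n_tracks = 21, seed = 1) {
  stopifnot(inherits(params, "tow_params"))
  flat <- list()
  for (side in c("forward", "backward")) {
    team <- params[[side]]
    for (k in names(.team_keys)) {
      flat[[paste0(side, "_", k)]] <- team[[.team_keys[[k]]]]
    }
  }
  flat$n_motors <- params$n_motors
  flat$duration_s <- duration_s
  flat$frame_interval_s <- frame_interval_s
  flat$n_tracks <- n_tracks
  flat$seed <- seed
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a flat YAML run configuration
#'
#' @param path YAML file written by [write_tow_config()] (or hand-edited with
#'   the same keys; missing run settings fall back to their defaults).
#' @return A list with `params` (a [tow_params()]), `duration_s`,
#'   `frame_interval_s`, `n_tracks`, `seed`.
#' @export
read_tow_config <- function(path) {
  flat <- yaml::read_yaml(path)
  team_from <- function(side) {
    vals <- lapply(names(.team_keys), function(k) {
      key <- paste0(side, "_", k)
      if (is.null(flat[[key]])) stop("config is missing key ", key)
      flat[[key]]
    })
    names(vals) <- unname(.team_keys)
    do.call(motor_team, vals)
  }
  if (is.null(flat$n_motors)) stop("config is missing key n_motors")
  list(params = tow_params(team_from("forward"), team_from("backward"),
                           n_motors = flat$n_motors),
       duration_s = flat$duration_s %||% 3600,
       frame_interval_s = flat$frame_interval_s %||% 5,
       n_tracks = flat$n_tracks %||% 21,
       seed = flat$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
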