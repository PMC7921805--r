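test_that("point-to-point displacements are exact and sign-symmetric", {
  trk <- sampled_track(c(0, 5, 10), c(0, 0.05, 0.05), 5)
  iv <- point_displacements(trk)
  expect_equal(iv$dx_um, c(0.05, 0))
  expect_equal(iv$v_nm_s, c(10, 0))
  expect_equal(as.character(iv$class), c("forward", "pause"))
  expect_equal(sum(iv$dx_um), 0.05)

  flat <- point_displacements(sampled_track(0:5, rep(1, 6), 1))
  expect_true(all(flat$v_nm_s == 0))
  expect_true(all(flat$class == "pause"))

  # reversing the positions negates every velocity
  set.seed(3)
  v <- rnorm(40, 2, 8)
  fwd <- point_displacements(track_from_velocities(v))
  rev <- point_displacements(track_from_velocities(-v))
  expect_equal(rev$v_nm_s, -fwd$v_nm_s)

  expect_error(point_displacements(data.frame(time_s = c(0, 5, 5),
                                              position_um = c(0, 1, 2))),
               "increasing")
  expect_error(point_displacements(sampled_track(0, 0, 1)), "2 frames")
})

test_that("speeds at the threshold classify as pauses", {
  iv <- point_displacements(track_from_velocities(c(1, -1, 1.0001, -1.0001)),
                            threshold = 1)
  expect_equal(as.character(iv$class),
               c("pause", "pause", "forward", "backward"))
})

test_that("run segmentation merges same-class intervals and tiles the track", {
  trk <- track_from_velocities(c(2, 3, -0.5, -2, -2), dt = 5)
  runs <- segment_runs(point_displacements(trk))
  expect_equal(as.character(runs$class), c("forward", "pause", "backward"))
  expect_equal(runs$duration_s, c(10, 5, 10))
  expect_equal(runs$n_intervals, c(2L, 1L, 2L))

  all_pause <- segment_runs(point_displacements(
    track_from_velocities(runif(10, -0.9, 0.9))))
  expect_equal(nrow(all_pause), 1)
  expect_equal(as.character(all_pause$class), "pause")

  # conservation on random tracks: durations and displacements re-sum exactly
  set.seed(14)
  for (i in 1:25) {
    v <- rnorm(sample(5:80, 1), sd = 6)
    trk <- track_from_velocities(v, dt = 2)
    runs <- segment_runs(point_displacements(trk))
    expect_equal(sum(runs$duration_s), trk$time_s[nrow(trk)])
    expect_equal(sum(runs$displacement_um),
                 trk$position_um[nrow(trk)] - trk$position_um[1])
    expect_true(all(head(as.character(runs$class), -1) !=
                      tail(as.character(runs$class), -1)))
  }
})

test_that("the strict run reading reclassifies single displacements", {
  v <- c(5, -4, -4, 0.2, 6, 6, 6)
  iv <- point_displacements(track_from_velocities(v))
  strict <- segment_runs(iv, min_intervals = 2)
  # the isolated forward interval joins the surrounding pauses/backward block
  expect_equal(as.character(strict$class), c("pause", "backward", "pause",
                                             "forward"))
  expect_equal(sum(strict$duration_s), 35)
})

test_that("raising the pause threshold never shrinks total pause time", {
  set.seed(8)
  for (i in 1:10) {
    trk <- track_from_velocities(rnorm(60, 1, 5))
    pause_time <- sapply(c(0.5, 1, 2, 4, 8), function(th) {
      runs <- segment_runs(point_displacements(trk, threshold = th))
      sum(runs$duration_s[runs$class == "pause"])
    })
    expect_true(all(diff(pause_time) >= 0))
  }
})

test_that("displacement weighting and Gaussian fits summarize velocities", {
  # hand-built intervals: weighted mean (10*1 + 20*3)/4 = 17.5
  iv <- data.frame(t_start = c(0, 5), t_end = c(5, 10), dt_s = 5,
                   dx_um = c(1, 3), v_nm_s = c(10, 20),
                   class = factor(c("forward", "forward"),
                                  levels = c("forward", "backward", "pause")))
  vd <- weighted_velocity_distribution(iv, "forward")
  expect_equal(vd$weighted_mean, 17.5)
  expect_equal(vd$total_weight, 4)

  # degenerate single-velocity data: no fit, moments still reported
  one <- iv
  one$v_nm_s <- c(10, 10)
  vd1 <- weighted_velocity_distribution(one, "forward")
  expect_false(vd1$fit_ok)
  expect_true(is.na(vd1$fit_mean))
  expect_equal(vd1$weighted_mean, 10)

  expect_error(weighted_velocity_distribution(iv, "backward"), "no backward")
})

test_that("Gaussian fit recovers generating parameters on synthetic data", {
  set.seed(33)
  n <- 1e4
  v <- rnorm(n, 11.55, 6.85)
  iv <- data.frame(t_start = seq_len(n) - 1, t_end = seq_len(n), dt_s = 1,
                   dx_um = rep(1, n), v_nm_s = v,
                   class = factor(rep("forward", n),
                                  levels = c("forward", "backward", "pause")))
  vd <- weighted_velocity_distribution(iv, "forward")
  expect_true(vd$fit_ok)
  expect_lt(abs(vd$fit_mean - 11.55), 0.5)
  expect_lt(abs(vd$fit_sd - 6.85), 0.5)

  # recovery stays within 0.1 sigma down to 1e3 intervals
  iv2 <- iv[1:1000, ]
  vd2 <- weighted_velocity_distribution(iv2, "forward")
  expect_lt(abs(vd2$fit_mean - mean(iv2$v_nm_s)), 0.1 * 6.85)
})

test_that("per-track statistics report absences and swap under time reversal", {
  fwd_only <- track_from_velocities(rep(c(10, 12), 10))
  st <- track_stats(fwd_only)
  expect_true(is.na(st$backward_v_nm_s))
  expect_true(is.na(st$backward_run_s))
  expect_equal(st$n_backward_runs, 0)
  expect_equal(st$net_v_nm_s, 11)

  set.seed(6)
  v <- rnorm(80, 1, 9)
  a <- track_stats(track_from_velocities(v))
  b <- track_stats(track_from_velocities(rev(-v)))
  expect_equal(a$forward_v_nm_s, b$backward_v_nm_s, tolerance = 1e-6)
  expect_equal(a$forward_run_s, b$backward_run_s, tolerance = 1e-9)
  expect_equal(a$net_v_nm_s, -b$net_v_nm_s, tolerance = 1e-9)
})

test_that("paired cohort comparison matches closed-form and permutation oracles", {
  # constructed cohort with a fixed 3 nm/s shift: closed-form paired t
  set.seed(12)
  bwd <- rnorm(21, 8, 1)
  d <- 3 + rnorm(21, 0, 1)
  stats <- data.frame(forward_v_nm_s = bwd + d, backward_v_nm_s = bwd,
                      forward_run_s = bwd + d, backward_run_s = bwd,
                      n_forward_runs = 1, n_backward_runs = 1)
  cmp <- cohort_compare(stats)
  t_stat <- mean(d) / (sd(d) / sqrt(21))
  p_manual <- 2 * pt(-abs(t_stat), df = 20)
  expect_equal(cmp$p_velocity, p_manual, tolerance = 1e-12)
  expect_lt(cmp$p_velocity, 0.001)

  # mirrored null cohort: no significance
  set.seed(13)
  null_stats <- data.frame(forward_v_nm_s = rnorm(21, 10, 2),
                           backward_v_nm_s = rnorm(21, 10, 2),
                           forward_run_s = rnorm(21, 30, 5),
                           backward_run_s = rnorm(21, 30, 5),
                           n_forward_runs = 1, n_backward_runs = 1)
  cmp0 <- cohort_compare(null_stats)
  expect_gt(cmp0$p_velocity, 0.05)

  # exact sign-flip permutation oracle on a small cohort
  set.seed(15)
  d6 <- c(2.1, -0.4, 1.7, 3.0, 0.9, 1.2)
  base <- rnorm(6, 10, 1)
  small <- data.frame(forward_v_nm_s = base + d6, backward_v_nm_s = base,
                      forward_run_s = base + d6, backward_run_s = base,
                      n_forward_runs = 1, n_backward_runs = 1)
  tval <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  flips <- expand.grid(rep(list(c(-1, 1)), 6))
  perm_t <- apply(flips, 1, function(s) tval(d6 * s))
  p_perm <- mean(abs(perm_t) >= abs(tval(d6)) - 1e-12)
  expect_lt(abs(cohort_compare(small)$p_velocity - p_perm), 0.1)

  # wilcoxon alternative runs and agrees on direction
  expect_lt(cohort_compare(stats, test = "wilcoxon")$p_velocity, 0.01)
  expect_error(cohort_compare(stats[1:2, ]), "at least 3")
})

test_that("simulator and synthetic tracks flow through one analysis path", {
  cohort <- simulate_cohort(default_params, n_tracks = 3, duration = 600,
                            frame_interval = 5, seed = 4)
  syn <- make_cohort(cohort_spec(n_tracks = 3, duration_s = 600), seed = 4)
  st_sim <- cohort_stats(cohort)
  st_syn <- cohort_stats(syn$tracks)
  expect_equal(names(st_sim), names(st_syn))
  expect_equal(nrow(st_sim), 3)
  expect_equal(nrow(st_syn), 3)
})
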