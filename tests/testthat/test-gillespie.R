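test_that("event rates split the total across the four channels", {
  p <- default_params
  r0 <- event_rates(0, 0, p)
  expect_equal(r0$bind_plus, 49)
  expect_equal(r0$bind_minus, 42)
  expect_equal(r0$unbind_plus, 0)
  expect_equal(r0$unbind_minus, 0)
  expect_equal(r0$total, 91)

  # saturated pool: no binding possible
  rfull <- event_rates(70, 0, p)
  expect_equal(rfull$bind_plus, 0)
  expect_equal(rfull$bind_minus, 0)

  # one unopposed bound motor carries no force: unloaded unbinding
  r1 <- event_rates(1, 0, p)
  expect_equal(r1$unbind_plus, 1.7)

  # both teams loaded: per-motor share F_c/n in the exponential
  m <- cargo_mechanics(5, 3, p)
  r <- event_rates(5, 3, p)
  expect_equal(r$unbind_plus, 5 * 1.7 * exp(m$force / 5 / 10))
  expect_equal(r$unbind_minus, 3 * 1.6 * exp(m$force / 3 / 10))
  expect_equal(r$total, r$bind_plus + r$bind_minus + r$unbind_plus +
                 r$unbind_minus)
})

test_that("a Gillespie step draws channels and waiting times correctly", {
  p <- default_params
  set.seed(11)
  n <- 2e4
  taus <- numeric(n)
  to_plus <- logical(n)
  for (i in seq_len(n)) {
    s <- ssa_step(0, 0, p)
    taus[i] <- s$tau
    to_plus[i] <- s$n_plus == 1
    expect_equal(s$n_plus + s$n_minus, 1)
  }
  # P(bind forward) = 49/91; tau ~ Exp(91): check within 3 standard errors
  p_hat <- mean(to_plus)
  expect_lt(abs(p_hat - 49 / 91), 3 * sqrt(49 / 91 * 42 / 91 / n))
  expect_lt(abs(mean(taus) - 1 / 91), 3 * (1 / 91) / sqrt(n))

  # single live channel: saturated pool can only unbind
  s <- ssa_step(70, 0, p)
  expect_equal(s$channel, "unbind_plus")
  expect_equal(s$n_plus, 69)
})

test_that("simulated trajectories are reproducible and conserve occupancy", {
  p <- default_params
  a <- simulate_trajectory(p, 120, seed = 5)
  b <- simulate_trajectory(p, 120, seed = 5)
  expect_identical(a$position_um, b$position_um)
  expect_identical(a$n_plus, b$n_plus)

  expect_true(all(diff(a$time_s) > 0))
  expect_true(all(a$n_plus >= 0 & a$n_minus >= 0))
  expect_true(all(a$n_plus + a$n_minus <= p$n_motors))
  expect_equal(a$time_s[1], 0)
  expect_equal(a$time_s[nrow(a)], 120)

  # position increments equal pre-event cargo velocity times waiting time,
  # cross-checking the compiled mechanics against the R reference
  v_pre <- cargo_velocity(head(a$n_plus, -1), head(a$n_minus, -1), p)
  expect_equal(diff(a$position_um), v_pre * diff(a$time_s), tolerance = 1e-9)
})

test_that("degenerate and one-team simulations behave as closed forms say", {
  p <- default_params
  z <- simulate_trajectory(p, 0, seed = 1)
  expect_equal(nrow(z), 1)
  expect_equal(z$time_s, 0)

  # forward team alone: motion alternates slope v_F (bound) and 0 (unbound)
  solo <- tow_params(default_params$forward,
                     motor_team(3, 10, 0, 1.6, 0.01, 0.001), n_motors = 1)
  tr <- simulate_trajectory(solo, 300, seed = 3)
  expect_true(all(tr$n_minus == 0))
  expect_true(all(diff(tr$position_um) >= 0))
  slopes <- diff(tr$position_um) / diff(tr$time_s)
  expect_true(all(abs(slopes) < 1e-9 | abs(slopes - 0.08) < 1e-9))

  expect_error(simulate_trajectory(p, -1), "duration")
})

test_that("burn-in discards the transient and re-zeroes the origin", {
  p <- default_params
  tr <- simulate_trajectory(p, 200, seed = 9, burn_in = 30)
  expect_equal(tr$time_s[1], 0)
  expect_equal(tr$position_um[1], 0)
  expect_equal(tr$time_s[nrow(tr)], 200)
  # state at the new origin is already relaxed, not the unbound start
  expect_gt(tr$n_plus[1] + tr$n_minus[1], 0)
})

test_that("downsampling interpolates linearly on the frame grid", {
  traj <- data.frame(time_s = c(0, 10), position_um = c(0, 0.8))
  trk <- downsample(traj, 5)
  expect_equal(trk$time_s, c(0, 5, 10))
  expect_equal(trk$position_um, c(0, 0.4, 0.8))

  # grid coinciding with uniform event epochs reproduces them exactly
  ev <- data.frame(time_s = seq(0, 50, 5), position_um = cumsum(runif(11)))
  expect_equal(downsample(ev, 5)$position_um, ev$position_um)

  # interpolated values lie inside the bracketing-epoch envelope
  set.seed(21)
  tr <- simulate_trajectory(default_params, 60, seed = 21)
  trk <- downsample(tr, 1.7)
  for (k in seq_len(nrow(trk))) {
    i <- findInterval(trk$time_s[k], tr$time_s)
    j <- min(i + 1, nrow(tr))
    expect_gte(trk$position_um[k] + 1e-12,
               min(tr$position_um[i], tr$position_um[j]))
    expect_lte(trk$position_um[k] - 1e-12,
               max(tr$position_um[i], tr$position_um[j]))
  }

  expect_error(downsample(data.frame(time_s = c(0, 3), position_um = c(0, 1)),
                          5), "span")
})

test_that("the SSA occupancy matches the explicit CTMC stationary law", {
  # reduced-size check; the deeper 1e6-event version runs with the
  # acceptance properties
  p <- tow_params(default_params$forward, default_params$backward,
                  n_motors = 2)
  st <- ctmc_stationary(p)
  traj <- simulate_trajectory(p, duration = 1e7, seed = 17,
                              max_events = 2e5)
  emp <- empirical_occupancy(traj, st$key)
  expect_lt(total_variation(emp, st$pi), 0.02)
})

test_that("cohorts derive per-track seeds reproducibly", {
  ch1 <- simulate_cohort(default_params, n_tracks = 3, duration = 60,
                         frame_interval = 5, seed = 2)
  ch2 <- simulate_cohort(default_params, n_tracks = 3, duration = 60,
                         frame_interval = 5, seed = 2)
  expect_identical(lapply(ch1, `[[`, "position_um"),
                   lapply(ch2, `[[`, "position_um"))
  expect_false(identical(ch1[[1]]$position_um, ch1[[2]]$position_um))
  expect_equal(length(ch1), 3)
})
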