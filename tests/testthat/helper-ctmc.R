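# independent CTMC oracle for the motor-binding chain: explicit generator
# matrix over the occupancy states {(n+, n-): n+ + n- <= N} and its
# stationary distribution, compared against sojourn-time occupancy of an
# SSA run.

ctmc_states <- function(n_motors) {
  grid <- expand.grid(n_plus = 0:n_motors, n_minus = 0:n_motors)
  grid[grid$n_plus + grid$n_minus <= n_motors, , drop = FALSE]
}

ctmc_generator <- function(params) {
  states <- ctmc_states(params$n_motors)
  k <- nrow(states)
  key <- paste(states$n_plus, states$n_minus)
  idx <- function(np, nm) match(paste(np, nm), key)
  Q <- matrix(0, k, k)
  for (i in seq_len(k)) {
    np <- states$n_plus[i]
    nm <- states$n_minus[i]
    r <- kchtow::event_rates(np, nm, params)
    if (np + nm < params$n_motors) {
      Q[i, idx(np + 1, nm)] <- r$bind_plus
      Q[i, idx(np, nm + 1)] <- r$bind_minus
    }
    if (np > 0) Q[i, idx(np - 1, nm)] <- r$unbind_plus
    if (nm > 0) Q[i, idx(np, nm - 1)] <- r$unbind_minus
    Q[i, i] <- -sum(Q[i, -i])
  }
  list(states = states, Q = Q, key = key)
}

ctmc_stationary <- function(params) {
  g <- ctmc_generator(params)
  k <- nrow(g$Q)
  A <- rbind(t(g$Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  list(states = g$states, pi = pmax(pi, 0) / sum(pmax(pi, 0)), key = g$key)
}

# sojourn-time-weighted empirical occupancy of a trajectory
empirical_occupancy <- function(traj, key) {
  dt <- diff(traj$time_s)
  lab <- paste(traj$n_plus, traj$n_minus)[-nrow(traj)]
  w <- tapply(dt, factor(lab, levels = key), sum, default = 0)
  as.numeric(w) / sum(dt)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
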