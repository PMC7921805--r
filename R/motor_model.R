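#' Single-motor parameter set for one motor team
#'
#' Bundles the load-response constants of one team of identical motors in the
#' tug-of-war: the linear force-velocity relation with stall force `F_s`, the
#' exponential load dependence of unbinding with detachment force `F_d`,
#' force-independent binding, and the slow backslip under superstall load.
#' Internal units are pN, um and s throughout; nm/s appears only in reported
#' statistics.
#'
#' @param stall_force Stall force `F_s` (pN): load at which the motor velocity
#'   reaches zero.
#' @param detachment_force Detachment force `F_d` (pN): force scale of the
#'   exponential load dependence of the unbinding rate.
#' @param binding_rate Binding rate `pi0` (1/s) of one unbound motor;
#'   independent of load.  May be 0 to disable a team entirely (a one-team
#'   control); all other parameters must be positive.
#' @param unbinding_rate Unloaded unbinding rate `eps0` (1/s).
#' @param forward_speed Unloaded speed `v_F` (um/s) toward the team's travel
#'   direction.
#' @param backslip_speed Superstall backslip speed `v_B` (um/s); must be
#'   smaller than `forward_speed`.
#'
#' @return An object of class `motor_team` (a validated named list).
#' @seealso [tow_params()], [motor_velocity()], [unbinding_rate()]
#' @export
#' @examples
#' motor_team(stall_force = 3, detachment_force = 10, binding_rate = 0.7,
#'            unbinding_rate = 1.7, forward_speed = 0.08,
#'            backslip_speed = 0.008)
motor_team <- function(stall_force, detachment_force, binding_rate,
                       unbinding_rate, forward_speed, backslip_speed) {
  vals <- c(stall_force = stall_force, detachment_force = detachment_force,
            binding_rate = binding_rate, unbinding_rate = unbinding_rate,
            forward_speed = forward_speed, backslip_speed = backslip_speed)
  if (!all(is.finite(vals)) || any(vals[-3] <= 0)) {
    stop("all motor_team parameters must be finite and > 0")
  }
  if (binding_rate < 0) stop("binding_rate must be >= 0")
  if (backslip_speed >= forward_speed) {
    stop("backslip_speed must be smaller than forward_speed")
  }
  structure(as.list(vals), class = "motor_team")
}

#' @export
print.motor_team <- function(x, ...) {
  cat(sprintf(
    "motor team: F_s = %g pN, F_d = %g pN, pi0 = %g /s, eps0 = %g /s, v_F = %g um/s, v_B = %g um/s\n",
    x$stall_force, x$detachment_force, x$binding_rate, x$unbinding_rate,
    x$forward_speed, x$backslip_speed))
  invisible(x)
}

#' Tug-of-war parameter set
#'
#' The two antagonistic motor teams plus a single shared pool of `n_motors`
#' motors.  Any unbound motor can bind to either microtubule orientation
#' class, so the binding propensity of each direction is proportional to the
#' whole free pool, not to a per-direction reservoir.
#'
#' @param forward [motor_team()] driving the cargo apexward (+x).
#' @param backward [motor_team()] driving the cargo toward the pollen grain
#'   (-x).
#' @param n_motors Total number of motors in the shared pool (>= 1).
#'
#' @return An object of class `tow_params`.
#' @seealso [default_tow_params()]
#' @export
tow_params <- function(forward, backward, n_motors = 70) {
  stopifnot(inherits(forward, "motor_team"), inherits(backward, "motor_team"))
  if (!is.finite(n_motors) || n_motors < 1 || n_motors != round(n_motors)) {
    stop("n_motors must be a positive integer")
  }
  structure(list(forward = forward, backward = backward,
                 n_motors = as.integer(n_motors)),
            class = "tow_params")
}

#' Default KCH tug-of-war parameters
#'
#' The standard parameter set for KCH-driven sperm cell transport: equal stall
#' (3 pN) and detachment (10 pN) forces for both teams, a slightly stickier
#' and faster forward team (pi0 = 0.7/s, eps0 = 1.7/s, v_F = 0.08 um/s,
#' v_B = 0.008 um/s) versus the backward team (0.6/s, 1.6/s, 0.01 um/s,
#' 0.001 um/s), and 70 motors in the shared pool.
#'
#' @param n_motors Total motor count; default 70.
#' @return A [tow_params()] object.
#' @export
#' @examples
#' p <- default_tow_params()
#' p$forward$binding_rate   # 0.7
default_tow_params <- function(n_motors = 70) {
  tow_params(
    forward = motor_team(stall_force = 3, detachment_force = 10,
                         binding_rate = 0.7, unbinding_rate = 1.7,
                         forward_speed = 0.08, backslip_speed = 0.008),
    backward = motor_team(stall_force = 3, detachment_force = 10,
                          binding_rate = 0.6, unbinding_rate = 1.6,
                          forward_speed = 0.01, backslip_speed = 0.001),
    n_motors = n_motors)
}

#' @export
print.tow_params <- function(x, ...) {
  cat(sprintf("tug-of-war parameters, shared pool of %d motors\nforward  ",
              x$n_motors))
  print(x$forward)
  cat("backward ")
  print(x$backward)
  invisible(x)
}

#' Load-dependent single-motor unbinding rate
#'
#' `eps(F) = eps0 * exp(|F| / F_d)`: detachment accelerates exponentially with
#' the magnitude of the load, on the scale of the detachment force.
#'
#' @param force Load on the motor (pN); the sign is ignored.  Vectorized.
#' @param team A [motor_team()].
#' @return Unbinding rate(s) in 1/s.
#' @export
#' @examples
#' fw <- default_tow_params()$forward
#' unbinding_rate(0, fw)    # 1.7
#' unbinding_rate(10, fw)   # 1.7 * e
unbinding_rate <- function(force, team) {
  stopifnot(inherits(team, "motor_team"), all(is.finite(force)))
  team$unbinding_rate * exp(abs(force) / team$detachment_force)
}

#' Single-motor binding rate
#'
#' Binding is force-independent: `pi(F) = pi0`.  The `force` argument is
#' accepted so the binding and unbinding rate functions share a signature.
#'
#' @param team A [motor_team()].
#' @param force Ignored load (pN); only its length is used for recycling.
#' @return Binding rate(s) in 1/s.
#' @export
binding_rate <- function(team, force = 0) {
  stopifnot(inherits(team, "motor_team"))
  rep_len(team$binding_rate, length(force))
}

#' Single-motor force-velocity relation
#'
#' Linear decrease from the unloaded speed to zero at the stall force, then a
#' slow backslip branch under superstall load:
#' `v(F) = v_F (1 - F/F_s)` for `F <= F_s` and `v(F) = v_B (1 - F/F_s)` for
#' `F >= F_s`.  Both branches vanish at `F = F_s`, so the relation is
#' continuous.  `F` is the magnitude of the load opposing the motor's travel
#' direction; the returned speed is in the motor's own frame (positive =
#' toward its travel direction, negative = backslip).
#'
#' @param force Opposing load (pN), `>= 0`.  Vectorized.
#' @param team A [motor_team()].
#' @return Velocity (um/s) in the motor frame.
#' @export
#' @examples
#' fw <- default_tow_params()$forward
#' motor_velocity(0, fw)   # 0.08
#' motor_velocity(3, fw)   # 0 (stall)
#' motor_velocity(6, fw)   # -0.008 (backslip)
motor_velocity <- function(force, team) {
  stopifnot(inherits(team, "motor_team"), all(is.finite(force)))
  if (any(force < 0)) {
    stop("motor_velocity takes the magnitude of the opposing load; force must be >= 0")
  }
  speed <- ifelse(force <= team$stall_force, team$forward_speed,
                  team$backslip_speed)
  speed * (1 - force / team$stall_force)
}

#' Cargo force and velocity for a given motor occupancy
#'
#' Resolves the tug-of-war between `n_plus` bound forward motors and
#' `n_minus` bound backward motors.  With both teams bound and unequal total
#' stall loads, force balance between the winning team (sub-stall, moving
#' forward in its own frame) and the losing team (superstall, backslipping)
#' gives, for forward dominance (`n+ Fs+ > n- Fs-`):
#'
#' \deqn{F_c = \lambda n_+ F_{s+} + (1-\lambda) n_- F_{s-}, \qquad
#'       \lambda = \frac{1}{1 + \frac{n_+ F_{s+} v_{B-}}{n_- F_{s-} v_{F+}}}}
#' \deqn{v_c = \frac{n_+ F_{s+} - n_- F_{s-}}
#'                  {n_+ F_{s+}/v_{F+} + n_- F_{s-}/v_{B-}}}
#'
#' and the mirrored expressions for backward dominance.  Both results satisfy
#' the consistency relation `v_c = v+(F_c/n+) = -v-(F_c/n-)` where `v+`/`v-`
#' are the single-motor force-velocity relations.  Degenerate occupancies
#' bypass the lambda machinery: one team alone moves unloaded at its own
#' `v_F` with `F_c = 0`; equal stall loads give a stalled pause
#' (`v_c = 0`, `F_c = n+ Fs+`); a fully unbound cargo does not move.
#'
#' @param n_plus,n_minus Bound motor counts (non-negative integers with
#'   `n_plus + n_minus <= n_motors`).
#' @param params A [tow_params()].
#' @return A list with `force` (total cargo force `F_c`, pN, magnitude),
#'   `velocity` (signed cargo velocity `v_c`, um/s, + = apexward) and
#'   `dominance` (one of `"forward"`, `"backward"`, `"balanced"`,
#'   `"unbound"`).
#' @export
#' @examples
#' p <- default_tow_params()
#' cargo_mechanics(2, 1, p)  # forward dominance: F_c = 5.5 pN, v_c = 1/150 um/s
cargo_mechanics <- function(n_plus, n_minus, params) {
  stopifnot(inherits(params, "tow_params"))
  if (n_plus < 0 || n_minus < 0 || n_plus + n_minus > params$n_motors) {
    stop("invalid motor occupancy")
  }
  fw <- params$forward
  bw <- params$backward
  load_plus <- n_plus * fw$stall_force
  load_minus <- n_minus * bw$stall_force
  if (n_plus == 0 && n_minus == 0) {
    return(list(force = 0, velocity = 0, dominance = "unbound"))
  }
  if (n_minus == 0) {
    return(list(force = 0, velocity = fw$forward_speed, dominance = "forward"))
  }
  if (n_plus == 0) {
    return(list(force = 0, velocity = -bw$forward_speed,
                dominance = "backward"))
  }
  if (load_plus == load_minus) {
    return(list(force = load_plus, velocity = 0, dominance = "balanced"))
  }
  if (load_plus > load_minus) {
    lambda <- 1 / (1 + (load_plus * bw$backslip_speed) /
                       (load_minus * fw$forward_speed))
    force <- lambda * load_plus + (1 - lambda) * load_minus
    velocity <- (load_plus - load_minus) /
      (load_plus / fw$forward_speed + load_minus / bw$backslip_speed)
    list(force = force, velocity = velocity, dominance = "forward")
  } else {
    lambda <- 1 / (1 + (load_plus * bw$forward_speed) /
                       (load_minus * fw$backslip_speed))
    force <- lambda * load_plus + (1 - lambda) * load_minus
    velocity <- (load_plus - load_minus) /
      (load_plus / fw$backslip_speed + load_minus / bw$forward_speed)
    list(force = force, velocity = velocity, dominance = "backward")
  }
}

#' Vectorized cargo velocity over occupancy states
#'
#' Convenience wrapper around [cargo_mechanics()] returning only the signed
#' cargo velocity, vectorized over `(n_plus, n_minus)` pairs.
#'
#' @inheritParams cargo_mechanics
#' @return Numeric vector of cargo velocities (um/s).
#' @export
cargo_velocity <- function(n_plus, n_minus, params) {
  mapply(function(np, nm) cargo_mechanics(np, nm, params)$velocity,
         n_plus, n_minus)
}
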