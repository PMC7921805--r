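# shared fixtures: parameter sets built in code, no files

default_params <- kchtow::default_tow_params()

# random positive parameter set for property tests; forces v_B < v_F
random_params <- function(n_motors = sample(2:40, 1)) {
  team <- function() {
    vf <- runif(1, 0.01, 0.2)
    kchtow::motor_team(stall_force = runif(1, 1, 8),
                       detachment_force = runif(1, 2, 20),
                       binding_rate = runif(1, 0.1, 2),
                       unbinding_rate = runif(1, 0.1, 3),
                       forward_speed = vf,
                       backslip_speed = vf * runif(1, 0.01, 0.9))
  }
  kchtow::tow_params(team(), team(), n_motors = n_motors)
}

# a sampled track straight from frame velocities (nm/s) at a uniform interval
track_from_velocities <- function(v_nm_s, dt = 5) {
  kchtow::sampled_track(seq(0, length(v_nm_s)) * dt,
                        cumsum(c(0, v_nm_s * dt / 1000)), dt,
                        provenance = "synthetic")
}
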