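# Shared fixtures, built in code at test time.

# A small, fast parameter set: 58 nm vesicle, short protocol.
small_params <- function(...) {
  do.call(star_params,
          modifyList(list(radius = 58, pH_out = 6.5, I_P = 117, P_H = 31e-5,
                          P_AHA2 = 8.5e-5, t_on = 20, t_off = 60,
                          t_final = 90, t_valinomycin = 0),
                     list(...)))
}

# Reference single-pump parameter set (trace 2: r = 145 nm).
trace2_params <- function(...) {
  do.call(star_params,
          modifyList(list(radius = 145, pH_out = 6.5, I_P = 448,
                          P_H = 3.9e-5, P_AHA2 = 65e-5, t_on = 180,
                          t_off = 506, t_final = 750),
                     list(...)))
}

# Noise-free ODE-generated trace at the camera cadence.
ode_trace <- function(p, cadence = 2) {
  traj <- simulate_ode(p, times = seq(0, p$t_final, by = cadence))
  star_trace(traj$times, trajectory_ph(traj), radius = p$radius,
             t_ATP = p$t_on, t_pump_stop = p$t_off, t_valinomycin = 0,
             pH_out = p$pH_out)
}

# A stub trajectory with prescribed proton counts, for observable tests.
stub_traj <- function(nh, dt = 0.1, radius = 58, nhb2 = NULL) {
  n <- length(nh)
  counts <- cbind(N_H = nh, N_K = 0, N_HB1 = 0,
                  N_HB2 = if (is.null(nhb2)) 0 else nhb2)
  structure(list(times = seq(0, by = dt, length.out = n), counts = counts,
                 active_pumps = rep(0, n), dpsi = rep(0, n), engine = "DS",
                 seed = 1L, params = list(sample_dt = dt),
                 volume = make_geometry(radius)$volume),
            class = "star_trajectory")
}
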