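test_that("a fully closed, reaction-free vesicle never changes state", {
  p <- star_params(radius = 58, P_H = 0, P_K = 0, I_P = 0, n_pumps = 0,
                   B1 = 0, phi = 1e-12, t_final = 5, sample_dt = 0.1)
  traj <- simulate_ds(p, seed = 1)
  expect_true(all(apply(traj$counts, 2, function(x) all(x == x[1]))))
})

test_that("identical seeds give bit-identical trajectories", {
  p <- small_params(pump_mode = "stochastic", n_pumps = 3, I_P = 117)
  a <- simulate_ds(p, seed = 99)
  b <- simulate_ds(p, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$active_pumps, b$active_pumps)
  c <- simulate_ds(p, seed = 100)
  expect_false(identical(a$counts, c$counts))
})

test_that("counts stay integral, non-negative and buffer-conserving", {
  p <- small_params()
  traj <- simulate_ds(p, seed = 2)
  bs <- starph:::build_system(p, "DS")
  expect_true(all(traj$counts >= 0))
  expect_true(all(traj$counts == round(traj$counts)))
  expect_true(all(traj$counts[, "N_HB1"] <= bs$sys$NT1))
  expect_true(all(traj$counts[, "N_HB2"] <= bs$sys$NT2))
})

test_that("a closed system conserves total protons exactly", {
  p <- star_params(radius = 58, P_H = 0, P_K = 0, I_P = 0, n_pumps = 0,
                   pH_out = 5.5, t_final = 30, sample_dt = 0.1)
  traj <- simulate_ds(p, seed = 3)
  tot <- rowSums(traj$counts[, c("N_H", "N_HB1", "N_HB2")])
  expect_true(all(tot == tot[1]))
})

test_that("sampled membrane potential equals the charge formula", {
  p <- small_params()
  traj <- simulate_ds(p, seed = 4)
  bs <- starph:::build_system(p, "DS")
  cn <- p$constants
  idx <- c(1, 100, 2000, length(traj$times))
  for (i in idx) {
    st <- lumen_state(traj$counts[i, "N_H"], traj$counts[i, "N_K"],
                      traj$counts[i, "N_HB1"], traj$counts[i, "N_HB2"])
    expect_equal(traj$dpsi[i],
                 membrane_potential(st, bs$geom, bs$donnan, cn),
                 tolerance = 1e-12)
  }
  expect_equal(traj$dpsi[1], 0)
})

test_that("equilibrium proton counts are Poisson", {
  p <- star_params(radius = 100, pH_out = 5.5, I_P = 0, n_pumps = 0,
                   P_H = 4.6e-5, t_final = 200)
  traj <- simulate_ds(p, seed = 5)
  ws <- window_stats(traj, window = c(40, 200))
  expect_equal(ws$mean_NH, expected_protons(5.5, traj$volume),
               tolerance = 0.05)
  expect_gt(ws$poisson_gof_p, 0.001)
  expect_equal(ws$fano, 1, tolerance = 0.1)
  expect_equal(ws$sigma_NH, sqrt(ws$mean_NH), tolerance = 0.1)
})

test_that("realized K+ statistics settle on the Nernst equilibrium", {
  # asymmetric K+ with the charge balance: the stationary potential must
  # satisfy [K]/[K]_o = exp(-dpsi F/RT), i.e. the in/out ratio law
  p <- star_params(radius = 58, pH_out = 6.5, K_in = 0.05, K_out = 0.1,
                   P_H = 0, I_P = 0, n_pumps = 0, t_final = 60,
                   sample_dt = 0.02)
  traj <- simulate_ds(p, seed = 6)
  cn <- p$constants
  vt <- cn$gas_constant * cn$temperature / cn$faraday
  sel <- traj$times >= 30
  NAV <- cn$avogadro * traj$volume
  nernst <- vt * log(p$K_out * NAV / mean(traj$counts[sel, "N_K"]))
  expect_equal(mean(traj$dpsi[sel]), nernst, tolerance = 0.02)
})

test_that("the continuum solution is constant at equilibrium and converged", {
  p <- star_params(radius = 100, pH_out = 6.0, I_P = 0, n_pumps = 0,
                   t_final = 100, sample_dt = 1)
  ode <- simulate_ode(p)
  ph <- trajectory_ph(ode)
  expect_lt(max(abs(ph - 6.0)), 1e-6)
  # halving tolerances barely moves the pumped solution
  p2 <- star_params(radius = 100, pH_out = 6.5, I_P = 300, P_H = 4.6e-5,
                    t_on = 10, t_off = 80, t_final = 100, sample_dt = 1)
  a <- trajectory_ph(simulate_ode(p2, rtol = 1e-8, atol = 1e-10))
  b <- trajectory_ph(simulate_ode(p2, rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("pump timelines honour their mode", {
  p0 <- star_params(n_pumps = 0)
  tl <- draw_pump_timeline(p0, seed = 1)
  expect_equal(active_count_steps(tl)$n_active, 0)

  pf <- star_params(n_pumps = 2, t_on = 180, t_off = 506)
  steps <- active_count_steps(draw_pump_timeline(pf))
  expect_equal(steps$time, c(0, 180, 506))
  expect_equal(steps$n_active, c(0, 2, 0))

  ps <- star_params(n_pumps = 400, pump_mode = "stochastic",
                    dwell_on = 50, dwell_off = 50, t_final = 750)
  tl <- draw_pump_timeline(ps, seed = 2)
  steps <- active_count_steps(tl)
  # equal dwells: long-run mean active fraction 1/2
  f <- function(s, tf) {
    dt <- diff(c(s$time, tf))
    sum(s$n_active * dt) / tf / 400
  }
  expect_equal(f(steps, 750), 0.5, tolerance = 0.05)
  # all-on start override
  pa <- star_params(n_pumps = 10, pump_mode = "stochastic",
                    start_active = TRUE)
  expect_equal(active_count_steps(draw_pump_timeline(pa, seed = 3))$n_active[1],
               10)
})

test_that("ensemble averaging behaves like a mean", {
  p <- small_params(t_final = 30)
  a <- simulate_ds(p, seed = 1)
  m1 <- ensemble_mean(list(a))
  expect_equal(m1$counts, a$counts)
  m3 <- ensemble_mean(list(a, a, a))
  expect_equal(m3$counts, a$counts)
  b <- simulate_ds(p, seed = 2)
  m <- ensemble_mean(list(a, b))
  expect_equal(m$counts[, "N_H"], (a$counts[, "N_H"] + b$counts[, "N_H"]) / 2)
  short <- simulate_ds(small_params(t_final = 20), seed = 1)
  expect_error(ensemble_mean(list(a, short)), "common sample grid")
})

test_that("averaging more stochastic runs approaches the continuum curve", {
  p <- small_params()
  ode <- simulate_ode(p)
  po <- ph_time_avg(ode)$pH
  runs <- lapply(1:24, function(s) simulate_ds(p, seed = s))
  rms <- function(n) {
    pm <- ph_time_avg(ensemble_mean(runs[seq_len(n)]))$pH
    ok <- is.finite(pm) & is.finite(po)
    sqrt(mean((pm[ok] - po[ok])^2))
  }
  expect_lt(rms(24), rms(4))
})

test_that("sensitivity coefficients carry the expected structure", {
  p <- star_params(radius = 145, pH_out = 6.5, I_P = 448, P_H = 3.9e-5)
  s <- local_sensitivity(p, "steady_state_pH",
                         param_names = c("I_P", "P_H", "area", "volume",
                                         "B1", "k_off"),
                         t_ss = 800)
  # more pumping -> more acidic
  expect_lt(s[["I_P"]], 0)
  # rescaling k_on and k_off together leaves the equilibrium constant and
  # hence the steady state untouched
  expect_lt(abs(s[["k_off"]]), 1e-3)
  # pump rate, proton permeability and surface area dominate the steady state
  expect_lt(abs(s[["volume"]]), abs(s[["I_P"]]))
  expect_lt(abs(s[["B1"]]), abs(s[["P_H"]]))
  expect_gt(abs(s[["area"]]), abs(s[["volume"]]))
  # buffering controls the acidification speed even where it leaves the
  # steady state unchanged
  sr <- local_sensitivity(p, "acidification_rate",
                          param_names = c("B1", "k_off"))
  expect_gt(abs(sr[["B1"]]), 1e-3)
})
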