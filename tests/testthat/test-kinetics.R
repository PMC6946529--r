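test_that("membrane potential is the net charge over the capacitance", {
  cn <- physical_constants()
  g <- make_geometry(100)
  # one excess elementary charge on a 100 nm vesicle
  one <- membrane_potential(lumen_state(N_H = 1), g, donnan = 0, cn)
  expect_equal(one * 1e3, 0.13, tolerance = 0.02)
  # linearity: 35 net charges read as 35 single-charge potentials
  st <- lumen_state(N_H = 5, N_K = 20, N_HB1 = 7, N_HB2 = 3)
  expect_equal(membrane_potential(st, g, 0, cn), 35 * one)
  # negating the net charge negates the potential: pick a Donnan load of
  # 70 charges so the same state carries -35
  B70 <- donnan_for_neutrality(lumen_state(N_H = 70), g, cn)
  expect_equal(membrane_potential(st, g, B70, cn), -35 * one)
})

test_that("voltage splitting preserves the equilibrium ratio law", {
  cn <- physical_constants()
  expect_equal(voltage_adjusted_rates(2.5e-16, 0, cn),
               list(k_in = 2.5e-16, k_out = 2.5e-16))
  # at dpsi = RT/F the out/in ratio is exactly e
  vt <- cn$gas_constant * cn$temperature / cn$faraday
  r <- voltage_adjusted_rates(1e-16, vt, cn)
  expect_equal(r$k_out / r$k_in, exp(1))
  for (dpsi in c(-0.08, -0.01, 0.013, 0.05)) {
    r <- voltage_adjusted_rates(3e-17, dpsi, cn)
    expect_equal(r$k_out / r$k_in, exp(dpsi / vt))
  }
})

test_that("net leak flux vanishes exactly at the Nernst potential", {
  cn <- physical_constants()
  vt <- cn$gas_constant * cn$temperature / cn$faraday
  c_out <- 0.1; c_in <- 0.02
  nernst <- vt * log(c_out / c_in)
  r <- voltage_adjusted_rates(1e-16, nernst, cn)
  expect_equal(r$k_in * c_out - r$k_out * c_in, 0)
})

test_that("the proton leak gains the pump term only after pump stop", {
  p <- star_params(radius = 75, P_H = 31e-5, P_AHA2 = 8.5e-5)
  a <- make_geometry(75)$area
  expect_equal(total_H_leak_rate(p, pump_stopped = FALSE),
               permeability_to_rate(31e-5, a))
  expect_equal(total_H_leak_rate(p, pump_stopped = TRUE),
               permeability_to_rate(31e-5 + 8.5e-5, a))
  p0 <- star_params(radius = 75, P_H = 31e-5, P_AHA2 = 0)
  expect_equal(total_H_leak_rate(p0, TRUE), total_H_leak_rate(p0, FALSE))
})

test_that("propensities respect detailed balance and the channel forms", {
  p <- star_params(radius = 145, pH_out = 6.5, I_P = 448)
  bs <- starph:::build_system(p, "ODE")
  st <- bs$state0
  a <- reaction_propensities(st, p, t = 0)
  expect_equal(attr(a, "dpsi"), 0)
  # equilibrium state at zero voltage: influx = efflux per ion
  expect_equal(a[["H_in"]], a[["H_out"]])
  expect_equal(a[["K_in"]], a[["K_out"]])
  # buffers at Henderson-Hasselbalch equilibrium: on-flux = off-flux
  expect_equal(a[["B1_protonate"]], a[["B1_deprotonate"]], tolerance = 1e-9)
  expect_equal(a[["B2_protonate"]], a[["B2_deprotonate"]], tolerance = 1e-9)
  # pump only while scheduled active
  expect_equal(a[["pump"]], 0)
  expect_equal(reaction_propensities(st, p, t = 200)[["pump"]], 448)
  expect_equal(reaction_propensities(st, p, t = 600)[["pump"]], 0)
  # first-order deprotonation: k_off * N_HB
  st2 <- st; st2[["N_HB1"]] <- 6.8e4
  expect_equal(reaction_propensities(st2, p)[["B1_deprotonate"]], 6.8e3)
  expect_error(reaction_propensities(lumen_state() - c(1, 0, 0, 0), p),
               "negative")
})

test_that("count-space and concentration-space buffer propensities agree", {
  p <- star_params(radius = 100)
  bs <- starph:::build_system(p, "ODE")
  st <- lumen_state(N_H = 7, N_K = 1000, N_HB1 = 5000, N_HB2 = 40)
  a <- reaction_propensities(st, p)
  NAV <- p$constants$avogadro * bs$geom$volume
  kon1 <- buffer_forward_rate(p$pKa1, p$k_off)
  conc_form <- p$constants$avogadro * bs$geom$volume * kon1 *
    ((bs$sys$NT1 - st[["N_HB1"]]) / NAV) * (st[["N_H"]] / NAV)
  expect_equal(a[["B1_protonate"]], conc_form)
})

test_that("propensity vector against stoichiometry reproduces the rate equations", {
  # term-by-term: S %*% a must equal the hand-written continuum RHS
  p <- star_params(radius = 120, pH_out = 6.0, I_P = 200, t_on = 0,
                   t_off = 750)
  bs <- starph:::build_system(p, "ODE")
  cn <- p$constants
  g <- bs$geom
  NAV <- cn$avogadro * g$volume
  st <- lumen_state(N_H = 4.7, N_K = 0.9 * NAV * 0.1, N_HB1 = 3e4,
                    N_HB2 = 100)
  a <- reaction_propensities(st, p, t = 10)
  rhs <- as.numeric(channel_stoichiometry() %*% a)

  dpsi <- membrane_potential(st, g, bs$donnan, cn)
  kH <- voltage_adjusted_rates(permeability_to_rate(p$P_H, g$area), dpsi, cn)
  kK <- voltage_adjusted_rates(permeability_to_rate(p$P_K, g$area), dpsi, cn)
  conc <- function(n) n / NAV
  kon1 <- buffer_forward_rate(p$pKa1, p$k_off)
  kon2 <- buffer_forward_rate(p$pKa2, p$k_off)
  jB1 <- NAV * (kon1 * conc(bs$sys$NT1 - st[["N_HB1"]]) * conc(st[["N_H"]]) -
                  p$k_off * conc(st[["N_HB1"]]))
  jB2 <- NAV * (kon2 * conc(bs$sys$NT2 - st[["N_HB2"]]) * conc(st[["N_H"]]) -
                  p$k_off * conc(st[["N_HB2"]]))
  dNH <- p$I_P + cn$avogadro * (kH$k_in * 10^(-p$pH_out) -
                                  kH$k_out * conc(st[["N_H"]])) - jB1 - jB2
  dNK <- cn$avogadro * (kK$k_in * p$K_out - kK$k_out * conc(st[["N_K"]]))
  expect_equal(rhs, c(dNH, dNK, jB1, jB2), tolerance = 1e-12)
})
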