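test_that("sphere geometry satisfies the analytic identities", {
  for (r in c(0.5, 20, 58, 150, 340, 1e4)) {
    g <- make_geometry(r)
    expect_equal(g$area, 4 * pi * r^2)
    expect_equal(g$volume, 4 / 3 * pi * r^3 * 1e-24)
  }
  expect_error(make_geometry(0), "positive")
  expect_error(make_geometry(-5), "positive")
})

test_that("geometry reproduces the reference volumes and ratios", {
  expect_equal(make_geometry(50)$volume * 1e12, 5e-7, tolerance = 0.05)
  expect_equal(make_geometry(58)$volume, 8.174e-19, tolerance = 1e-3)
  expect_equal(round(make_geometry(197)$volume / make_geometry(75)$volume),
               18)
})

test_that("detailed balance fixes the buffer forward rates", {
  # Table-style values for the bulk buffer and the dye
  expect_equal(buffer_forward_rate(6.1, 0.1), 1.3e5, tolerance = 0.05)
  expect_equal(buffer_forward_rate(5.72, 0.1), 5.2e4, tolerance = 0.01)
  expect_equal(buffer_forward_rate(0, 0.37), 0.37)
  # at pH = pKa with [B] = [HB+], forward and reverse fluxes balance
  pKa <- 6.1; k_off <- 0.1
  conc <- 10^-pKa
  expect_equal(buffer_forward_rate(pKa, k_off) * conc * 1, k_off * 1)
  expect_error(buffer_forward_rate(6.1, 0), "positive")
})

test_that("dye copy number follows the area density", {
  g58 <- make_geometry(58)
  dc <- dye_copy_number(g58, dye_layout())
  expect_equal(dc$expected, 90.6, tolerance = 1e-3)
  expect_equal(dc$count, 91)
  # vanishing density limits
  expect_equal(dye_copy_number(g58, dye_layout(area_per_lipid = 1e12))$count,
               0)
  big <- dye_copy_number(g58, dye_layout(mole_fraction = 1e-12))
  expect_equal(big$expected, 0, tolerance = 1e-6)
})

test_that("permeability-rate conversion is exact and invertible", {
  expect_equal(permeability_to_rate(1e17, 1), 1)
  a145 <- make_geometry(145)$area
  expect_equal(permeability_to_rate(3.9e-5, a145), 1.03e-16,
               tolerance = 2e-3)
  for (P in c(0, 1.1e-7, 4.6e-5, 0.3)) {
    k0 <- permeability_to_rate(P, a145)
    expect_identical(rate_to_permeability(k0, a145) * a145 / 1e17, k0)
    expect_equal(rate_to_permeability(k0, a145), P)
  }
})

test_that("Donnan choice closes the loop to zero membrane potential", {
  cn <- physical_constants()
  for (r in c(58, 100, 197)) {
    g <- make_geometry(r)
    st <- lumen_state(N_H = 3, N_K = 250, N_HB1 = 747, N_HB2 = 12)
    B <- donnan_for_neutrality(st, g, cn)
    expect_equal(membrane_potential(st, g, B, cn), 0)
  }
  g <- make_geometry(100)
  expect_equal(donnan_for_neutrality(lumen_state(), g, cn), 0)
  st <- lumen_state(N_H = 400, N_K = 600)
  expect_equal(donnan_for_neutrality(st, g, cn),
               1000 / (cn$avogadro * g$volume))
})

test_that("equilibrium initial state matches the bath", {
  g <- make_geometry(58)
  bufs <- list(buffer_species("B1", 6.1, total_copies = 1000),
               buffer_species("B2", 6.5, total_copies = 88))
  ini <- equilibrium_initial_state(6.5, bufs, g, K_in = 0.1)
  # ~0.156 expected free protons rounds to 0
  expect_equal(ini$real[["N_H"]], 0.156, tolerance = 0.01)
  expect_identical(ini$counts[["N_H"]], 0)
  # a buffer at its pKa is half protonated
  expect_equal(ini$real[["N_HB2"]], 44)
  # pH 5 in a 50 nm vesicle holds about 3 free protons
  ini5 <- equilibrium_initial_state(5, bufs, make_geometry(50), K_in = 0.1)
  expect_equal(ini5$real[["N_H"]], 3, tolerance = 0.06)
})

test_that("parameter documents survive a JSON round trip", {
  p <- star_params(radius = 145, I_P = 448, P_H = 3.9e-5, P_AHA2 = 65e-5,
                   pump_mode = "stochastic", dwell_on = 273, dwell_off = 150,
                   K_in = 0.05)
  path <- tempfile(fileext = ".json")
  write_params(p, path, seed = 42L)
  back <- read_params(path)
  expect_equal(back$seed, 42L)
  for (f in c("radius", "pH_out", "K_out", "K_in", "B1", "pKa1", "pKa2",
              "k_off", "P_H", "P_AHA2", "P_K", "I_P", "n_pumps",
              "pump_mode", "t_on", "t_off", "dwell_on", "dwell_off",
              "t_valinomycin", "t_final", "sample_dt"))
    expect_equal(back$params[[f]], p[[f]], info = f)
  writeLines('{"radius_nm": 100, "bogus_key": 1}', path)
  expect_error(read_params(path), "unknown parameter keys")
})

test_that("parameter validation rejects unphysical input", {
  expect_error(star_params(radius = -1), "radius")
  expect_error(star_params(P_H = -1e-5), "permeabilit")
  expect_error(star_params(I_P = -3), "pump rate")
  expect_error(star_params(pump_mode = "stochastic", dwell_on = 0), "dwell")
  expect_error(star_params(t_valinomycin = 900), "t_valinomycin")
  expect_error(star_params(sample_dt = 0), "sample_dt")
})
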