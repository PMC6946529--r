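test_that("instantaneous pH reproduces the small-count landmarks", {
  v58 <- make_geometry(58)$volume
  expect_equal(round(ph_instant(1, v58), 1), 5.7)
  expect_equal(round(ph_instant(2, v58), 1), 5.4)
  expect_identical(ph_instant(0, v58), Inf)
  expect_error(ph_instant(-1, v58), ">= 0")
})

test_that("expected_protons inverts ph_instant and hits the landmarks", {
  expect_equal(expected_protons(5.5, make_geometry(20)$volume), 0.06,
               tolerance = 0.07)
  expect_equal(expected_protons(5.0, make_geometry(50)$volume), 3,
               tolerance = 0.06)
  v <- make_geometry(145)$volume
  for (n in c(1, 7, 350.25))
    expect_equal(expected_protons(ph_instant(n, v), v), n)
  for (ph in c(4.2, 5.5, 7.9))
    expect_equal(ph_instant(expected_protons(ph, v), v), ph)
})

test_that("time-averaged pH is the pH of the window-mean count", {
  v <- make_geometry(58)$volume
  tr <- stub_traj(rep(3, 40))
  expect_true(all(ph_time_avg(tr, 0.5)$pH == ph_instant(3, v)))
  # equal occupancy of 0 and 1 protons reads as half a proton
  tr01 <- stub_traj(rep(c(0, 1), 20))
  expect_equal(unique(ph_time_avg(tr01, 1)$pH), ph_instant(0.5, v))
  # an all-zero window keeps the infinite sentinel
  trz <- stub_traj(rep(0, 10))
  expect_identical(unique(ph_time_avg(trz, 0.5)$pH), Inf)
  expect_error(ph_time_avg(stub_traj(1:5, dt = 1), 0.5), "window")
})

test_that("Henderson-Hasselbalch protonation behaves", {
  expect_equal(hh_protonated(6.1, 6.1, 500), 250)
  expect_equal(hh_protonated(-50, 6.1, 500), 500)
  expect_equal(hh_protonated(50, 6.1, 500), 0)
  # a 58 nm vesicle's dye pool at bath pH 6.5: ~12 protonated of 88
  expect_equal(hh_protonated(6.5, 5.72, 88), 12.5, tolerance = 0.01)
  # strictly decreasing
  ph <- seq(3, 9, by = 0.25)
  expect_true(all(diff(hh_protonated(ph, 5.72, 91)) < 0))
})

test_that("two-point dye calibration solves the linear model", {
  # anchors engineered to give N_HB2 = 10 and 50 out of N_T = 100
  nt <- 100; pka <- 6
  ph1 <- pka + log10((nt - 10) / 10)
  ph2 <- pka + log10((nt - 50) / 50)
  cal <- calibrate_dye(ph1, ph2, 110, 510, pKa2 = pka, N_T = nt)
  expect_equal(cal$c, 10)
  expect_equal(cal$b, 10)
  # photons proportional to the protonated count recover b = 0
  cal0 <- calibrate_dye(ph1, ph2, 70, 350, pKa2 = pka, N_T = nt)
  expect_equal(cal0$c, 7)
  expect_equal(cal0$b, 0)
  expect_error(calibrate_dye(6.5, 6.5, 100, 100, N_T = nt), "singular")
  expect_warning(dye_calibration(-2, 5), "non-physical")
})

test_that("photon emission is Poisson about the linear mean", {
  tr <- stub_traj(rep(0, 20001), dt = 0.02, nhb2 = rep(30, 20001))
  cal <- dye_calibration(c = 12, b = 40)
  ph <- emit_photons(tr, cal, seed = 1)
  expect_true(all(ph$counts == round(ph$counts)) && all(ph$counts >= 0))
  expect_equal(mean(ph$counts), 12 * 30 + 40, tolerance = 0.02)
  expect_equal(fano_factor(ph$counts), 1, tolerance = 0.15)
  # with c = 0 the counts are pure background
  cal0 <- suppressWarnings(dye_calibration(c = 0, b = 40))
  ph0 <- emit_photons(tr, cal0, seed = 2)
  expect_equal(mean(ph0$counts), 40, tolerance = 0.05)
})

test_that("photon-derived pH inverts the forward model exactly when noiseless", {
  nt <- 91; pka <- 5.72
  cal <- dye_calibration(c = 40, b = 100)
  for (nhb2 in c(5, 45.5, 80)) {
    est <- ph_from_photons(cal$c * nhb2 + cal$b, cal, pKa2 = pka, N_T = nt)
    expect_equal(est$pH_hnu, pka + log10((nt - nhb2) / nhb2))
    expect_false(est$clipped_flag)
  }
  half <- ph_from_photons(cal$c * nt / 2 + cal$b, cal, pKa2 = pka, N_T = nt)
  expect_equal(half$pH_hnu, pka)
  # background-only frame clips at the lower bound and is flagged
  lo <- ph_from_photons(cal$b, cal, pKa2 = pka, N_T = nt)
  expect_true(lo$clipped_flag)
  expect_equal(lo$pH_hnu, pka + log10((nt - 0.5) / 0.5))
})

test_that("the stationary dye pool agrees with equilibrium protonation", {
  p <- star_params(radius = 58, pH_out = 6.0, I_P = 0, n_pumps = 0,
                   P_H = 4.6e-5, t_final = 150)
  traj <- simulate_ds(p, seed = 7)
  bs <- starph:::build_system(p, "DS")
  sel <- traj$times >= 30
  expect_equal(mean(traj$counts[sel, "N_HB2"]),
               hh_protonated(6.0, p$pKa2, bs$sys$NT2),
               tolerance = 0.15)
})

test_that("the full photon loop returns the true mean pH", {
  p <- star_params(radius = 100, pH_out = 5.5, I_P = 0, n_pumps = 0,
                   t_final = 150)
  traj <- simulate_ds(p, seed = 8)
  cal <- dye_calibration(c = 40, b = 100)
  nt <- round(dye_copy_number(make_geometry(100))$expected)
  est <- ph_from_photons(emit_photons(traj, cal, seed = 9), cal,
                         pKa2 = 5.72, N_T = nt)
  sel <- est$frame_time_s >= 30 & !est$clipped_flag
  expect_equal(mean(est$pH_hnu[sel]), 5.5, tolerance = 0.01)
})
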