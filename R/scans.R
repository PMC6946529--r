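# Fluctuation scans over vesicle radius, bath pH, pumped steady states and
# pump copy number.  Each grid point is one DS run summarized by
# window_stats(); histograms of the windowed free proton count (or pH, for
# the multi-pump experiment) ride along for plotting.

scan_point <- function(params, seed, discard, thin = 1L) {
  traj <- simulate_ds(params, seed = seed)
  ws <- window_stats(traj, window = c(discard, params$t_final), thin = thin)
  sel <- traj$times >= discard
  list(stats = ws, histogram = table(traj$counts[sel, "N_H"]))
}

stats_row <- function(ws) {
  data.frame(mean_NH = ws$mean_NH, sigma_NH = ws$sigma_NH,
             mean_pH = ws$mean_pH, sigma_pH = ws$sigma_pH, fano = ws$fano,
             poisson_gof_p = ws$poisson_gof_p, n_samples = ws$n_samples,
             masked = ws$infinite_pH_mask_count)
}

#' Equilibrium fluctuation scan over vesicle radius
#'
#' For each radius, one stochastic run of a vesicle at equilibrium with the
#' bath (no pump, K+ clamp on from the start, lumen pH equal to bath pH);
#' after discarding an equilibration prefix, the free proton count and pH
#' fluctuation statistics are recorded.  Under Poisson statistics
#' `sigma(N_H)` grows as `r^(3/2)` and `sigma(pH)` falls as `r^(-3/2)`.
#'
#' @param r_grid radii in nm.
#' @param pH bath (and lumen) pH.
#' @param P_H passive proton permeability, cm/s.
#' @param t_run run length, s.
#' @param discard equilibration prefix discarded, s.
#' @param seed integer seed (point `i` uses `seed + i`).
#' @param base named list of extra [star_params()] overrides.
#' @return Object of class `scan_result`: data frame `summary` plus
#'   per-point count histograms.
#' @export
scan_radius <- function(r_grid = c(70, 120, 170, 220, 270), pH = 5.5,
                        P_H = 4.6e-5, t_run = 750, discard = 50, seed = 1,
                        base = list()) {
  rows <- vector("list", length(r_grid))
  hists <- vector("list", length(r_grid))
  for (i in seq_along(r_grid)) {
    p <- do.call(star_params,
                 modifyList(list(radius = r_grid[i], pH_out = pH, I_P = 0,
                                 n_pumps = 0, P_H = P_H, t_valinomycin = 0,
                                 t_final = t_run), base))
    pt <- scan_point(p, seed + i, discard)
    rows[[i]] <- cbind(data.frame(radius = r_grid[i], pH_set = pH),
                       stats_row(pt$stats))
    hists[[i]] <- pt$histogram
  }
  structure(list(summary = do.call(rbind, rows), histograms = hists,
                 swept = "radius"), class = "scan_result")
}

#' Equilibrium fluctuation scan over bath pH
#'
#' As [scan_radius()] but sweeping the bath (and lumen) pH at fixed radius.
#' Under Poisson statistics `sigma(N_H)` scales as `10^(-pH/2)` and
#' `sigma(pH)` as `10^(+pH/2)`.
#'
#' @param pH_grid bath pH values.
#' @param r radius, nm.
#' @inheritParams scan_radius
#' @return A `scan_result`.
#' @export
scan_ph <- function(pH_grid = seq(4.5, 6.3, length.out = 5), r = 150,
                    P_H = 4.6e-5, t_run = 750, discard = 50, seed = 1,
                    base = list()) {
  rows <- vector("list", length(pH_grid))
  hists <- vector("list", length(pH_grid))
  for (i in seq_along(pH_grid)) {
    p <- do.call(star_params,
                 modifyList(list(radius = r, pH_out = pH_grid[i], I_P = 0,
                                 n_pumps = 0, P_H = P_H, t_valinomycin = 0,
                                 t_final = t_run), base))
    pt <- scan_point(p, seed + i, discard)
    rows[[i]] <- cbind(data.frame(radius = r, pH_set = pH_grid[i]),
                       stats_row(pt$stats))
    hists[[i]] <- pt$histogram
  }
  structure(list(summary = do.call(rbind, rows), histograms = hists,
                 swept = "pH"), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result over %s (%d points)\n", x$swept,
              nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Fitted noise scaling exponents of a scan
#'
#' Log-log (radius sweep) or semi-log (pH sweep) regression slopes of
#' `sigma(N_H)` and `sigma(pH)` against the swept variable.
#'
#' @param scan a `scan_result` from [scan_radius()] or [scan_ph()].
#' @return Named vector `c(sigma_NH, sigma_pH)` of slopes: per decade of
#'   radius for a radius sweep, per pH unit for a pH sweep.
#' @export
scan_exponents <- function(scan) {
  s <- scan$summary
  x <- if (scan$swept == "radius") log10(s$radius) else s$pH_set
  c(sigma_NH = unname(coef(lm(log10(s$sigma_NH) ~ x))[2]),
    sigma_pH = unname(coef(lm(log10(s$sigma_pH) ~ x))[2]))
}

#' Fluctuations at pumped steady states
#'
#' For each (radius, target pH) pair, the pump rate that holds the given
#' steady-state lumenal pH is solved by bisection on the continuum model,
#' then one stochastic run with the pump permanently on is summarized over
#' its final half.  Points whose target pH cannot be reached within the
#' rate bracket are flagged.
#'
#' @param r_grid radii, nm.
#' @param target_pH_grid steady-state lumenal pH targets.
#' @param pH_out bath pH.
#' @param P_H passive proton permeability, cm/s.
#' @param t_run DS run length, s.
#' @param seed integer seed.
#' @param base extra [star_params()] overrides.
#' @return A `scan_result`; the summary gains columns `I_P` (solved rate)
#'   and `flagged`.
#' @export
scan_pumped_steady_state <- function(r_grid = 150, target_pH_grid = 5.5,
                                     pH_out = 6.5, P_H = 4.6e-5,
                                     t_run = 750, seed = 1, base = list()) {
  grid <- expand.grid(radius = r_grid, target_pH = target_pH_grid)
  rows <- vector("list", nrow(grid))
  hists <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p0 <- do.call(star_params,
                  modifyList(list(radius = grid$radius[i], pH_out = pH_out,
                                  n_pumps = 1, P_H = P_H,
                                  t_on = 0, t_off = t_run, t_final = t_run,
                                  t_valinomycin = 0), base))
    ip <- solve_pump_rate(p0, grid$target_pH[i])
    flagged <- is.na(ip)
    if (flagged) {
      rows[[i]] <- cbind(data.frame(radius = grid$radius[i],
                                    target_pH = grid$target_pH[i],
                                    I_P = NA_real_, flagged = TRUE),
                         stats_row(list(mean_NH = NA, sigma_NH = NA,
                                        mean_pH = NA, sigma_pH = NA,
                                        fano = NA, poisson_gof_p = NA,
                                        n_samples = 0,
                                        infinite_pH_mask_count = 0)))
      next
    }
    p0$I_P <- ip
    pt <- scan_point(p0, seed + i, discard = t_run / 2)
    rows[[i]] <- cbind(data.frame(radius = grid$radius[i],
                                  target_pH = grid$target_pH[i],
                                  I_P = ip, flagged = FALSE),
                       stats_row(pt$stats))
    hists[[i]] <- pt$histogram
  }
  structure(list(summary = do.call(rbind, rows), histograms = hists,
                 swept = "pumped"), class = "scan_result")
}

#' Multi-pump acidification of a lysosome-sized vesicle
#'
#' Stochastic runs of a large vesicle carrying many proton pumps that cycle
#' independently between active and inactive states with exponential dwell
#' times.  For each pump count the steady-state distribution of the
#' instantaneous pH is summarized by its mean, standard deviation and total
#' spread (both max - min and the 2.5-97.5 percentile range, the latter
#' robust to single excursions).  In ensemble mode the pump counts are the
#' stated Poisson percentiles of a mean pool size, and each histogram is
#' weighted by the probability mass of its count.
#'
#' @param pump_counts total pumps per vesicle.
#' @param r radius, nm.
#' @param I_P pump rate when active, H+/s.
#' @param dwell mean dwell time in each state, s.
#' @param P_H passive proton permeability, cm/s.
#' @param pH0 bath and starting lumenal pH.
#' @param t_run run length, s.
#' @param discard_frac fraction of the run discarded before summarizing.
#' @param seed integer seed.
#' @param ensemble if `TRUE`, simulate the Poisson-percentile ensemble.
#' @param mean_pumps ensemble mean pump count.
#' @param percentiles ensemble percentiles (in percent).
#' @param base extra [star_params()] overrides.
#' @return A `scan_result`; in ensemble mode the summary gains the
#'   percentile and its Poisson probability weight.
#' @export
multipump_experiment <- function(pump_counts = c(20, 40, 80, 160, 320, 640),
                                 r = 340, I_P = 100, dwell = 273,
                                 P_H = 4.6e-5, pH0 = 6.0, t_run = 750,
                                 discard_frac = 0.5, seed = 1,
                                 ensemble = FALSE, mean_pumps = 640,
                                 percentiles = c(5, 25, 50, 75, 95),
                                 base = list()) {
  if (ensemble) {
    pump_counts <- qpois(percentiles / 100, mean_pumps)
    weights <- dpois(pump_counts, mean_pumps)
    weights <- weights / sum(weights)
  }
  rows <- vector("list", length(pump_counts))
  hists <- vector("list", length(pump_counts))
  for (i in seq_along(pump_counts)) {
    p <- do.call(star_params,
                 modifyList(list(radius = r, pH_out = pH0,
                                 I_P = I_P, n_pumps = pump_counts[i],
                                 pump_mode = "stochastic",
                                 dwell_on = dwell, dwell_off = dwell,
                                 P_H = P_H, t_valinomycin = 0,
                                 t_final = t_run, sample_dt = 0.05), base))
    traj <- simulate_ds(p, seed = seed + i)
    sel <- traj$times >= discard_frac * t_run
    ph <- ph_instant(traj$counts[sel, "N_H"], traj$volume)
    fin <- ph[is.finite(ph)]
    qs <- stats::quantile(fin, c(0.025, 0.975))
    rows[[i]] <- data.frame(
      n_pumps = pump_counts[i], mean_pH = mean(fin), sigma_pH = sd(fin),
      spread_total = max(fin) - min(fin),
      spread_p95 = unname(qs[2] - qs[1]),
      mean_active = mean(traj$active_pumps[sel]),
      masked = sum(!is.finite(ph)))
    hists[[i]] <- graphics::hist(fin, breaks = seq(floor(min(fin) * 20) / 20,
                                                   ceiling(max(fin) * 20) / 20,
                                                   by = 0.05), plot = FALSE)
  }
  out <- do.call(rbind, rows)
  if (ensemble) {
    out$percentile <- percentiles
    out$weight <- weights
  }
  structure(list(summary = out, histograms = hists, swept = "pumps"),
            class = "scan_result")
}
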