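#' Root-mean-square deviation between aligned series
#'
#' `sqrt(mean((model - exp)^2))` over the finite pairs; non-finite entries
#' (missing data, infinite-pH sentinels) are masked and their count
#' reported as attribute `"n_masked"`.
#'
#' @param model_series,exp_series aligned numeric series of equal length.
#' @return RMSD value with attribute `n_masked`.
#' @export
#' @examples
#' rmsd(c(0, 1, 2), c(1, 1, 1))  # sqrt(2/3)
rmsd <- function(model_series, exp_series) {
  if (length(model_series) != length(exp_series))
    stop("series lengths differ")
  ok <- is.finite(model_series) & is.finite(exp_series)
  if (!any(ok)) stop("no finite pairs to compare")
  structure(sqrt(mean((model_series[ok] - exp_series[ok])^2)),
            n_masked = sum(!ok))
}

#' Back-convert a pH trace to free proton counts
#'
#' `N(t) = N_A * V * 10^(-pH(t))`; the infinite-pH sentinel maps to 0.
#' Used by the proton-count fitting mode, where comparing counts avoids the
#' undefined pH of a protonless vesicle.
#'
#' @param trace a [star_trace()] object.
#' @param constants a [physical_constants()] object.
#' @return Numeric vector of real-valued counts.
#' @export
back_convert_to_counts <- function(trace,
                                   constants = physical_constants()) {
  vol <- make_geometry(trace$radius)$volume
  n <- expected_protons(trace$pH, vol, constants)
  n[is.infinite(trace$pH)] <- 0
  n
}

# Parameter set implied by a trace's segmentation plus free parameters.
fit_params <- function(trace, theta, base = list(), sample_dt = 0.02) {
  args <- list(radius = trace$radius,
               pH_out = trace$pH_out,
               I_P = theta[["I_P"]], P_H = theta[["P_H"]],
               P_AHA2 = theta[["P_AHA2"]],
               n_pumps = 1, pump_mode = "fixed",
               t_on = trace$t_ATP, t_off = trace$t_pump_stop,
               t_valinomycin = trace$t_valinomycin,
               t_final = max(trace$times), sample_dt = sample_dt)
  do.call(star_params, modifyList(args, base))
}

# Window-mean free proton count ending at each frame time (the quantity a
# 0.5-s camera integration reports).
windowed_counts <- function(traj, frame_times, window = 0.5) {
  dt <- traj$params$sample_dt
  k <- max(1L, round(window / dt))
  nh <- traj$counts[, "N_H"]
  vapply(frame_times, function(tf) {
    i1 <- which.min(abs(traj$times - tf))
    mean(nh[max(1L, i1 - k + 1L):i1])
  }, numeric(1))
}

#' Averaged stochastic objective
#'
#' The fitting objective at a point in parameter space.  In the ODE mode a
#' single deterministic RMSD; in the stochastic modes the mean RMSD over
#' `n_runs` independently seeded runs (any one run can match a trace poorly
#' even at the optimum, so a point in parameter space is scored by its
#' average).  Comparison variable by mode: pH for `ode` and `ds_photons`,
#' free proton count (experimental pH back-converted) for `ds_protons`.
#'
#' @param theta named vector `c(I_P, P_H, P_AHA2)`.
#' @param trace a [star_trace()] object.
#' @param mode `"ode"`, `"ds_protons"` or `"ds_photons"`.
#' @param n_runs stochastic runs averaged (ignored in ODE mode).
#' @param seed base seed; run `j` uses `seed + j`.
#' @param base named list of [star_params()] overrides.
#' @param cal [dye_calibration()] (required for `ds_photons`).
#' @return Objective value; for DS modes with attributes `sd` and `se`
#'   across runs.
#' @export
averaged_objective <- function(theta, trace,
                               mode = c("ode", "ds_protons", "ds_photons"),
                               n_runs = 10, seed = 1, base = list(),
                               cal = NULL) {
  mode <- match.arg(mode)
  if (mode == "ode") {
    p <- fit_params(trace, theta, base)
    traj <- simulate_ode(p, times = trace$times)
    return(as.numeric(rmsd(trajectory_ph(traj), trace$pH)))
  }
  p <- fit_params(trace, theta, base)
  vals <- vapply(seq_len(n_runs), function(j) {
    traj <- simulate_ds(p, seed = seed + j)
    if (mode == "ds_protons") {
      as.numeric(rmsd(windowed_counts(traj, trace$times),
                      back_convert_to_counts(trace)))
    } else {
      if (is.null(cal)) stop("ds_photons mode requires a dye calibration")
      nt <- round(dye_copy_number(make_geometry(trace$radius),
                                  dye_layout(p$A_L, p$phi, p$pKa2))$expected)
      ph <- emit_photons(traj, cal, frame_times = trace$times)
      est <- ph_from_photons(ph, cal, pKa2 = p$pKa2, N_T = nt)
      as.numeric(rmsd(est$pH_hnu, trace$pH))
    }
  }, numeric(1))
  structure(mean(vals), sd = sd(vals), se = sd(vals) / sqrt(n_runs))
}

#' Estimate pump rate and membrane permeabilities from a trace
#'
#' Nelder-Mead minimization of the (run-averaged, for stochastic modes)
#' RMSD objective over the three free parameters `(I_P, P_H, P_AHA2)`,
#' internally log-transformed to enforce positivity.  The pump rate applies
#' only on `[t_ATP, t_pump_stop)` and the pump-dependent leak only after
#' `t_pump_stop`; all other model parameters are held fixed, and the lumen
#' starts in equilibrium with the bath pH.  Stochastic objectives reuse the
#' same seed block at every iteration (common random numbers, which keeps
#' the simplex from chasing noise); the final objective is re-evaluated
#' with fresh seeds.
#'
#' @param trace a [star_trace()] object; its `pH_out` defaults to the
#'   median pre-ATP pH.
#' @param mode `"ode"`, `"ds_protons"` or `"ds_photons"`.
#' @param init named initial guess `c(I_P, P_H, P_AHA2)`.
#' @param n_runs runs averaged per objective evaluation (DS modes).
#' @param seed integer seed for the common-random-number block.
#' @param restarts simplex restarts from the perturbed optimum.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param base named list of [star_params()] overrides.
#' @param cal [dye_calibration()] for `ds_photons`.
#' @return Object of class `fit_result`: estimates, objective (with fresh
#'   -seed standard error in DS modes), convergence flag and iteration log.
#' @export
fit_trace <- function(trace, mode = c("ode", "ds_protons", "ds_photons"),
                      init = c(I_P = 100, P_H = 1e-5, P_AHA2 = 1e-4),
                      n_runs = 10, seed = 1, restarts = 2, maxit = 200,
                      base = list(), cal = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "star_trace"))
  if (!is.finite(trace$t_ATP) || !is.finite(trace$t_pump_stop) ||
      trace$t_ATP >= trace$t_pump_stop)
    stop("degenerate trace: no pumping section")
  init <- init[c("I_P", "P_H", "P_AHA2")]
  if (any(!is.finite(init) | init <= 0))
    stop("initial guess must be positive for all three parameters")

  log_env <- new.env()
  log_env$iters <- list()
  obj <- function(lth) {
    theta <- setNames(exp(lth), c("I_P", "P_H", "P_AHA2"))
    val <- as.numeric(averaged_objective(theta, trace, mode,
                                         n_runs = n_runs, seed = seed,
                                         base = base, cal = cal))
    log_env$iters[[length(log_env$iters) + 1L]] <- c(theta, err = val)
    if (!is.finite(val)) 1e10 else val
  }

  best <- optim(log(init), obj, method = "Nelder-Mead",
                control = list(maxit = maxit))
  set.seed(seed + 7919L)  # perturbation stream for restarts
  for (r in seq_len(restarts)) {
    start <- best$par + 0.2 * stats::rnorm(3)
    cand <- optim(start, obj, method = "Nelder-Mead",
                  control = list(maxit = maxit))
    if (cand$value < best$value) best <- cand
  }

  theta <- setNames(exp(best$par), c("I_P", "P_H", "P_AHA2"))
  final <- averaged_objective(theta, trace, mode, n_runs = n_runs,
                              seed = seed + 1000L, base = base, cal = cal)
  structure(list(I_P = theta[["I_P"]], P_H = theta[["P_H"]],
                 P_AHA2 = theta[["P_AHA2"]],
                 objective = as.numeric(final),
                 objective_se = attr(final, "se"),
                 mode = mode, n_runs = if (mode == "ode") 1L else n_runs,
                 seed = seed,
                 converged = best$convergence == 0,
                 n_evals = length(log_env$iters),
                 iterations = do.call(rbind, log_env$iters)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: I_P = %.4g H+/s, P_H = %.4g cm/s, P_AHA2 = %.4g cm/s\n",
              x$mode, x$I_P, x$P_H, x$P_AHA2))
  cat(sprintf("  objective = %.5g%s after %d evaluations%s\n", x$objective,
              if (!is.null(x$objective_se) && is.finite(x$objective_se %||% NA))
                sprintf(" (se %.2g)", x$objective_se) else "",
              x$n_evals,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flat-direction diagnostic for the post-stop leak
#'
#' The pump-dependent leak empties the vesicle so quickly after the pump
#' stops that its permeability is poorly constrained from above: increasing
#' it beyond a critical value barely changes the fit.  This diagnostic
#' reports the relative change in the objective when the fitted `P_AHA2`
#' is multiplied by a factor.
#'
#' @param fit a [fit_trace()] result.
#' @param trace the fitted trace.
#' @param factor multiplier on `P_AHA2`.
#' @param ... passed to [averaged_objective()].
#' @return Relative objective change `(err_scaled - err) / err`.
#' @export
paha2_flatness <- function(fit, trace, factor = 5, ...) {
  theta <- c(I_P = fit$I_P, P_H = fit$P_H, P_AHA2 = fit$P_AHA2)
  e0 <- as.numeric(averaged_objective(theta, trace, mode = fit$mode,
                                      seed = fit$seed, ...))
  theta["P_AHA2"] <- theta[["P_AHA2"]] * factor
  e1 <- as.numeric(averaged_objective(theta, trace, mode = fit$mode,
                                      seed = fit$seed, ...))
  (e1 - e0) / e0
}
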