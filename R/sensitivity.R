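# Steady-state helpers and local sensitivity analysis of the continuum
# model.

#' Continuum steady-state pH under constant pumping
#'
#' Integrates the continuum model with the pump permanently on until the
#' acidified quasi-steady state is reached and returns the final lumenal
#' pH.
#'
#' @param params a [star_params()] object (its pump schedule is overridden
#'   by pump-always-on).
#' @param I_P pump rate, H+/s; default taken from `params`.
#' @param t_ss integration horizon, s (several buffering-slowed leak time
#'   constants).
#' @return Steady-state pH.
#' @export
ode_steady_ph <- function(params, I_P = params$I_P, t_ss = 1500) {
  p <- params
  p$I_P <- I_P
  p$pump_mode <- "fixed"
  p$t_on <- 0
  p$t_off <- t_ss
  p$t_final <- t_ss
  traj <- simulate_ode(p, times = c(0, t_ss * 0.9, t_ss))
  tail(trajectory_ph(traj), 1)
}

#' Pump rate achieving a target steady-state pH
#'
#' Bisection on [ode_steady_ph()] over the pump rate.  Returns `NA` when
#' the target lies outside what the rate bracket can reach (for example a
#' target more alkaline than the bath).
#'
#' @param params a [star_params()] object.
#' @param target_pH desired steady-state lumenal pH.
#' @param bracket pump-rate search interval, H+/s.
#' @param tol bisection tolerance in pH units.
#' @param t_ss passed to [ode_steady_ph()].
#' @return Pump rate in H+/s, or `NA_real_` if the target is unreachable.
#' @export
solve_pump_rate <- function(params, target_pH, bracket = c(1e-3, 1e7),
                            tol = 2e-3, t_ss = 1500) {
  f <- function(ip) ode_steady_ph(params, I_P = ip, t_ss = t_ss) - target_pH
  flo <- f(bracket[1])
  fhi <- f(bracket[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
  lo <- bracket[1]; hi <- bracket[2]
  for (i in 1:60) {
    mid <- sqrt(lo * hi)   # bisection in log space: rates span decades
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm * flo <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  sqrt(lo * hi)
}

# Maximum acidification speed (-dpH/dt) after pump-on, from a dense
# continuum solution.
ode_acidification_rate <- function(params, I_P = params$I_P,
                                   horizon = 300) {
  p <- params
  p$I_P <- I_P
  p$pump_mode <- "fixed"
  p$t_on <- 0
  p$t_off <- horizon
  p$t_final <- horizon
  traj <- simulate_ode(p, times = seq(0, horizon, by = 1))
  ph <- trajectory_ph(traj)
  max(-diff(ph) / diff(traj$times))
}

.sens_apply <- function(params, name, factor) {
  p <- params
  geom <- make_geometry(p$radius, p$area, p$volume)
  switch(name,
         I_P = { p$I_P <- p$I_P * factor },
         P_H = { p$P_H <- p$P_H * factor },
         P_K = { p$P_K <- p$P_K * factor },
         area = { p$area <- geom$area * factor; p$volume <- geom$volume },
         volume = { p$volume <- geom$volume * factor; p$area <- geom$area },
         radius = { p$radius <- p$radius * factor },
         B1 = { p$B1 <- p$B1 * factor },
         k_off = { p$k_off <- p$k_off * factor },
         K_out = { p$K_out <- p$K_out * factor },
         capacitance = {
           p$constants$capacitance <- p$constants$capacitance * factor
         },
         stop("unknown sensitivity parameter: ", name))
  p
}

#' Local sensitivity of the continuum model
#'
#' Normalized logarithmic sensitivity coefficients
#' `d ln(output) / d ln(parameter)` by central finite differences with a
#' +/-1% perturbation.  Outputs: the pumped steady-state pH or the maximum
#' acidification rate.  `area` and `volume` are perturbed independently of
#' the radius (and of each other) to separate surface-coupled from
#' volume-coupled effects; perturbing `k_off` rescales both buffer rate
#' constants together (the equilibrium constant is held fixed), so its
#' steady-state coefficient vanishing is a consistency check.
#'
#' @param params a [star_params()] object with a non-zero `I_P`.
#' @param output `"steady_state_pH"` or `"acidification_rate"`.
#' @param param_names parameters to perturb.
#' @param rel relative perturbation.
#' @param t_ss steady-state horizon, s.
#' @return Named vector of sensitivity coefficients (`NaN` flags a
#'   non-finite perturbed output).
#' @export
local_sensitivity <- function(params,
                              output = c("steady_state_pH",
                                         "acidification_rate"),
                              param_names = c("I_P", "P_H", "P_K", "area",
                                              "volume", "B1", "k_off",
                                              "K_out", "capacitance"),
                              rel = 0.01, t_ss = 1500) {
  output <- match.arg(output)
  metric <- function(p) {
    if (output == "steady_state_pH") ode_steady_ph(p, t_ss = t_ss)
    else ode_acidification_rate(p)
  }
  vapply(param_names, function(nm) {
    up <- metric(.sens_apply(params, nm, 1 + rel))
    dn <- metric(.sens_apply(params, nm, 1 - rel))
    if (!is.finite(up) || !is.finite(dn) || up <= 0 || dn <= 0)
      return(NaN)
    (log(up) - log(dn)) / (log(1 + rel) - log(1 - rel))
  }, numeric(1))
}
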