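#' Voltage-adjusted leak rate constants
#'
#' A passive monovalent-cation leak with zero-voltage rate constant `k0`
#' splits the membrane-potential dependence equally between influx and
#' efflux:
#' `k_in = k0 * exp(-dpsi*F/(2RT))`, `k_out = k0 * exp(+dpsi*F/(2RT))`,
#' so that `k_out / k_in = exp(dpsi*F/(RT))` and the net flux vanishes at
#' the Nernst potential.
#'
#' @param k0 zero-voltage rate constant, L/s (>= 0).
#' @param dpsi membrane potential, volts.
#' @param constants a [physical_constants()] object.
#' @return List with `k_in` and `k_out` (L/s).
#' @export
voltage_adjusted_rates <- function(k0, dpsi,
                                   constants = physical_constants()) {
  if (any(k0 < 0)) stop("k0 must be >= 0")
  x <- dpsi * constants$faraday /
    (2 * constants$gas_constant * constants$temperature)
  list(k_in = k0 * exp(-x), k_out = k0 * exp(x))
}

.channel_names <- c("H_in", "H_out", "K_in", "K_out",
                    "B1_protonate", "B1_deprotonate",
                    "B2_protonate", "B2_deprotonate", "pump")

# Stoichiometry matrix: state change per firing, channels in columns.
# Rows: N_H, N_K, N_HB1, N_HB2.
.stoich <- matrix(c( 1, 0, 0, 0,
                    -1, 0, 0, 0,
                     0, 1, 0, 0,
                     0,-1, 0, 0,
                    -1, 0, 1, 0,
                     1, 0,-1, 0,
                    -1, 0, 0, 1,
                     1, 0, 0,-1,
                     1, 0, 0, 0),
                  nrow = 4, dimnames = list(names(lumen_state()),
                                            .channel_names))

#' Reaction channel stoichiometry
#'
#' The integer state change of `c(N_H, N_K, N_HB1, N_HB2)` caused by one
#' firing of each of the nine reaction channels.  Every firing moves exactly
#' one particle.
#'
#' @return A 4 x 9 integer matrix.
#' @export
channel_stoichiometry <- function() .stoich

#' Per-channel propensities of the reaction network
#'
#' Evaluates the nine channel rates (1/s) at a given state and time: the
#' voltage-split H+ and K+ leaks (the K+ leak is zero before valinomycin
#' addition, and the pump-dependent H+ leak is added once the fixed-schedule
#' pump has stopped), the count-space bimolecular buffer protonation
#' `k_on/(N_A V) * N_B * N_H`, first-order buffer deprotonation
#' `k_off * N_HB`, and the pump at `I_P` per active pump.  The membrane
#' potential is recomputed from the state.
#'
#' In the discrete engine these are jump propensities; summed against the
#' channel stoichiometry they are exactly the right-hand side of the
#' continuum rate equations.
#'
#' @param state a [lumen_state()] vector.
#' @param params a [star_params()] object.
#' @param t time, s (determines valinomycin, pump activity and pump-stop
#'   leak under the fixed schedule).
#' @param n_active number of active pumps; by default from the fixed
#'   schedule.
#' @return Named numeric vector of nine propensities, with the membrane
#'   potential attached as attribute `"dpsi"`.
#' @export
reaction_propensities <- function(state, params, t = 0, n_active = NULL) {
  if (any(state < 0)) stop("internal-consistency error: negative count")
  bs <- build_system(params, engine = "ODE")
  sys <- bs$sys
  if (any(state[c("N_HB1", "N_HB2")] > c(sys$NT1, sys$NT2) + 1e-9))
    stop("internal-consistency error: protonated buffer exceeds total")
  pump_on <- params$pump_mode == "fixed" &&
    t >= params$t_on && t < params$t_off
  if (is.null(n_active)) n_active <- if (pump_on) params$n_pumps else 0
  stopped <- params$pump_mode == "fixed" && t >= params$t_off
  kH0 <- bs$k_lipid0 + if (stopped) bs$k_AHA2_0 else 0
  kK0 <- if (t >= params$t_valinomycin) bs$k_K0 else 0

  dpsi <- sys$dpsi_q * (sum(state) - sys$q0)
  x <- dpsi * sys$beta
  ein <- exp(-x / 2)
  eout <- exp(x / 2)

  a <- c(kH0 * sys$Hin_pref * ein,
         kH0 * sys$invV * eout * state[["N_H"]],
         kK0 * sys$Kin_pref * ein,
         kK0 * sys$invV * eout * state[["N_K"]],
         sys$konf1 * (sys$NT1 - state[["N_HB1"]]) * state[["N_H"]],
         sys$koff1 * state[["N_HB1"]],
         sys$konf2 * (sys$NT2 - state[["N_HB2"]]) * state[["N_H"]],
         sys$koff2 * state[["N_HB2"]],
         params$I_P * n_active)
  names(a) <- .channel_names
  structure(a, dpsi = dpsi)
}
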