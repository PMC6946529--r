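#' Full model parameter set for a single-vesicle run
#'
#' Collects every tunable quantity of the acidification model: vesicle
#' geometry, bath composition, buffer and dye specifications, membrane
#' permeabilities, the pump specification (rate, copy number, fixed or
#' stochastic on/off schedule) and the run schedule.
#'
#' Units: lengths nm, concentrations mol/L, permeabilities cm/s, pump rate
#' H+/s per active pump, times s.  The potassium permeability is zero
#' before `t_valinomycin` and `P_K` afterwards.  In `"fixed"` pump mode all
#' pumps are active on `[t_on, t_off)` and the pump-dependent proton leak
#' `P_AHA2` switches on at `t_off`; in `"stochastic"` mode each pump cycles
#' independently between active and inactive states with exponential dwell
#' times, and `P_AHA2` is not applied.
#'
#' @param radius vesicle radius, nm.
#' @param pH_out bath pH.
#' @param K_out bath potassium, mol/L.
#' @param K_in initial lumenal potassium, mol/L (defaults to the bath value;
#'   it only matters once the K+ clamp is on).
#' @param B1 bulk buffer concentration, mol/L.
#' @param pKa1,pKa2 pKa of the bulk buffer and the dye.
#' @param k_off buffer dissociation rate, 1/s (shared by both buffers; the
#'   forward rates follow from detailed balance).
#' @param A_L area per lipid headgroup, nm^2.
#' @param phi dye-to-lipid mole fraction.
#' @param P_H,P_AHA2,P_K membrane permeabilities, cm/s.
#' @param I_P pumping rate per active pump, H+/s.
#' @param n_pumps number of pumps.
#' @param pump_mode `"fixed"` or `"stochastic"`.
#' @param t_on,t_off pump schedule in fixed mode, s.
#' @param dwell_on,dwell_off mean dwell times in stochastic mode, s.
#' @param start_active `NULL` for stationary random initial pump states
#'   (probability `dwell_on / (dwell_on + dwell_off)`), or `TRUE`/`FALSE`
#'   to start all pumps active/inactive.
#' @param t_valinomycin time at which the K+ permeability switches on, s.
#' @param t_final run length, s.
#' @param sample_dt trajectory sampling interval, s.
#' @param area,volume optional geometry overrides (nm^2, L); by default both
#'   follow from `radius` via the sphere formulas.
#' @param constants a [physical_constants()] object.
#' @return Object of class `star_params`.
#' @export
#' @examples
#' p <- star_params(radius = 145, I_P = 448, P_H = 3.9e-5, P_AHA2 = 65e-5)
#' p
star_params <- function(radius = 100, pH_out = 6.5, K_out = 0.1, K_in = K_out,
                        B1 = 0.01, pKa1 = 6.1, pKa2 = 5.72, k_off = 0.1,
                        A_L = 0.7, phi = 1.5 / 1000,
                        P_H = 4.6e-5, P_AHA2 = 0, P_K = 1.1e-7,
                        I_P = 0, n_pumps = 1,
                        pump_mode = c("fixed", "stochastic"),
                        t_on = 180, t_off = 506,
                        dwell_on = 273, dwell_off = 273, start_active = NULL,
                        t_valinomycin = 0, t_final = 750, sample_dt = 0.02,
                        area = NULL, volume = NULL,
                        constants = physical_constants()) {
  pump_mode <- match.arg(pump_mode)
  p <- list(radius = radius, pH_out = pH_out, K_out = K_out, K_in = K_in,
            B1 = B1, pKa1 = pKa1, pKa2 = pKa2, k_off = k_off,
            A_L = A_L, phi = phi, P_H = P_H, P_AHA2 = P_AHA2, P_K = P_K,
            I_P = I_P, n_pumps = n_pumps, pump_mode = pump_mode,
            t_on = t_on, t_off = t_off,
            dwell_on = dwell_on, dwell_off = dwell_off,
            start_active = start_active,
            t_valinomycin = t_valinomycin, t_final = t_final,
            sample_dt = sample_dt, area = area, volume = volume,
            constants = constants)
  validate_star_params(p)
  structure(p, class = "star_params")
}

validate_star_params <- function(p) {
  with(p, {
    if (radius <= 0) stop("radius must be positive")
    if (!is.finite(pH_out)) stop("pH_out must be finite")
    if (K_out < 0 || K_in < 0 || B1 < 0) stop("concentrations must be >= 0")
    if (P_H < 0 || P_AHA2 < 0 || P_K < 0)
      stop("permeabilities must be >= 0")
    if (I_P < 0) stop("pump rate must be >= 0")
    if (n_pumps < 0 || n_pumps != round(n_pumps))
      stop("n_pumps must be a non-negative integer")
    if (k_off <= 0) stop("k_off must be positive")
    if (pump_mode == "stochastic" && (dwell_on <= 0 || dwell_off <= 0))
      stop("dwell means must be positive in stochastic mode")
    if (t_valinomycin < 0 || t_valinomycin > t_final)
      stop("t_valinomycin must lie in [0, t_final]")
    if (sample_dt <= 0) stop("sample_dt must be positive")
    if (pump_mode == "fixed" && t_on > t_off)
      stop("t_on must not exceed t_off")
  })
  invisible(p)
}

#' @export
print.star_params <- function(x, ...) {
  cat(sprintf("star_params: r = %g nm, bath pH %g\n", x$radius, x$pH_out))
  cat(sprintf("  P_H = %.3g, P_AHA2 = %.3g, P_K = %.3g cm/s\n",
              x$P_H, x$P_AHA2, x$P_K))
  if (x$pump_mode == "fixed")
    cat(sprintf("  pump: %d x %g H+/s on [%g, %g) s\n",
                x$n_pumps, x$I_P, x$t_on, x$t_off))
  else
    cat(sprintf("  pump: %d x %g H+/s, stochastic dwell %g/%g s\n",
                x$n_pumps, x$I_P, x$dwell_on, x$dwell_off))
  cat(sprintf("  valinomycin at %g s, run %g s, sampled every %g s\n",
              x$t_valinomycin, x$t_final, x$sample_dt))
  invisible(x)
}

# Derive every engine-facing quantity from a parameter set: geometry, buffer
# copy numbers and rate constants, the equilibrium initial state, the Donnan
# reference charge (set so dpsi(0) = 0 for the engine's own rounding), and
# the scalar bundle the compiled kernels consume.
build_system <- function(p, engine = c("DS", "ODE")) {
  engine <- match.arg(engine)
  cn <- p$constants
  geom <- make_geometry(p$radius, area = p$area, volume = p$volume)
  NAV <- cn$avogadro * geom$volume

  NT1 <- NAV * p$B1
  NT2 <- dye_copy_number(geom, dye_layout(p$A_L, p$phi, p$pKa2))$expected
  if (engine == "DS") {
    NT1 <- round(NT1)
    NT2 <- round(NT2)
  }
  b1 <- buffer_species("B1", p$pKa1, p$k_off, NT1)
  b2 <- buffer_species("pHrodo", p$pKa2, p$k_off, NT2)

  ini <- equilibrium_initial_state(p$pH_out, list(b1, b2), geom, p$K_in, cn)
  state0 <- if (engine == "DS") ini$counts else ini$real
  donnan <- donnan_for_neutrality(state0, geom, cn)
  q0 <- cn$avogadro * geom$volume * donnan

  area_cm2 <- geom$area * 1e-14
  sys <- list(
    q0 = q0,
    dpsi_q = cn$faraday / (cn$avogadro * area_cm2 * cn$capacitance),
    beta = cn$faraday / (cn$gas_constant * cn$temperature),
    Hin_pref = cn$avogadro * 10^(-p$pH_out),
    Kin_pref = cn$avogadro * p$K_out,
    invV = 1 / geom$volume,
    konf1 = b1$k_on / NAV, koff1 = b1$k_off, NT1 = NT1,
    konf2 = b2$k_on / NAV, koff2 = b2$k_off, NT2 = NT2,
    IP = p$I_P)

  list(params = p, engine = engine, geom = geom, constants = cn,
       buffers = list(b1, b2), state0 = state0, donnan = donnan, sys = sys,
       k_lipid0 = permeability_to_rate(p$P_H, geom$area),
       k_AHA2_0 = permeability_to_rate(p$P_AHA2, geom$area),
       k_K0 = permeability_to_rate(p$P_K, geom$area))
}

#' Total passive proton leak rate constant
#'
#' The proton leak is the sum of a constant lipid-mediated term and a
#' pump-dependent term that is present only once the pump has permanently
#' stopped: `k_H0 = k_lipid0 + k_AHA2_0 * pump_stopped`, each term converted
#' from its permeability via [permeability_to_rate()].
#'
#' @param params a [star_params()] object.
#' @param pump_stopped has the pump permanently stopped?
#' @return `k_H0` in L/s.
#' @export
total_H_leak_rate <- function(params, pump_stopped = FALSE) {
  geom <- make_geometry(params$radius, params$area, params$volume)
  permeability_to_rate(params$P_H, geom$area) +
    if (pump_stopped) permeability_to_rate(params$P_AHA2, geom$area) else 0
}

# ---- JSON serialization ------------------------------------------------

.param_keys <- c("radius_nm", "pH_out", "P_H", "P_AHA2", "P_K", "K_out_mM",
                 "K_in_mM", "B1_mM", "pKa1", "pKa2", "k_off", "A_L", "phi",
                 "F", "R", "T", "C", "I_P", "n_pumps", "pump_mode",
                 "t_on_s", "t_off_s", "dwell_on_s", "dwell_off_s",
                 "t_valinomycin", "t_final", "sample_dt", "seed")

#' Read and write parameter documents
#'
#' Parameter sets serialize to a flat JSON document whose keys carry
#' explicit units (`radius_nm`, `K_out_mM`, ...).  Unknown keys are
#' rejected on read.
#'
#' @param params a [star_params()] object.
#' @param path file path.
#' @param seed optional integer seed stored alongside the parameters.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   list with elements `params` and `seed`.
#' @export
write_params <- function(params, path, seed = NULL) {
  doc <- params_to_doc(params)
  if (!is.null(seed)) doc$seed <- seed
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

params_to_doc <- function(p) {
  cn <- p$constants
  list(radius_nm = p$radius, pH_out = p$pH_out, P_H = p$P_H,
       P_AHA2 = p$P_AHA2, P_K = p$P_K,
       K_out_mM = p$K_out * 1e3, K_in_mM = p$K_in * 1e3, B1_mM = p$B1 * 1e3,
       pKa1 = p$pKa1, pKa2 = p$pKa2, k_off = p$k_off,
       A_L = p$A_L, phi = p$phi,
       F = cn$faraday, R = cn$gas_constant, T = cn$temperature,
       C = cn$capacitance,
       I_P = p$I_P, n_pumps = p$n_pumps, pump_mode = p$pump_mode,
       t_on_s = p$t_on, t_off_s = p$t_off,
       dwell_on_s = p$dwell_on, dwell_off_s = p$dwell_off,
       t_valinomycin = p$t_valinomycin, t_final = p$t_final,
       sample_dt = p$sample_dt)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(doc), .param_keys)
  if (length(unknown))
    stop("unknown parameter keys: ", paste(unknown, collapse = ", "))
  g <- function(key, default) if (key %in% names(doc)) doc[[key]] else default
  cn <- physical_constants(faraday = g("F", 96485),
                           gas_constant = g("R", 8.31),
                           temperature = g("T", 293),
                           capacitance = g("C", 1e-6))
  p <- star_params(radius = g("radius_nm", 100), pH_out = g("pH_out", 6.5),
                   K_out = g("K_out_mM", 100) / 1e3,
                   K_in = g("K_in_mM", g("K_out_mM", 100)) / 1e3,
                   B1 = g("B1_mM", 10) / 1e3,
                   pKa1 = g("pKa1", 6.1), pKa2 = g("pKa2", 5.72),
                   k_off = g("k_off", 0.1),
                   A_L = g("A_L", 0.7), phi = g("phi", 1.5e-3),
                   P_H = g("P_H", 4.6e-5), P_AHA2 = g("P_AHA2", 0),
                   P_K = g("P_K", 1.1e-7),
                   I_P = g("I_P", 0), n_pumps = g("n_pumps", 1),
                   pump_mode = g("pump_mode", "fixed"),
                   t_on = g("t_on_s", 180), t_off = g("t_off_s", 506),
                   dwell_on = g("dwell_on_s", 273),
                   dwell_off = g("dwell_off_s", 273),
                   t_valinomycin = g("t_valinomycin", 0),
                   t_final = g("t_final", 750),
                   sample_dt = g("sample_dt", 0.02),
                   constants = cn)
  list(params = p, seed = if ("seed" %in% names(doc)) doc$seed else NULL)
}
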