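#' Physical constants
#'
#' Bundle of the physical constants entering the model: Faraday's constant,
#' the gas constant, absolute temperature, specific membrane capacitance and
#' Avogadro's number.  Defaults are the values used for all single-vesicle
#' calculations in this package.
#'
#' @param faraday Faraday's constant, C/mol.
#' @param gas_constant gas constant, J/(K mol).
#' @param temperature absolute temperature, K.
#' @param capacitance specific membrane capacitance, F/cm^2.
#' @param avogadro Avogadro's number, 1/mol.
#' @return An object of class `star_constants`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function(faraday = 96485, gas_constant = 8.31,
                               temperature = 293, capacitance = 1e-6,
                               avogadro = 6.02214076e23) {
  vals <- c(faraday = faraday, gas_constant = gas_constant,
            temperature = temperature, capacitance = capacitance,
            avogadro = avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical constants must be finite and strictly positive")
  structure(as.list(vals), class = "star_constants")
}

#' Spherical vesicle geometry
#'
#' Radius with derived surface area and volume.  The vesicle is assumed
#' spherical; `area` and `volume` may be overridden individually, which is
#' used by the sensitivity analysis to perturb them independently.
#'
#' @param radius radius in nm (> 0).
#' @param area surface area in nm^2; default `4*pi*radius^2`.
#' @param volume volume in litres; default `(4/3)*pi*radius^3 * 1e-24`
#'   (1 nm^3 = 1e-24 L).
#' @return An object of class `vesicle_geometry` with fields `radius`
#'   (nm), `area` (nm^2) and `volume` (L).
#' @export
#' @examples
#' make_geometry(50)$volume * 1e12   # pL, approximately 5e-7
make_geometry <- function(radius, area = NULL, volume = NULL) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number (nm)")
  if (is.null(area)) area <- 4 * pi * radius^2
  if (is.null(volume)) volume <- 4 / 3 * pi * radius^3 * 1e-24
  if (area <= 0 || volume <= 0) stop("area and volume must be positive")
  structure(list(radius = radius, area = area, volume = volume),
            class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf("vesicle: r = %g nm, A = %.4g nm^2, V = %.4g L\n",
              x$radius, x$area, x$volume))
  invisible(x)
}

#' Buffer forward rate from detailed balance
#'
#' The protonation (on) rate of a buffer follows from its measured pKa and
#' dissociation (off) rate through detailed balance:
#' `k_on = 10^pKa * k_off`.
#'
#' @param pKa acid dissociation constant exponent (dimensionless).
#' @param k_off dissociation rate, 1/s (> 0).
#' @return `k_on` in L/(mol s).
#' @export
#' @examples
#' buffer_forward_rate(6.1, 0.1)    # ~1.3e5, bulk buffer
#' buffer_forward_rate(5.72, 0.1)   # ~5.2e4, lipid dye
buffer_forward_rate <- function(pKa, k_off) {
  if (!is.finite(pKa)) stop("pKa must be finite")
  if (k_off <= 0) stop("k_off must be positive")
  10^pKa * k_off
}

#' Lumenal buffer species
#'
#' @param name label.
#' @param pKa dissociation constant exponent.
#' @param k_off dissociation rate, 1/s.
#' @param total_copies total copy number N_T (protonated + free), >= 0.
#' @param protonated_charge integer charge of the protonated form.
#' @return Object of class `buffer_species`; `k_on` is derived via
#'   [buffer_forward_rate()].
#' @export
buffer_species <- function(name, pKa, k_off = 0.1, total_copies,
                           protonated_charge = 1L) {
  if (total_copies < 0) stop("total_copies must be >= 0")
  structure(list(name = name, pKa = pKa, k_off = k_off,
                 k_on = buffer_forward_rate(pKa, k_off),
                 total_copies = total_copies,
                 protonated_charge = as.integer(protonated_charge)),
            class = "buffer_species")
}

#' Lipid-conjugated dye layout
#'
#' Describes how the pH-sensitive dye is distributed in the membrane:
#' area per lipid headgroup, dye-to-lipid mole fraction, and dye pKa.
#'
#' @param area_per_lipid nm^2 per lipid headgroup.
#' @param mole_fraction dye-to-lipid mole fraction, in (0, 1).
#' @param pKa dye pKa (lipidated form).
#' @return Object of class `dye_layout`.
#' @export
dye_layout <- function(area_per_lipid = 0.7, mole_fraction = 1.5 / 1000,
                       pKa = 5.72) {
  if (area_per_lipid <= 0) stop("area_per_lipid must be positive")
  if (mole_fraction <= 0 || mole_fraction >= 1)
    stop("mole_fraction must be in (0, 1)")
  structure(list(area_per_lipid = area_per_lipid,
                 mole_fraction = mole_fraction, pKa = pKa),
            class = "dye_layout")
}

#' Dye copy number from vesicle geometry
#'
#' Average number of dye molecules in the leaflet, `(A / A_L) * phi` where
#' `A` is the vesicle surface area, `A_L` the area per lipid and `phi` the
#' dye mole fraction.  The discrete engine uses the value rounded to the
#' nearest integer; the unrounded expectation is also returned.
#'
#' @param geom a [make_geometry()] object.
#' @param layout a [dye_layout()] object.
#' @return List with `expected` (real) and `count` (nearest integer).
#' @export
#' @examples
#' dye_copy_number(make_geometry(58), dye_layout())  # ~91 copies
dye_copy_number <- function(geom, layout = dye_layout()) {
  stopifnot(inherits(geom, "vesicle_geometry"), inherits(layout, "dye_layout"))
  expected <- geom$area / layout$area_per_lipid * layout$mole_fraction
  list(expected = expected, count = round(expected))
}

#' Convert membrane permeability to a volume rate constant
#'
#' A permeability `P` (cm/s) over a membrane of area `A` (nm^2) corresponds
#' to the volume rate constant `k0 = P * A / 1e17` (L/s), and conversely.
#'
#' @param P permeability, cm/s (>= 0).
#' @param area membrane area, nm^2 (> 0).
#' @return `k0` in L/s.
#' @export
permeability_to_rate <- function(P, area) {
  if (any(P < 0)) stop("permeability must be >= 0")
  if (area <= 0) stop("area must be positive")
  P * area / 1e17
}

#' @rdname permeability_to_rate
#' @param k0 volume rate constant, L/s.
#' @export
rate_to_permeability <- function(k0, area) {
  if (any(k0 < 0)) stop("rate constant must be >= 0")
  if (area <= 0) stop("area must be positive")
  k0 * 1e17 / area
}

#' Lumen state constructor
#'
#' A lumen state is a named numeric vector of copy numbers
#' `c(N_H, N_K, N_HB1, N_HB2)`; real-valued in the continuum engine,
#' integer-valued in the discrete engine.
#'
#' @param N_H free protons.
#' @param N_K potassium ions.
#' @param N_HB1,N_HB2 protonated copies of buffer 1 (bulk) and 2 (dye).
#' @return Named numeric vector.
#' @export
lumen_state <- function(N_H = 0, N_K = 0, N_HB1 = 0, N_HB2 = 0) {
  s <- c(N_H = unname(N_H), N_K = unname(N_K), N_HB1 = unname(N_HB1),
         N_HB2 = unname(N_HB2))
  if (any(!is.finite(s)) || any(s < 0))
    stop("all copy numbers must be finite and >= 0")
  s
}

#' Donnan concentration for exact initial electroneutrality
#'
#' Chooses the concentration of impermeant, singly negative Donnan particles
#' such that the membrane potential is exactly zero at the supplied state.
#' This encodes the equilibrium-start assumption: before ATP addition the
#' lumen is in equilibrium with the bath and carries no net charge.
#'
#' @param state a [lumen_state()] vector.
#' @param geom a [make_geometry()] object.
#' @param constants a [physical_constants()] object.
#' @return Donnan particle concentration `B` in mol/L.
#' @export
donnan_for_neutrality <- function(state, geom,
                                  constants = physical_constants()) {
  q <- state[["N_H"]] + state[["N_HB1"]] + state[["N_HB2"]] + state[["N_K"]]
  B <- q / (constants$avogadro * geom$volume)
  if (B < 0) stop("invalid initial state: negative Donnan concentration")
  B
}

#' Membrane potential from net lumenal charge
#'
#' Net transferred charge divided by the membrane capacitance:
#' `dpsi = F / (N_A * A * C) * (N_H + N_HB1 + N_HB2 + N_K - N_A * V * B)`
#' with the area converted to cm^2.
#'
#' @param state a [lumen_state()] vector.
#' @param geom a [make_geometry()] object.
#' @param donnan Donnan particle concentration, mol/L.
#' @param constants a [physical_constants()] object.
#' @return Membrane potential in volts (lumen minus bath).
#' @export
membrane_potential <- function(state, geom, donnan = 0,
                               constants = physical_constants()) {
  q <- state[["N_H"]] + state[["N_HB1"]] + state[["N_HB2"]] + state[["N_K"]] -
    constants$avogadro * geom$volume * donnan
  area_cm2 <- geom$area * 1e-14
  constants$faraday / (constants$avogadro * area_cm2 * constants$capacitance) * q
}

#' Lumen state in equilibrium with the bath
#'
#' Free protons at the bath concentration, buffers protonated according to
#' Henderson-Hasselbalch at the bath pH, potassium at the chosen initial
#' lumenal concentration.  Expected copy numbers are returned unrounded
#' (continuum engine) and rounded to the nearest integer, ties to even
#' (discrete engine).
#'
#' @param pH_out bath pH.
#' @param buffers list of [buffer_species()] (protonated counts are filled
#'   for the first two).
#' @param geom a [make_geometry()] object.
#' @param K_in initial lumenal potassium, mol/L.
#' @param constants a [physical_constants()] object.
#' @return List with elements `real` and `counts`, both [lumen_state()]
#'   vectors.
#' @export
equilibrium_initial_state <- function(pH_out, buffers, geom, K_in = 0.1,
                                      constants = physical_constants()) {
  if (!is.finite(pH_out)) stop("bath pH must be finite")
  NAV <- constants$avogadro * geom$volume
  nh <- NAV * 10^(-pH_out)
  nhb <- vapply(buffers, function(b)
    hh_protonated(pH_out, b$pKa, b$total_copies), numeric(1))
  real <- lumen_state(nh, NAV * K_in, nhb[1], nhb[2])
  list(real = real, counts = round(real))
}
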