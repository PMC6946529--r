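---
title: "Discrete and continuum models of single-vesicle acidification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete and continuum models of single-vesicle acidification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starph)
```

## The problem

A proteoliposome of radius 50–200 nm reconstituted with a single proton
pump is about the smallest system in which active pH regulation can be
watched one transporter at a time.  At these volumes the continuum notion
of pH frays: a 58 nm vesicle at pH 5.7 holds exactly one free proton, and
a synaptic-vesicle-sized compartment at pH 5.5 holds 0.06 of one.  `starph`
models such vesicles two ways on the same reaction network — as a discrete
Markov jump process simulated exactly, and as the corresponding continuum
rate equations — together with the fluorescent-dye observable through which
such experiments actually see pH, the fitting machinery to estimate pump
and leak parameters from recorded traces, and the fluctuation analysis that
says what the noise in such recordings does and does not reveal.

## The reaction network

The lumen state is the copy-number vector (N~H~, N~K~, N~HB1~, N~HB2~):
free protons, potassium ions, and the protonated fractions of two buffers —
a bulk solution buffer B1 and the membrane-bound pH-sensitive dye B2.  Nine
reaction channels act on it:

* **Pump.** Each active pump injects protons at a constant rate I~P~
  (H⁺/s); a firing moves one proton.  The pump is voltage-independent
  (nothing in the underlying kinetics specifies a Δψ dependence) and its
  on/off activity is an external process, not a reaction channel: dwell
  times (~10²–10³ s) are orders of magnitude slower than the chemistry, so
  switching times are drawn up-front and applied as deterministic
  interrupts.
* **Passive H⁺ and K⁺ leaks.** A permeability P (cm/s) over membrane area
  A (nm²) gives the volume rate constant k⁰ = P·A/10¹⁷ (L/s).  Influx is
  N~A~·k·[X]~out~ and efflux k·N~X~/V.  The proton leak has two terms: a
  constant lipid-mediated permeability P~H~, plus a pump-mediated
  permeability P~AHA2~ that switches on once the pump has permanently
  stopped (the stalled transporter leaks).  The K⁺ leak is zero until
  valinomycin is added, after which P~K~ applies.
* **Buffer protonation.** Detailed balance ties each buffer's on-rate to
  its measured pK~a~: k~on~ = 10^pKa^·k~off~.  The bimolecular channel is
  evaluated in count space, (k~on~/(N~A~V))·N~B~·N~H~, which stays exact at
  single-digit copy numbers; the concentration form is algebraically
  identical and is what the continuum engine integrates.

**Membrane potential.** Δψ is not a state variable but an algebraic
function of the state: the net transferred charge (protons, protonated
buffers, potassium, minus a fixed concentration of impermeant −1 Donnan
particles) divided by the membrane capacitance.  Every leak rate splits its
voltage dependence symmetrically, k~in~ = k⁰e^−ΔψF/2RT^ and
k~out~ = k⁰e^+ΔψF/2RT^, so the ratio obeys the Nernst condition exactly.
The symmetric split is a modelling choice; only the ratio is constrained
by reversibility, and any asymmetry would be absorbed into fitted
permeabilities.

**Initialization.** Runs start in equilibrium with the bath: free protons
at the bath concentration, buffers at their Henderson–Hasselbalch
protonation, lumenal K⁺ at a configurable concentration defaulting to the
bath's 100 mM (the choice is inert until the K⁺ clamp opens).  The Donnan
concentration is then solved so that Δψ(0) = 0 exactly — Donnan particles
are a fixed continuous concentration, never discrete, because they do not
react.  Expected copy numbers are rounded to the nearest integer (ties to
even) for the discrete engine and used unrounded by the continuum engine;
each engine's Donnan reference is computed from its own initial state so
both start exactly electroneutral.

## Parameters that matter

| quantity | default | units | note |
|---|---|---|---|
| radius r | per run | nm | sphere assumed; area/volume can be overridden independently for sensitivity work |
| P~H~, P~AHA2~, P~K~ | 4.6×10⁻⁵, 0, 1.1×10⁻⁷ | cm/s | P~H~/P~AHA2~ are the usual fit targets |
| I~P~ | per run | H⁺/s per pump | third fit target |
| [K⁺]~out~, [B1] | 100, 10 | mM | bath composition |
| pK~a~¹, pK~a~² | 6.1, 5.72 | — | bulk buffer; lipid-conjugated dye |
| k~off~ | 0.1 | 1/s | shared buffer off-rate; the printed source value ("0.11 s") is unit-ambiguous, and 0.1 is the value consistent with the tabulated forward rates 1.3×10⁵ and 5.2×10⁴ L/(mol·s) |
| A~L~, φ | 0.7 nm², 1.5/1000 | — | dye surface density; N~T~ = (A/A~L~)·φ ≈ 91 for r = 58 nm |
| F, R, T, C | 96485, 8.31, 293, 10⁻⁶ | SI; C in F/cm² | |
| dwell~on~, dwell~off~ | 273, 273 | s | stochastic pump mode, exponential dwells |
| sample_dt | 0.02 | s | trajectory recording grid |

The dye copy number uses the nominal vesicle radius with no inner-leaflet
correction; a leaflet offset of a few nm would shave a few percent off N~T~
and is absorbed by the calibration constants in any case.

## The two engines

`simulate_ds()` is a direct-method stochastic simulation with a full
propensity refresh after every firing.  A dependency-graph method buys
nothing here: every charge-moving event changes Δψ and therefore all four
leak propensities.  The only caching is of the two voltage Boltzmann
factors, which live on an integer lattice of net charge and are memoized —
this is exact, not an approximation.  Pump switches, valinomycin and the
post-stop leak are deterministic interrupts; the exponential clock is
memoryless, so re-drawing the waiting time at each interrupt keeps the
sampled path statistically exact.  The state is recorded left-continuously
on the uniform grid.  One integer seed drives everything: the pump timeline
is drawn first from the seeded stream, the chemistry consumes the rest, so
a trajectory is reproduced bit-identically from (parameters, seed).  The
compiled loop sustains roughly 10⁷ events/s on one core, which is what
makes the run-averaged fitting objective practical.

`simulate_ode()` integrates the identical network as real-valued rate
equations with `deSolve::lsoda`, piecewise across schedule discontinuities,
at rtol 10⁻⁸ / atol 10⁻¹⁰ (halving the tolerances moves the solution by
under 10⁻⁶ pH units).  The continuum solution is, to excellent accuracy,
the pointwise mean of the jump process: averaging 100 seeded runs
reproduces it to a few hundredths of a pH unit everywhere.  That comparison
is made on the 0.5-s time-averaged pH.  On the raw 0.02-s grid the
comparison is not meaningful at small copy number: pre-acidification the
vesicle holds ~2.4 free protons, the mean of 100 Poisson draws still has a
~0.03 pH spread, and the maximum of 3.7×10⁴ effectively independent
deviations is ~4.7σ — an extreme-value artefact, not model disagreement.

At equilibrium the stationary proton count is Poisson (the network is at
detailed balance, so the stationary law is a product of a Poisson for free
protons and binomials for the buffer pools), and the engine's samples pass
chi-square goodness-of-fit tests across radii and pH.  The membrane
potential stays small throughout — the K⁺ clamp holds the continuum Δψ
within a few mV (≪ RT/F ≈ 25 mV) even during the pump-stop transient,
while instantaneous DS values fluctuate around that with ~1 mV standard
deviation.

## Three ways of reading out pH

1. **Instantaneous:** pH = −log₁₀(N~H~/(N~A~V)).  Zero protons is a typed
   `Inf` sentinel, masked (and counted) by every downstream statistic.
2. **Time-averaged:** mean count over contiguous 0.5-s windows, then the
   log — the averaging a camera frame performs.  It removes the discrete
   staircase; alkaline values become fractional proton counts.
3. **Dye/photon:** protonated dye count → expected photons c·N~HB2~ + b per
   frame (0.5 s integration reported every 2 s) → Poisson draw → inversion
   N̂~HB2~ = (N~hν~ − b)/c → Henderson–Hasselbalch pH.  The printed source
   inversion "N~hν~/c − b" is inconsistent with its own forward model and
   is corrected here.  N̂~HB2~ is clipped to (0.5, N~T~ − 0.5) dye
   molecules; clipped frames are flagged, never dropped silently.  The
   two-point calibration solves for (c, b) from the pre-ATP and maximally
   acidified windows.

## Fitting

`fit_trace()` estimates (I~P~, P~H~, P~AHA2~) from a segmented trace by
Nelder–Mead in log-parameter space (positivity by construction, with
restarts from the perturbed optimum).  The objective is the RMSD — the
printed source writes a bare sum of squares under that name; the square
root of the mean square has the same argmin and comparable values across
trace lengths.  Stochastic modes average the RMSD over n seeded runs
(default 10) with common random numbers across simplex iterations, and the
reported objective is re-evaluated with fresh seeds.  Comparison variables:
pH for the continuum and photon modes, back-converted proton counts for the
count mode (pH is undefined at zero protons).  P~AHA2~ is structurally
poorly constrained from above whenever the post-stop collapse completes
within a frame or two; `paha2_flatness()` quantifies that flat direction
rather than pretending the estimate is sharp.

A caveat discovered while validating recovery: with the simulation's
deliberately slow buffer kinetics (k~off~ = 0.1/s) the dye pool relaxes in
2–9 s, so a *photon-derived* synthetic trace lags the true pH during
transitions.  Fitting such a trace with a forward model that lacks the dye
(continuum or count mode) is then a mis-specified regression and biases
(I~P~, P~H~) down together by ~10–15% — a pure time-scale stretch.  Real
dyes equilibrate orders of magnitude faster, so experimental traces do not
carry this lag.  Recovery validation therefore pairs each fit mode with its
matched observable (`generate_synthetic_star(observable =)`): continuum
fits on continuum or count traces, photon-mode fits on photon traces.

## Noise analysis

Under Poisson statistics σ(N~H~) = √N~H~, so σ(N~H~) grows as r^3/2^ at
fixed pH and as 10^−pH/2^ at fixed radius, while the log transform gives
σ(pH) = 1/(ln 10·√N~H~) ∝ r^−3/2^ and 10^+pH/2^ — larger, more acidic
vesicles have quieter pH.  The scans reproduce all four exponents on
five-point grids.  Two systematic effects are worth knowing: the σ(pH)
statistics mask infinite-pH samples, and at means below ~5 counts the
zero-truncated log-Poisson spread sits slightly below the asymptotic law,
which shaves the fitted radius exponent from −1.50 toward −1.49 and adds
~+0.02 to the pH exponent on the default grids — well inside the tolerance
bands.

The dye reports a different noise altogether: binomial fluctuation of a
fixed pool plus photon shot noise,
σ(pH^hν^) = [1/(ln 10·f(1−f))]·√((f(1−f) + f/λ)/N~dye~).  The f-variance
in this expression is exact; the formula as a whole is first-order in the
log transform, and Monte-Carlo shows it is accurate to better than 10%
only while σ(f̂) is small compared to min(f, 1−f) — at λ = 1 with a 50–100
molecule pool and f near 0.8 the transform nonlinearity pushes the true
spread 13–15% above the formula.  The package reports the empirical spread
and the closed form side by side rather than hiding the regime boundary.
Because the dye pool, not the proton count, dominates recorded
fluctuations, trace noise cannot be inverted into true pH fluctuations;
pumping itself adds no measurable pH noise (the pumped steady state
matches the equilibrium σ(pH) at the same mean pH, and its counts remain
Poisson).

For lysosome-sized vesicles (r = 340 nm) with tens to hundreds of pumps
cycling stochastically (273 s mean dwells), `multipump_experiment()`
reports the steady-state pH histogram per pump count and the
Poisson-percentile ensemble over pump number.  "Total spread" is reported
both as max − min and as the 2.5–97.5 percentile range; the percentile
range is the one used in tests because a single excursion moves max − min
arbitrarily.

## The synthetic recording generator

`generate_synthetic_star()` emulates the experimental protocol — bath pH
6.5, K⁺ clamp active throughout, ATP added near 180 s, pump stop near
506 s, 750 s total, frames integrated 0.5 s and reported every 2 s — with
a known ground truth, defaulting to r = 100 nm, I~P~ = 300 H⁺/s,
P~H~ = 4.6×10⁻⁵ cm/s, P~AHA2~ = 2×10⁻⁴ cm/s.  The default calibration
(c = 40 photons per protonated dye per frame, b = 100 background photons)
puts frame counts in the few-thousand range typical of single-vesicle
fluorescence.  What it does *not* emulate: camera gain and read noise,
photobleaching, dye flip-flop between leaflets, drift in pump activity, or
vesicle size uncertainty — passing recovery tests on these fixtures shows
the estimator is consistent under the model's own noise, not that real
data are this kind.

## Numerical choices, in one place

* Copy-number rounding: nearest integer, ties to even; continuum engine
  unrounded.
* ODE tolerances rtol 10⁻⁸, atol 10⁻¹⁰; piecewise integration across every
  schedule discontinuity.
* Dye-count clipping at 0.5 molecules from either end of the pool, with
  quality flags.
* Poisson GOF: chi-square with adjacent bins merged to expected ≥ 5,
  degrees of freedom = bins − 2; grid-wide tests Bonferroni-corrected.
* Infinite-pH sentinels masked and counted in all σ/mean computations.
* Steady-state windows default to the final half of a run; equilibrium
  scans discard a 50 s prefix.
* Bisection for pump-rate targets runs in log-rate space to 2×10⁻³ pH.
* Sensitivity coefficients: central differences at ±1%,
  ∂ln(output)/∂ln(parameter).
* Problem sizes in the shipped checks: 100-run ensembles for the
  mean-trajectory comparison, 200 s scans on 5-point grids, 750 s
  equilibrium runs, 12–20 synthetic recordings for recovery, stochastic
  fits averaged over 3 runs — sizes chosen so the whole battery runs on a
  single core in well under an hour while leaving Monte-Carlo error
  comfortably inside each tolerance.

## Known limitations

Spherical geometry only; single-valued pK~a~ per buffer with no
temperature dependence or surface-potential correction; no Cl⁻/Na⁺ species
or antiporter kinetics; the pump is voltage-independent; photon statistics
are pure Poisson (no instrument noise); and the stochastic pump mode does
not model the post-stop transporter leak, which is defined by the
single-pump experimental protocol.  The reporter-noise closed form is a
first-order approximation with the validity boundary described above.
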