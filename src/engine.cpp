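#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-method exact stochastic simulation of the vesicle acidification
// network.  Every firing updates the lumenal charge, hence the membrane
// potential, so all propensities are refreshed after every event; the only
// cached quantities are the two voltage Boltzmann factors, recomputed only
// when a charge-moving channel fired.
//
// State: N_H, N_K, N_HB1, N_HB2 (integer-valued, carried as doubles; all
// counts here stay far below 2^53).  Channels, in fixed order:
//   1 H_in   2 H_out   3 K_in   4 K_out
//   5 B1_protonate  6 B1_deprotonate  7 B2_protonate  8 B2_deprotonate
//   9 pump
//
// Piecewise-constant external conditions (pump activity, valinomycin K+
// permeability, post-pump-stop AHA2 leak) arrive as a segment table; the
// exponential clock is memoryless so re-drawing the waiting time at each
// segment boundary keeps the path statistically exact.
//
// `sys` layout (see build_system() on the R side):
//   q0        reference charge count (Donnan particles, N_A*V*B)
//   dpsi_q    volts per unit net charge count, F/(N_A * A_cm2 * C)
//   beta      F/(R*T), 1/V
//   Hin_pref  N_A * [H+]_o  (multiplied by k_H0 * exp(-x/2) -> 1/s)
//   Kin_pref  N_A * [K+]_o
//   invV      1/V in 1/L (efflux: k0 * N / V)
//   konf1/2   k_on / (N_A * V): count-space bimolecular rate
//   koff1/2   1/s
//   NT1/NT2   total buffer copies
//   IP        H+/s per active pump
//
// segments: columns t_start, t_end, kH0, kK0, n_active.

// [[Rcpp::export]]
List ssa_run_cpp(NumericVector init, List sys, NumericMatrix segments,
                 NumericVector sample_times) {
  double NH = init[0], NK = init[1], NHB1 = init[2], NHB2 = init[3];

  const double q0       = as<double>(sys["q0"]);
  const double dpsi_q   = as<double>(sys["dpsi_q"]);
  const double beta     = as<double>(sys["beta"]);
  const double Hin_pref = as<double>(sys["Hin_pref"]);
  const double Kin_pref = as<double>(sys["Kin_pref"]);
  const double invV     = as<double>(sys["invV"]);
  const double konf1    = as<double>(sys["konf1"]);
  const double koff1    = as<double>(sys["koff1"]);
  const double NT1      = as<double>(sys["NT1"]);
  const double konf2    = as<double>(sys["konf2"]);
  const double koff2    = as<double>(sys["koff2"]);
  const double NT2      = as<double>(sys["NT2"]);
  const double IP       = as<double>(sys["IP"]);

  const int nsamp = sample_times.size();
  NumericMatrix out(nsamp, 7);
  int si = 0;
  double t = segments(0, 0);
  double q = NH + NK + NHB1 + NHB2 - q0;     // net charge count
  double x = dpsi_q * q * beta;              // dpsi * F / (R*T)
  double ein = std::exp(-0.5 * x), eout = std::exp(0.5 * x);
  bool qdirty = false;
  double nevents = 0.0;

  // the net charge moves by +/-1 per event, so the two Boltzmann factors
  // take values on an integer lattice: memoize them around the start
  const int CW = 4096;
  const double q_base = q;
  std::vector<double> cein(2 * CW + 1), ceout(2 * CW + 1);
  std::vector<char> cvalid(2 * CW + 1, 0);

  for (int seg = 0; seg < segments.nrow(); ++seg) {
    const double tend = segments(seg, 1);
    const double kH0  = segments(seg, 2);
    const double kK0  = segments(seg, 3);
    const double nact = segments(seg, 4);

    for (;;) {
      if (qdirty) {
        const double d = q - q_base;
        const int k = (int)(d < 0 ? d - 0.5 : d + 0.5);
        if (k >= -CW && k <= CW && std::abs(d - k) < 1e-9) {
          const int idx = k + CW;
          if (!cvalid[idx]) {
            x = dpsi_q * q * beta;
            cein[idx] = std::exp(-0.5 * x);
            ceout[idx] = std::exp(0.5 * x);
            cvalid[idx] = 1;
          }
          ein = cein[idx];
          eout = ceout[idx];
        } else {
          x = dpsi_q * q * beta;
          ein = std::exp(-0.5 * x);
          eout = std::exp(0.5 * x);
        }
        qdirty = false;
      }
      const double a1 = kH0 * Hin_pref * ein;
      const double a2 = kH0 * invV * eout * NH;
      const double a3 = kK0 * Kin_pref * ein;
      const double a4 = kK0 * invV * eout * NK;
      const double a5 = konf1 * (NT1 - NHB1) * NH;
      const double a6 = koff1 * NHB1;
      const double a7 = konf2 * (NT2 - NHB2) * NH;
      const double a8 = koff2 * NHB2;
      const double a9 = IP * nact;
      const double a0 = a1 + a2 + a3 + a4 + a5 + a6 + a7 + a8 + a9;
      if (!R_finite(a0) || a0 < 0.0)
        stop("non-finite or negative total propensity at t = %g", t);

      double tnext = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;

      if (tnext >= tend) {
        // no further event in this segment: record up to and including tend
        // (a sample exactly at a boundary is left-continuous, so it carries
        // the pre-switch pump activity)
        while (si < nsamp && sample_times[si] <= tend) {
          out(si, 0) = sample_times[si];
          out(si, 1) = NH;  out(si, 2) = NK;
          out(si, 3) = NHB1; out(si, 4) = NHB2;
          out(si, 5) = nact; out(si, 6) = dpsi_q * q;
          ++si;
        }
        t = tend;
        break;
      }

      while (si < nsamp && sample_times[si] < tnext) {
        out(si, 0) = sample_times[si];
        out(si, 1) = NH;  out(si, 2) = NK;
        out(si, 3) = NHB1; out(si, 4) = NHB2;
        out(si, 5) = nact; out(si, 6) = dpsi_q * q;
        ++si;
      }

      double u = unif_rand() * a0;
      if      ((u -= a1) < 0) { NH += 1; q += 1; qdirty = true; }
      else if ((u -= a2) < 0) { NH -= 1; q -= 1; qdirty = true; }
      else if ((u -= a3) < 0) { NK += 1; q += 1; qdirty = true; }
      else if ((u -= a4) < 0) { NK -= 1; q -= 1; qdirty = true; }
      else if ((u -= a5) < 0) { NH -= 1; NHB1 += 1; }
      else if ((u -= a6) < 0) { NH += 1; NHB1 -= 1; }
      else if ((u -= a7) < 0) { NH -= 1; NHB2 += 1; }
      else if ((u -= a8) < 0) { NH += 1; NHB2 -= 1; }
      else                    { NH += 1; q += 1; qdirty = true; }

      if (NH < 0 || NK < 0 || NHB1 < 0 || NHB2 < 0 ||
          NHB1 > NT1 || NHB2 > NT2)
        stop("internal error: count left its admissible range at t = %g", t);

      t = tnext;
      nevents += 1.0;
      if (((long long)nevents & 0xFFFFF) == 0) checkUserInterrupt();
    }
  }

  return List::create(_["samples"] = out, _["n_events"] = nevents);
}

// Deterministic right-hand side of the same network (counts as reals),
// used by the stiff ODE integrator.  Parameter vector layout mirrors `sys`
// with the per-segment quantities appended: kH0, kK0, n_active.
// [[Rcpp::export]]
NumericVector ode_rhs_cpp(double t, NumericVector y, NumericVector p) {
  const double NH = y[0], NK = y[1], NHB1 = y[2], NHB2 = y[3];
  const double q0 = p[0], dpsi_q = p[1], beta = p[2], Hin_pref = p[3],
               Kin_pref = p[4], invV = p[5], konf1 = p[6], koff1 = p[7],
               NT1 = p[8], konf2 = p[9], koff2 = p[10], NT2 = p[11],
               IP = p[12], kH0 = p[13], kK0 = p[14], nact = p[15];

  const double x = dpsi_q * (NH + NK + NHB1 + NHB2 - q0) * beta;
  const double ein = std::exp(-0.5 * x), eout = std::exp(0.5 * x);

  const double jH  = kH0 * (Hin_pref * ein - invV * eout * NH);
  const double jK  = kK0 * (Kin_pref * ein - invV * eout * NK);
  const double jB1 = konf1 * (NT1 - NHB1) * NH - koff1 * NHB1;
  const double jB2 = konf2 * (NT2 - NHB2) * NH - koff2 * NHB2;

  NumericVector dy(4);
  dy[0] = IP * nact + jH - jB1 - jB2;
  dy[1] = jK;
  dy[2] = jB1;
  dy[3] = jB2;
  return dy;
}
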