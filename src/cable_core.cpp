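#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Implicit (backward Euler) integration of the multicompartment cable
// equation on a tree, with Hodgkin-Huxley style gating integrated by the
// exponential-relaxation rule at the previous voltage, and an extracellular
// potential entering as axial currents driven by differences of Ve across
// connected nodes.
//
// Units: t in ms, V in mV, capacitance in uF, conductance in mS (so
// currents are in uA).
//
// Nodes are ordered so that parent[i] < i (parent[root] = -1); the
// resulting symmetric tree-structured linear system is solved exactly in
// O(n) per step by Hines elimination.
//
// Gate parameter rows (one per gate, stacked over channels):
//   0 exponent, 1 inf_vhalf, 2 inf_k, 3 tau_min, 4 tau_amp,
//   5 tau_vhalf, 6 tau_ka, 7 tau_kb
//
// wave[k] is the dimensionless modulator at t = k * dt (k = 0..n_steps);
// the per-node extracellular potential at that time is pattern * wave[k]
// (pattern already includes the amplification coefficient).

// [[Rcpp::export]]
List cable_run_cpp(IntegerVector parent, NumericVector g_parent,
                   NumericVector cap, NumericVector g_leak,
                   NumericVector e_leak, NumericVector erev,
                   IntegerVector gates_per_channel,
                   NumericMatrix gate_params, NumericMatrix gbar,
                   NumericVector v0, NumericMatrix gates0,
                   NumericVector pattern, NumericVector wave,
                   NumericVector i_inject, double dt, int record_stride) {
  const int n = parent.size();
  const int n_channels = erev.size();
  const int n_gates = gate_params.nrow();
  const int n_steps = wave.size() - 1;

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> gates(n * n_gates);
  for (int g = 0; g < n_gates; ++g)
    for (int i = 0; i < n; ++i) gates[g * n + i] = gates0(i, g);

  // static part of the diagonal: sum of incident axial conductances
  std::vector<double> g_axial_sum(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (parent[i] >= 0) {
      g_axial_sum[i] += g_parent[i];
      g_axial_sum[parent[i]] += g_parent[i];
    }
  }

  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix vm_out(n, n_rec);
  IntegerVector rec_steps(n_rec);
  for (int i = 0; i < n; ++i) vm_out(i, 0) = v[i];
  rec_steps[0] = 0;
  int rec = 1;

  std::vector<double> d(n), rhs(n), g_ion(n), b_ion(n), open(n);

  for (int k = 1; k <= n_steps; ++k) {
    // 1. gate update (exponential relaxation at frozen voltage)
    int g0 = 0;
    for (int c = 0; c < n_channels; ++c) {
      for (int gg = 0; gg < gates_per_channel[c]; ++gg) {
        const int g = g0 + gg;
        const double vh = gate_params(g, 1), kk = gate_params(g, 2);
        const double tmin = gate_params(g, 3), tamp = gate_params(g, 4);
        const double tvh = gate_params(g, 5), tka = gate_params(g, 6),
                     tkb = gate_params(g, 7);
        double *x = &gates[g * n];
        for (int i = 0; i < n; ++i) {
          const double xinf = 1.0 / (1.0 + std::exp(-(v[i] - vh) / kk));
          const double tau = tmin + tamp /
            (std::exp((v[i] - tvh) / tka) + std::exp(-(v[i] - tvh) / tkb));
          x[i] += (xinf - x[i]) * (1.0 - std::exp(-dt / tau));
        }
      }
      g0 += gates_per_channel[c];
    }

    // 2. ionic conductances at updated gates
    std::fill(g_ion.begin(), g_ion.end(), 0.0);
    std::fill(b_ion.begin(), b_ion.end(), 0.0);
    g0 = 0;
    for (int c = 0; c < n_channels; ++c) {
      std::fill(open.begin(), open.end(), 1.0);
      for (int gg = 0; gg < gates_per_channel[c]; ++gg) {
        const int g = g0 + gg;
        const int e = (int) gate_params(g, 0);
        const double *x = &gates[g * n];
        for (int i = 0; i < n; ++i) {
          double p = x[i];
          double acc = 1.0;
          int ee = e;
          while (ee > 0) { if (ee & 1) acc *= p; p *= p; ee >>= 1; }
          open[i] *= acc;
        }
      }
      for (int i = 0; i < n; ++i) {
        const double gch = gbar(i, c) * open[i];
        g_ion[i] += gch;
        b_ion[i] += gch * erev[c];
      }
      g0 += gates_per_channel[c];
    }

    // 3. assemble implicit system at t + dt
    const double w = wave[k];
    for (int i = 0; i < n; ++i) {
      d[i] = cap[i] / dt + g_leak[i] + g_ion[i] + g_axial_sum[i];
      rhs[i] = cap[i] / dt * v[i] + g_leak[i] * e_leak[i] + b_ion[i] +
        i_inject[i];
    }
    for (int i = 0; i < n; ++i) {
      const int p = parent[i];
      if (p >= 0) {
        const double f = g_parent[i] * (pattern[p] - pattern[i]) * w;
        rhs[i] += f;
        rhs[p] -= f;
      }
    }

    // 4. Hines solve (leaves -> root, then root -> leaves)
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = g_parent[i] / d[i];
      d[p] -= g_parent[i] * f;
      rhs[p] += rhs[i] * f;
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      v[i] = (rhs[i] + g_parent[i] * v[parent[i]]) / d[i];
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i])) {
        stop("non-finite membrane potential at node %d, t = %g ms", i + 1,
             k * dt);
      }
    }

    if (k % record_stride == 0 && rec < n_rec) {
      for (int i = 0; i < n; ++i) vm_out(i, rec) = v[i];
      rec_steps[rec] = k;
      ++rec;
    }
  }

  NumericVector v_final(n);
  for (int i = 0; i < n; ++i) v_final[i] = v[i];
  NumericMatrix gates_final(n, n_gates);
  for (int g = 0; g < n_gates; ++g)
    for (int i = 0; i < n; ++i) gates_final(i, g) = gates[g * n + i];

  return List::create(_["vm"] = vm_out, _["rec_steps"] = rec_steps,
                      _["v_final"] = v_final,
                      _["gates_final"] = gates_final);
}
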