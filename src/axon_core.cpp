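// Core numerical kernels: exponential-Euler integration of the
// Na/KH/KL/leak point-neuron, state-based rendering of biexponential
// EPSC superpositions, and the seeded renewal EPSC event generator.
// All time in ms, voltage in mV, conductance densities in mS/cm^2,
// capacitance in uF/cm^2, point currents in pA.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gating kinetics of the sodium (m, h), high-voltage-gated potassium
// (n, p) and low-voltage-gated potassium (w, z) channels.
static inline double xinf_m(double v) { return 1.0 / (1.0 + std::exp(-(v + 38.0) / 7.0)); }
static inline double tau_m(double v)  { return 10.0 / (5.0 * std::exp((v + 60.0) / 18.0) + 36.0 * std::exp(-(v + 60.0) / 25.0)) + 0.04; }
static inline double xinf_h(double v) { return 1.0 / (1.0 + std::exp((v + 65.0) / 6.0)); }
static inline double tau_h(double v)  { return 100.0 / (7.0 * std::exp((v + 60.0) / 11.0) + 10.0 * std::exp(-(v + 60.0) / 25.0)) + 0.6; }
static inline double xinf_n(double v) { return std::pow(1.0 + std::exp(-(v + 15.0) / 5.0), -0.5); }
static inline double tau_n(double v)  { return 100.0 / (11.0 * std::exp((v + 60.0) / 24.0) + 21.0 * std::exp(-(v + 60.0) / 23.0)) + 0.7; }
static inline double xinf_p(double v) { return 1.0 / (1.0 + std::exp(-(v + 23.0) / 6.0)); }
static inline double tau_p(double v)  { return 100.0 / (4.0 * std::exp((v + 60.0) / 32.0) + 5.0 * std::exp(-(v + 60.0) / 22.0)) + 5.0; }
static inline double xinf_w(double v) { return std::pow(1.0 + std::exp(-(v + 48.0) / 6.0), -0.25); }
static inline double tau_w(double v)  { return 100.0 / (6.0 * std::exp((v + 60.0) / 6.0) + 16.0 * std::exp(-(v + 60.0) / 45.0)) + 1.5; }
static inline double xinf_z(double v) { return 0.5 + 0.5 / (1.0 + std::exp((v + 71.0) / 10.0)); }
static inline double tau_z(double v)  { return 1000.0 / (std::exp((v + 60.0) / 20.0) + std::exp(-(v + 60.0) / 8.0)) + 50.0; }

// [[Rcpp::export]]
List cpp_gating_inf_tau(NumericVector v) {
  int n = v.size();
  NumericMatrix xinf(n, 6), tau(n, 6);
  for (int i = 0; i < n; ++i) {
    double vv = v[i];
    xinf(i, 0) = xinf_m(vv); tau(i, 0) = tau_m(vv);
    xinf(i, 1) = xinf_h(vv); tau(i, 1) = tau_h(vv);
    xinf(i, 2) = xinf_n(vv); tau(i, 2) = tau_n(vv);
    xinf(i, 3) = xinf_p(vv); tau(i, 3) = tau_p(vv);
    xinf(i, 4) = xinf_w(vv); tau(i, 4) = tau_w(vv);
    xinf(i, 5) = xinf_z(vv); tau(i, 5) = tau_z(vv);
  }
  colnames(xinf) = CharacterVector::create("m", "h", "n", "p", "w", "z");
  colnames(tau) = CharacterVector::create("m", "h", "n", "p", "w", "z");
  return List::create(_["xinf"] = xinf, _["tau"] = tau);
}

struct GateTables {
  // per-gate steady states and exp(-dt/tau) on a uniform voltage grid;
  // tau_scale > 1 speeds all gating kinetics uniformly (temperature)
  double vmin, dv_inv;
  int n;
  std::vector<double> xinf[6], edt[6];
  GateTables(double dt, double tau_scale = 1.0, double vlo = -150.0,
             double vhi = 80.0, double dv = 0.05) {
    vmin = vlo; dv_inv = 1.0 / dv;
    n = (int)((vhi - vlo) / dv) + 2;
    double (*fi[6])(double) = {xinf_m, xinf_h, xinf_n, xinf_p, xinf_w, xinf_z};
    double (*ft[6])(double) = {tau_m, tau_h, tau_n, tau_p, tau_w, tau_z};
    for (int g = 0; g < 6; ++g) {
      xinf[g].resize(n); edt[g].resize(n);
      for (int i = 0; i < n; ++i) {
        double v = vlo + i / dv_inv;
        xinf[g][i] = fi[g](v);
        edt[g][i] = std::exp(-dt * tau_scale / ft[g](v));
      }
    }
  }
  inline void lookup(double v, double* xi, double* ed) const {
    double x = (v - vmin) * dv_inv;
    if (x < 0.0) x = 0.0;
    if (x > n - 2) x = n - 2;
    int i0 = (int)x;
    double f = x - i0;
    for (int g = 0; g < 6; ++g) {
      xi[g] = xinf[g][i0] + f * (xinf[g][i0 + 1] - xinf[g][i0]);
      ed[g] = edt[g][i0] + f * (edt[g][i0 + 1] - edt[g][i0]);
    }
  }
};

// [[Rcpp::export]]
List cpp_simulate_axon(List params, IntegerVector event_idx, NumericVector event_amp,
                       NumericVector i_gvs, double total_ms, double dt,
                       double tau_rise, double tau_decay,
                       double v_init, NumericVector gates_init,
                       double threshold, double refractory,
                       bool record_v) {
  double g_na = params["g_na"], g_kh = params["g_kh"], g_kl = params["g_kl"],
         g_leak = params["g_leak"], e_na = params["e_na"], e_k = params["e_k"],
         e_leak = params["e_leak"], cm = params["cm"], area = params["area"],
         tau_scale = params.containsElementNamed("tau_scale") ?
           as<double>(params["tau_scale"]) : 1.0;
  long n = (long)std::llround(total_ms / dt) + 1;
  bool gvs_scalar = (i_gvs.size() == 1);
  if (!gvs_scalar && (long)i_gvs.size() != n)
    stop("i_gvs must have length 1 or match the time grid");

  GateTables tab(dt, tau_scale);
  // biexponential synapse as two decaying states
  double er = std::exp(-dt / tau_rise), ed_syn = std::exp(-dt / tau_decay);
  double tpk = std::log(tau_decay / tau_rise) /
               (1.0 / tau_rise - 1.0 / tau_decay);
  double norm = 1.0 / (std::exp(-tpk / tau_decay) - std::exp(-tpk / tau_rise));
  double syn_r = 0.0, syn_d = 0.0;

  double v = v_init;
  double gate[6];
  for (int g = 0; g < 6; ++g) gate[g] = gates_init[g];

  NumericVector v_out;
  if (record_v) v_out = NumericVector(n);
  std::vector<double> spikes;
  double last_spike = -1e9;
  double pa_to_uAcm2 = 1e-6 / area;
  int ne = event_idx.size(), ev = 0;
  double xi[6], edt[6];

  for (long i = 0; i < n; ++i) {
    while (ev < ne && event_idx[ev] == i) {
      syn_r += event_amp[ev] * norm;
      syn_d += event_amp[ev] * norm;
      ++ev;
    }
    double i_syn = syn_d - syn_r;  // pA, >= 0
    double i_inj = (i_syn + (gvs_scalar ? i_gvs[0] : i_gvs[i])) * pa_to_uAcm2;

    double i_na = g_na * gate[0] * gate[0] * gate[0] * gate[1] * (v - e_na);
    double i_kh = g_kh * (0.85 * gate[2] * gate[2] + 0.15 * gate[3]) * (v - e_k);
    double i_kl = g_kl * gate[4] * gate[4] * gate[4] * gate[4] * gate[5] * (v - e_k);
    double i_lk = g_leak * (v - e_leak);
    double vnew = v + dt * (-(i_na + i_kh + i_kl + i_lk) + i_inj) / cm;

    tab.lookup(v, xi, edt);
    for (int g = 0; g < 6; ++g)
      gate[g] = xi[g] + (gate[g] - xi[g]) * edt[g];

    double t = i * dt;
    if (vnew >= threshold && v < threshold && (t - last_spike) >= refractory) {
      spikes.push_back(t);
      last_spike = t;
    }
    v = vnew;
    if (record_v) v_out[i] = v;
    if (!R_finite(v) || std::fabs(v) > 1000.0)
      stop("integration failure (V = %f mV) at t = %f ms", v, t);
    syn_r *= er; syn_d *= ed_syn;
  }

  List out = List::create(_["spike_times"] = wrap(spikes),
                          _["n_steps"] = (double)n);
  if (record_v) out["v"] = v_out;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_render_epsc(NumericVector event_times, NumericVector event_amp,
                              long n, double dt, double tau_rise, double tau_decay) {
  NumericVector out((R_xlen_t)n);
  double er = std::exp(-dt / tau_rise), ed = std::exp(-dt / tau_decay);
  double tpk = std::log(tau_decay / tau_rise) / (1.0 / tau_rise - 1.0 / tau_decay);
  double norm = 1.0 / (std::exp(-tpk / tau_decay) - std::exp(-tpk / tau_rise));
  double r = 0.0, d = 0.0;
  int ne = event_times.size(), ev = 0;
  for (long i = 0; i < n; ++i) {
    while (ev < ne && (long)std::llround(event_times[ev] / dt) == i) {
      r += event_amp[ev] * norm;
      d += event_amp[ev] * norm;
      ++ev;
    }
    out[i] = d - r;
    r *= er; d *= ed;
  }
  return out;
}

// Renewal EPSC arrival times with exponential inter-arrival intervals whose
// mean follows a piecewise-constant mu(t) (segments of length seg_ms).
// Uses R's RNG stream so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_draw_epsc_times(NumericVector mu, double seg_ms, double total_ms) {
  RNGScope scope;
  std::vector<double> times;
  int nseg = mu.size();
  double t = 0.0;
  while (true) {
    int seg = (int)(t / seg_ms);
    if (seg >= nseg) seg = nseg - 1;
    t += mu[seg] * exp_rand();
    if (t >= total_ms) break;
    times.push_back(t);
  }
  return wrap(times);
}
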