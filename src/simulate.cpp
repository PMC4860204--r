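// Forward-Euler core for the conductance-based neuron, the voltage-shift
// threshold probe, and the exact-integration adaptive threshold (MAT) model.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (see .param_vec() on the R side):
// 0 C_m, 1 g_L, 2 g_Na, 3 g_Kd, 4 g_M, 5 g_Ca, 6 g_AHP,
// 7 E_L, 8 E_Na, 9 E_K, 10 E_Ca, 11 tau_max (ms), 12 beta_s (/ms),
// 13 tau_Ca (ms), 14 Ca_inf (uM), 15 F (C/mol)

// State vector layout: 0 V, 1 m, 2 h, 3 n, 4 p, 5 q, 6 r, 7 s, 8 Ca

// x / (1 - exp(-x/y)); removable singularity at x = 0 handled by its limit
// y + x/2 when |x/y| < 1e-7.
static inline double expdiv(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y + 0.5 * x;
  return x / (1.0 - std::exp(-x / y));
}

// Rate functions for gates m, h, n, p, q, r, s (units /ms, V in mV, Ca in uM)
static void all_rates(const double* pp, double V, double Ca,
                      double* a, double* b) {
  a[0] = 0.32 * expdiv(V + 45.0, 4.0);
  b[0] = 0.28 * expdiv(-(V + 18.0), 5.0);
  a[1] = 0.128 * std::exp(-(V + 41.0) / 18.0);
  b[1] = 4.0 / (1.0 + std::exp(-(V + 18.0) / 5.0));
  a[2] = 0.032 * expdiv(V + 43.0, 5.0);
  b[2] = 0.5 * std::exp(-(V + 48.0) / 40.0);
  double pinf = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
  double taup = pp[11] / (3.3 * std::exp((V + 35.0) / 20.0) +
                          std::exp(-(V + 35.0) / 20.0));
  a[3] = pinf / taup;
  b[3] = (1.0 - pinf) / taup;
  a[4] = 0.055 * expdiv(V + 27.0, 3.8);
  b[4] = 0.94 * std::exp(-(V + 75.0) / 17.0);
  a[5] = 0.000457 * std::exp(-(V + 13.0) / 50.0);
  b[5] = 0.0065 / (1.0 + std::exp(-(V + 15.0) / 28.0));
  a[6] = 0.01 * Ca;
  b[6] = pp[12];
}

// Per-ion currents: I_L, I_Na, I_Kd, I_M, I_Ca, I_AHP (uA/cm^2)
static inline void ionic_currents(const double* pp, const double* st,
                                  double* I) {
  double V = st[0];
  double n2 = st[3] * st[3];
  I[0] = pp[1] * (V - pp[7]);
  I[1] = pp[2] * st[1] * st[1] * st[1] * st[2] * (V - pp[8]);
  I[2] = pp[3] * n2 * n2 * (V - pp[9]);
  I[3] = pp[4] * st[4] * (V - pp[9]);
  I[4] = pp[5] * st[5] * st[5] * st[6] * (V - pp[10]);
  I[5] = pp[6] * st[7] * (V - pp[9]);
}

// One forward-Euler step in place; returns false on non-finite state.
static inline bool euler_step(const double* pp, double* st, double Iex,
                              double dt) {
  double a[7], b[7], I[6];
  all_rates(pp, st[0], st[8], a, b);
  ionic_currents(pp, st, I);
  double Isum = I[0] + I[1] + I[2] + I[3] + I[4] + I[5];
  double dCa = -1e5 * I[4] / (2.0 * pp[15]) - (st[8] - pp[14]) / pp[13];
  st[0] += dt * (-(Isum) + Iex) / pp[0];
  for (int g = 0; g < 7; ++g) {
    double w = st[1 + g] + dt * (a[g] * (1.0 - st[1 + g]) - b[g] * st[1 + g]);
    // clip only hair-width numerical excursions; larger ones surface as errors
    if (w < 0.0 && w > -1e-12) w = 0.0;
    if (w > 1.0 && w < 1.0 + 1e-12) w = 1.0;
    st[1 + g] = w;
  }
  st[8] += dt * dCa;
  if (st[8] < 0.0 && st[8] > -1e-12) st[8] = 0.0;
  return std::isfinite(st[0]) && std::isfinite(st[8]);
}

// [[Rcpp::export]]
NumericMatrix gate_rates_cpp(NumericVector par, NumericVector V,
                             NumericVector Ca) {
  int n = V.size();
  NumericMatrix out(n, 14); // alpha x 7, beta x 7
  double a[7], b[7];
  for (int i = 0; i < n; ++i) {
    all_rates(REAL(par), V[i], Ca[i % Ca.size()], a, b);
    for (int g = 0; g < 7; ++g) {
      out(i, g) = a[g];
      out(i, 7 + g) = b[g];
    }
  }
  return out;
}

// [[Rcpp::export]]
List hh_sim_cpp(NumericVector par, NumericVector Iex, double dt,
                NumericVector init, bool record_currents, bool record_gates) {
  int n = Iex.size();
  const double* pp = REAL(par);
  double st[9];
  for (int k = 0; k < 9; ++k) st[k] = init[k];
  NumericVector V(n);
  NumericMatrix cur(record_currents ? n : 0, 6);
  NumericMatrix gat(record_gates ? n : 0, 8);
  double I[6];
  for (int i = 0; i < n; ++i) {
    V[i] = st[0];
    if (record_currents) {
      ionic_currents(pp, st, I);
      for (int k = 0; k < 6; ++k) cur(i, k) = I[k];
    }
    if (record_gates) {
      for (int k = 0; k < 8; ++k) gat(i, k) = st[1 + k];
    }
    if (i < n - 1) {
      if (!euler_step(pp, st, Iex[i], dt))
        stop("conductance-based simulation diverged at step %d (t = %.3f ms)",
             i + 1, i * dt);
    }
  }
  NumericVector fin(9);
  for (int k = 0; k < 9; ++k) fin[k] = st[k];
  List out = List::create(_["V"] = V, _["final_state"] = fin);
  if (record_currents) out["currents"] = cur;
  if (record_gates) out["gates"] = gat;
  return out;
}

// Relax toward a fixed point under constant current. Returns the final state,
// whether all time-derivatives fell below tol, and whether a spike occurred.
// [[Rcpp::export]]
List hh_relax_cpp(NumericVector par, double Ic, double dt, NumericVector init,
                  double max_ms, double tol) {
  const double* pp = REAL(par);
  double st[9];
  for (int k = 0; k < 9; ++k) st[k] = init[k];
  int nmax = (int)std::ceil(max_ms / dt);
  bool spiked = false, converged = false;
  double t = 0.0;
  double a[7], b[7], I[6];
  for (int i = 0; i < nmax; ++i) {
    double prevV = st[0];
    if (!euler_step(pp, st, Ic, dt))
      stop("relaxation diverged at t = %.3f ms", i * dt);
    t += dt;
    if (prevV <= 0.0 && st[0] > 0.0) spiked = true;
    if (i % 20 == 19) {
      all_rates(pp, st[0], st[8], a, b);
      ionic_currents(pp, st, I);
      double Isum = I[0] + I[1] + I[2] + I[3] + I[4] + I[5];
      double dmax = std::fabs((-Isum + Ic) / pp[0]);
      for (int g = 0; g < 7; ++g) {
        double dw = std::fabs(a[g] * (1.0 - st[1 + g]) - b[g] * st[1 + g]);
        if (dw > dmax) dmax = dw;
      }
      double dCa = std::fabs(-1e5 * I[4] / (2.0 * pp[15]) -
                             (st[8] - pp[14]) / pp[13]);
      if (dCa > dmax) dmax = dCa;
      if (dmax < tol) { converged = true; break; }
    }
  }
  NumericVector fin(9);
  for (int k = 0; k < 9; ++k) fin[k] = st[k];
  return List::create(_["state"] = fin, _["converged"] = converged,
                      _["spiked"] = spiked, _["elapsed_ms"] = t);
}

// Voltage-shift spike probe: set V <- c (gates and Ca untouched), integrate
// for `horizon` ms under constant current Ic, return the interpolated time of
// the first upward crossing of `level`, or -1 if none.
// [[Rcpp::export]]
double hh_first_crossing_cpp(NumericVector par, NumericVector init, double c,
                             double Ic, double horizon, double dt,
                             double level) {
  const double* pp = REAL(par);
  double st[9];
  for (int k = 0; k < 9; ++k) st[k] = init[k];
  st[0] = c;
  int nmax = (int)std::ceil(horizon / dt);
  for (int i = 0; i < nmax; ++i) {
    double prevV = st[0];
    if (!euler_step(pp, st, Ic, dt))
      stop("probe simulation diverged at t = %.3f ms", i * dt);
    if (prevV <= level && st[0] > level) {
      double frac = (level - prevV) / (st[0] - prevV);
      return (i + frac) * dt;
    }
  }
  return -1.0;
}

// MAT model with exact subthreshold integration. The threshold is maintained
// as one decaying accumulator per kernel exponential; each accumulator gains
// alpha_j at a spike, so theta(t) = theta_inf + sum_j h_j(t) equals the sum
// of the kernel over all past spikes.
// [[Rcpp::export]]
List mat_sim_cpp(NumericVector Iex, double dt, double tau_m, double C_m,
                 double theta_inf, NumericVector alpha, NumericVector tau,
                 double refractory, double u0, bool record) {
  int n = Iex.size();
  int L = alpha.size();
  double decay_u = std::exp(-dt / tau_m);
  double gain = tau_m * (1.0 - decay_u) / C_m;
  std::vector<double> decay(L), h(L, 0.0);
  for (int j = 0; j < L; ++j) decay[j] = std::exp(-dt / tau[j]);
  double u = u0;
  double last_spike = -1e18;
  std::vector<double> spikes;
  NumericVector urec(record ? n : 0), trec(record ? n : 0);
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(Iex[i])) stop("non-finite input current at sample %d", i + 1);
    double theta = theta_inf;
    for (int j = 0; j < L; ++j) theta += h[j];
    double t = i * dt;
    if (record) { urec[i] = u; trec[i] = theta; }
    if (u >= theta && t - last_spike >= refractory) {
      spikes.push_back(t);
      last_spike = t;
      for (int j = 0; j < L; ++j) h[j] += alpha[j];
    }
    u = u * decay_u + Iex[i] * gain;
    for (int j = 0; j < L; ++j) h[j] *= decay[j];
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (record) { out["u"] = urec; out["theta"] = trec; }
  return out;
}

// Greedy in-order one-to-one matching of two sorted spike trains with
// tolerance delta; returns the number of matched pairs.
// [[Rcpp::export]]
int count_coincidences_cpp(NumericVector a, NumericVector b, double delta) {
  int i = 0, j = 0, nc = 0;
  while (i < a.size() && j < b.size()) {
    double d = a[i] - b[j];
    if (std::fabs(d) <= delta) { ++nc; ++i; ++j; }
    else if (d > 0) ++j;
    else ++i;
  }
  return nc;
}
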