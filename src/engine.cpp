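// Fixed-step network engine: odorant transduction cascade, Connor-Stevens
// axon hillocks, alpha synapses, divisive presynaptic terminals.
// Exponential-Euler updates throughout; voltage-dependent gating kinetics
// are tabulated per run (0.05 mV grid, linear interpolation) as neural
// simulators conventionally do.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct CSParams {
  double C, gna, ena, gk, ek, ga, ea, gl, el, v0, thresh, lockout;
};

CSParams read_cs(const List& cs) {
  CSParams p;
  p.C = as<double>(cs["capacitance"]);
  p.gna = as<double>(cs["g_na"]);   p.ena = as<double>(cs["e_na"]);
  p.gk = as<double>(cs["g_k"]);     p.ek = as<double>(cs["e_k"]);
  p.ga = as<double>(cs["g_a"]);     p.ea = as<double>(cs["e_a"]);
  p.gl = as<double>(cs["g_leak"]);  p.el = as<double>(cs["e_leak"]);
  p.v0 = as<double>(cs["v_init"]);
  p.thresh = as<double>(cs["spike_threshold"]);
  p.lockout = as<double>(cs["spike_lockout"]);
  return p;
}

inline double safe_exp_ratio(double x, double num_scale, double denom_scale) {
  // num_scale * x / (1 - exp(-x / denom_scale)), with the x -> 0 limit
  if (std::fabs(x) < 1e-7) return num_scale * denom_scale;
  return num_scale * x / (1.0 - std::exp(-x / denom_scale));
}

// Connor-Stevens gating kinetics (canonical published rate functions,
// temperature-adjusted; V in mV, rates in 1/ms)
inline void cs_rates(double V, double* xinf, double* tau) {
  double am = safe_exp_ratio(V + 29.7, 0.38, 10.0);
  double bm = 15.2 * std::exp(-0.0556 * (V + 54.7));
  double ah = 0.266 * std::exp(-0.05 * (V + 48.0));
  double bh = 3.8 / (1.0 + std::exp(-0.1 * (V + 18.0)));
  double an = safe_exp_ratio(V + 45.7, 0.02, 10.0);
  double bn = 0.25 * std::exp(-0.0125 * (V + 55.7));
  xinf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  xinf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  xinf[2] = an / (an + bn); tau[2] = 1.0 / (an + bn);
  xinf[3] = std::pow(0.0761 * std::exp((V + 94.22) / 31.84) /
                     (1.0 + std::exp((V + 1.17) / 28.93)), 1.0 / 3.0);
  tau[3] = 0.3632 + 1.158 / (1.0 + std::exp((V + 55.96) / 20.12));
  xinf[4] = std::pow(1.0 / (1.0 + std::exp((V + 53.3) / 14.54)), 4.0);
  tau[4] = 1.24 + 2.678 / (1.0 + std::exp((V + 50.0) / 16.027));
}

// lookup table for exp(-x) on [0, 16] (linear interpolation, ~5e-7 abs
// error); arguments beyond the range decay to 0
struct ExpTable {
  double inv_dx;
  int n;
  std::vector<double> v;
  void build(double xmax = 16.0, int n_ = 8193) {
    n = n_;
    inv_dx = (n - 1) / xmax;
    v.resize(n);
    for (int i = 0; i < n; ++i) v[i] = std::exp(-i / inv_dx);
  }
  inline double neg(double x) const {
    double pos = x * inv_dx;
    if (pos >= n - 1) return 0.0;
    if (pos < 0.0) pos = 0.0;
    int i = (int)pos;
    double w = pos - i;
    return v[i] * (1.0 - w) + v[i + 1] * w;
  }
};

// Gating lookup table over [vmin, vmax] at dv resolution, storing xinf and
// the per-step decay factor exp(-dt/tau) for the 5 gating variables.
struct GateTable {
  double vmin, vmax, inv_dv;
  int n;
  std::vector<double> xinf;  // n x 5
  std::vector<double> fdec;  // n x 5
  void build(double dt, double vmin_ = -120.0, double vmax_ = 80.0,
             double dv = 0.05) {
    vmin = vmin_; vmax = vmax_; inv_dv = 1.0 / dv;
    n = (int)std::floor((vmax - vmin) / dv) + 1;
    xinf.resize((size_t)n * 5);
    fdec.resize((size_t)n * 5);
    double xi[5], tau[5];
    for (int i = 0; i < n; ++i) {
      double V = vmin + i / inv_dv;
      cs_rates(V, xi, tau);
      for (int j = 0; j < 5; ++j) {
        xinf[(size_t)i * 5 + j] = xi[j];
        fdec[(size_t)i * 5 + j] = std::exp(-dt / tau[j]);
      }
    }
  }
  inline void lookup(double V, double* xi, double* fd) const {
    double pos = (V - vmin) * inv_dv;
    if (pos < 0.0) pos = 0.0;
    if (pos > n - 1.000001) pos = n - 1.000001;
    int i = (int)pos;
    double w = pos - i;
    const double* x0 = &xinf[(size_t)i * 5];
    const double* f0 = &fdec[(size_t)i * 5];
    for (int j = 0; j < 5; ++j) {
      xi[j] = x0[j] * (1.0 - w) + x0[j + 5] * w;
      fd[j] = f0[j] * (1.0 - w) + f0[j + 5] * w;
    }
  }
};

struct CSState {
  double V, m, h, n, a, b, last_spike;
  void init(const CSParams& p) {
    V = p.v0;
    double xi[5], tau[5];
    cs_rates(V, xi, tau);
    m = xi[0]; h = xi[1]; n = xi[2]; a = xi[3]; b = xi[4];
    last_spike = -1e9;
  }
};

// one exponential-Euler step; returns true on an upward threshold crossing
// outside the lockout window
inline bool cs_step(CSState& s, const CSParams& p, const GateTable& tab,
                    const ExpTable& et, double dt, double t, double I_drive,
                    double g_syn, double ge_syn) {
  double xi[5], fd[5];
  tab.lookup(s.V, xi, fd);
  double gna = p.gna * s.m * s.m * s.m * s.h;
  double gk = p.gk * s.n * s.n * s.n * s.n;
  double ga = p.ga * s.a * s.a * s.a * s.b;
  double gtot = p.gl + gna + gk + ga + g_syn;
  double drive = p.gl * p.el + gna * p.ena + gk * p.ek + ga * p.ea +
    ge_syn + I_drive;
  double vinf = drive / gtot;
  double vprev = s.V;
  s.V = vinf + (s.V - vinf) * et.neg(dt * gtot / p.C);
  s.m = xi[0] + (s.m - xi[0]) * fd[0];
  s.h = xi[1] + (s.h - xi[1]) * fd[1];
  s.n = xi[2] + (s.n - xi[2]) * fd[2];
  s.a = xi[3] + (s.a - xi[3]) * fd[3];
  s.b = xi[4] + (s.b - xi[4]) * fd[4];
  bool spike = vprev < p.thresh && s.V >= p.thresh &&
    (t - s.last_spike) >= p.lockout;
  if (spike) s.last_spike = t;
  return spike;
}

} // namespace

//' @useDynLib antennalobe, .registration = TRUE
//' @importFrom Rcpp evalCpp

// [[Rcpp::export]]
List cs_integrate_cpp(NumericVector ivec, double dt, List cs, bool record_v) {
  CSParams p = read_cs(cs);
  GateTable tab; tab.build(dt);
  ExpTable et; et.build();
  CSState s; s.init(p);
  int n_steps = ivec.size();
  std::vector<double> spikes;
  NumericVector v;
  if (record_v) v = NumericVector(n_steps);
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    if (cs_step(s, p, tab, et, dt, t, ivec[k], 0.0, 0.0)) spikes.push_back(t);
    if (!R_finite(s.V) || std::fabs(s.V) > 500.0)
      stop("integration blow-up at t = %.3f ms", t);
    if (record_v) v[k] = s.V;
  }
  List out = List::create(_["spike_times"] = wrap(spikes));
  if (record_v) out["v"] = v;
  return out;
}

// [[Rcpp::export]]
List run_network_cpp(IntegerVector class_code, NumericVector i_ext,
                     NumericVector osn_b, NumericVector osn_d,
                     NumericMatrix u_samples, double u_dt_ms,
                     IntegerVector e_pre, IntegerVector e_post,
                     NumericVector e_gbar, NumericVector e_tau,
                     NumericVector e_erev, IntegerVector e_presyn,
                     NumericVector e_kappa,
                     List cs, List otp,
                     double dt, double duration_s, double window_s,
                     bool record_v, double record_dt) {
  const int n_neurons = class_code.size();
  const int n_edges = e_pre.size();
  CSParams p = read_cs(cs);
  GateTable tab; tab.build(dt);
  ExpTable et; et.build();

  const double i_max = as<double>(otp["i_max"]);
  const double k_half = as<double>(otp["k_half"]);
  const double gamma_adapt = as<double>(otp["gamma_adapt"]);
  const double tau_act = as<double>(otp["tau_act"]);
  const double tau_adapt = as<double>(otp["tau_adapt"]);
  const double f_act = std::exp(-dt / tau_act);
  const double f_adapt = std::exp(-dt / tau_adapt);

  std::vector<CSState> st(n_neurons);
  for (int i = 0; i < n_neurons; ++i) st[i].init(p);
  std::vector<double> otp_x(n_neurons, 0.0), otp_v(n_neurons, 0.0),
    otp_a(n_neurons, 0.0);

  // per-edge alpha-cascade states and precomputed decay constants
  std::vector<double> eA(n_edges, 0.0), eG(n_edges, 0.0),
    eF(n_edges), eDt(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    eF[e] = std::exp(-dt / e_tau[e]);
    eDt[e] = dt / e_tau[e];
  }
  // outgoing-edge adjacency
  std::vector<std::vector<int> > out_edges(n_neurons);
  for (int e = 0; e < n_edges; ++e) out_edges[e_pre[e]].push_back(e);

  const int n_steps = (int)std::lround(duration_s * 1000.0 / dt);
  const double t_window = (duration_s - window_s) * 1000.0;

  std::vector<std::vector<double> > spikes(n_neurons);
  std::vector<double> gsum(n_neurons), gesum(n_neurons), acc(n_neurons),
    gain(n_neurons, 1.0);
  std::vector<int> spiked;

  int rec_every = record_v ? std::max(1, (int)std::lround(record_dt / dt)) : 0;
  int n_rec = record_v ? (n_steps + rec_every - 1) / rec_every : 0;
  NumericMatrix vrec;
  NumericVector trec;
  if (record_v) { vrec = NumericMatrix(n_rec, n_neurons); trec = NumericVector(n_rec); }
  int rec_i = 0;

  double ff_acc = 0.0, gain_acc = 0.0;
  long ff_n = 0;
  int n_osn = 0;
  for (int i = 0; i < n_neurons; ++i) if (class_code[i] == 0) ++n_osn;

  const int n_u = u_samples.nrow();

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    bool in_window = t >= t_window;

    // divisive terminal gains from presynaptic-modulation edges
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int e = 0; e < n_edges; ++e)
      if (e_presyn[e]) acc[e_post[e]] += e_kappa[e] * eG[e];
    for (int i = 0; i < n_neurons; ++i) gain[i] = 1.0 / (1.0 + acc[i]);

    // synaptic conductance inputs
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    double ff_now = 0.0;
    for (int e = 0; e < n_edges; ++e) {
      if (e_presyn[e]) continue;
      int pre = e_pre[e], post = e_post[e];
      double geff = eG[e];
      if (class_code[pre] == 0) geff *= gain[pre];
      gsum[post] += geff;
      gesum[post] += geff * e_erev[e];
      if (in_window && class_code[pre] == 0 && class_code[post] == 1)
        ff_now += geff;
    }
    if (in_window) {
      ff_acc += ff_now; ++ff_n;
      for (int i = 0; i < n_neurons; ++i)
        if (class_code[i] == 0) gain_acc += gain[i];
    }

    // transduction and neuron updates
    spiked.clear();
    double upos = t / u_dt_ms;
    int ui = (int)upos; if (ui > n_u - 2) ui = n_u - 2;
    double uw = upos - ui; if (uw < 0) uw = 0; if (uw > 1) uw = 1;
    for (int i = 0; i < n_neurons; ++i) {
      double I = i_ext[i];
      if (class_code[i] == 0) {
        double u = u_samples(ui, i) * (1.0 - uw) + u_samples(ui + 1, i) * uw;
        double bu = osn_b[i] * u / 1000.0;   // per ms
        double dd = osn_d[i] / 1000.0;
        double rate = bu + dd;
        double xinf = rate > 0 ? bu / rate : otp_x[i];
        double xprev = otp_x[i];
        otp_x[i] = xinf + (otp_x[i] - xinf) * et.neg(rate * dt);
        otp_v[i] = xprev + (otp_v[i] - xprev) * f_act;
        double ainf = gamma_adapt * xprev;
        otp_a[i] = ainf + (otp_a[i] - ainf) * f_adapt;
        I += i_max * otp_v[i] / (otp_v[i] + k_half * (1.0 + otp_a[i]));
      }
      if (cs_step(st[i], p, tab, et, dt, t, I, gsum[i], gesum[i]))
        spiked.push_back(i);
      if (!R_finite(st[i].V) || std::fabs(st[i].V) > 500.0)
        stop("integration blow-up in neuron %d at t = %.3f ms", i + 1, t);
    }

    // record, decay synapses, deliver this step's spikes
    if (record_v && k % rec_every == 0) {
      for (int i = 0; i < n_neurons; ++i) vrec(rec_i, i) = st[i].V;
      trec[rec_i] = t; ++rec_i;
    }
    for (int e = 0; e < n_edges; ++e) {
      eG[e] = eF[e] * (eG[e] + eA[e] * eDt[e]);
      eA[e] *= eF[e];
    }
    for (size_t si = 0; si < spiked.size(); ++si) {
      int i = spiked[si];
      spikes[i].push_back(t);
      const std::vector<int>& oe = out_edges[i];
      for (size_t j = 0; j < oe.size(); ++j)
        eA[oe[j]] += e_gbar[oe[j]] * M_E;
    }
  }

  List sp(n_neurons);
  for (int i = 0; i < n_neurons; ++i) sp[i] = wrap(spikes[i]);
  List out = List::create(
    _["spikes_ms"] = sp,
    _["ff_conductance_mean"] = ff_n > 0 ? ff_acc / ff_n : 0.0,
    _["osn_gain_mean"] = (ff_n > 0 && n_osn > 0) ?
      gain_acc / ((double)ff_n * n_osn) : 1.0);
  if (record_v) {
    out["v"] = vrec;
    out["v_t_ms"] = trec;
  }
  return out;
}
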