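#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step exponential-Euler integrator for a single-compartment
// conductance-based neuron.  All channel kinetics arrive as flat numeric
// matrices built by the R side (see build_core_params in R/neuron.R), so the
// same core serves every preset.
//
// Units: mV, ms, nS, pF, pA, uM.  nS * mV = pA; pA / pF = mV/ms.
//
// gate matrix columns (one row per voltage gate):
//   0 chan (0-based channel index)
//   1 exponent
//   2 vhalf (mV)
//   3 slope (mV; sign encodes activation vs inactivation)
//   4 tau_type: 0 constant, 1 bell (cosh), 2 sigmoid
//   5-8 tau params tp1..tp4
//   9 ca_shift (mV of vhalf shift per decade of [Ca] above 0.1 uM; BK)
//
// chan matrix columns (one row per channel):
//   0 gbar (nS), 1 erev (mV), 2 carries_ca (0/1), 3 ca_mode (0 none, 1 Hill),
//   4 ca_kd (uM), 5 ca_hill
//
// syn_params columns (one row per receptor class):
//   0 tau_rise (ms), 1 tau_decay (ms), 2 erev (mV), 3 mg_block (0/1)
// syn_events columns: 0 time (ms), 1 class (0-based), 2 peak amplitude (nS,
//   short-term depression already applied), sorted by time.

static inline double gate_inf(double v, double vhalf, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / slope));
}

static inline double gate_tau(double v, int type, double p1, double p2,
                              double p3, double p4) {
  switch (type) {
  case 0: return p1;
  case 1: return p1 + p2 / std::cosh((v - p3) / p4);
  default: return p1 + p2 / (1.0 + std::exp((v - p3) / p4));
  }
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericMatrix gates, NumericMatrix chans,
                   double capacitance, double g_leak, double e_leak,
                   NumericVector ca_pool,  // influx_scale, decay_tau, floor
                   double bias_pa,
                   double inj_amp, double inj_on, double inj_off,
                   NumericMatrix syn_params, NumericMatrix syn_events,
                   double dt, double total_ms,
                   double v0, NumericVector gate0, double ca0,
                   bool record_v) {
  const int n_gate = gates.nrow();
  const int n_chan = chans.nrow();
  const int n_syn = syn_params.nrow();
  const int n_ev = syn_events.nrow();
  const int n_step = (int)std::round(total_ms / dt);

  const double ca_scale = ca_pool[0], ca_tau = ca_pool[1], ca_floor = ca_pool[2];
  const double ca_decay = (ca_tau > 0) ? std::exp(-dt / ca_tau) : 0.0;

  std::vector<double> g(n_gate);
  if (gate0.size() == n_gate) {
    for (int i = 0; i < n_gate; ++i) g[i] = gate0[i];
  } else {
    for (int i = 0; i < n_gate; ++i)
      g[i] = gate_inf(v0, gates(i, 2), gates(i, 3));
  }
  double v = v0, ca = (ca0 > 0) ? ca0 : ca_floor;

  // dual-exponential synaptic accumulators per receptor class
  std::vector<double> a_r(n_syn, 0.0), a_d(n_syn, 0.0);
  std::vector<double> dec_r(n_syn), dec_d(n_syn), norm(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    double tr = syn_params(s, 0), td = syn_params(s, 1);
    dec_r[s] = std::exp(-dt / tr);
    dec_d[s] = std::exp(-dt / td);
    double tpk = (tr * td / (td - tr)) * std::log(td / tr);
    norm[s] = 1.0 / (std::exp(-tpk / td) - std::exp(-tpk / tr));
  }

  NumericVector vtr(record_v ? (n_step + 1) : 1);
  if (record_v) vtr[0] = v;

  int ev = 0;
  for (int k = 0; k < n_step; ++k) {
    double t = k * dt;
    // deliver synaptic events that occur in [t, t+dt)
    while (ev < n_ev && syn_events(ev, 0) < t + dt) {
      int cls = (int)syn_events(ev, 1);
      a_r[cls] += syn_events(ev, 2);
      a_d[cls] += syn_events(ev, 2);
      ++ev;
    }

    // gate update from current voltage (exponential Euler; stays in [0,1])
    for (int i = 0; i < n_gate; ++i) {
      double vh = gates(i, 2);
      double shift = gates(i, 9);
      if (shift != 0.0) vh -= shift * std::log10(ca / 0.1);
      double xinf = gate_inf(v, vh, gates(i, 3));
      double tau = gate_tau(v, (int)gates(i, 4), gates(i, 5), gates(i, 6),
                            gates(i, 7), gates(i, 8));
      g[i] = xinf + (g[i] - xinf) * std::exp(-dt / tau);
    }

    // per-channel effective conductances
    double g_tot = g_leak, ge_tot = g_leak * e_leak;
    double i_ca = 0.0;  // pA, Ca-carrying channels only
    for (int c = 0; c < n_chan; ++c) {
      double open = 1.0;
      for (int i = 0; i < n_gate; ++i) {
        if ((int)gates(i, 0) == c) {
          double x = g[i];
          int p = (int)gates(i, 1);
          for (int q = 0; q < p; ++q) open *= x;
        }
      }
      if ((int)chans(c, 3) == 1) {  // Hill function of [Ca]
        double r = std::pow(ca / chans(c, 4), chans(c, 5));
        open *= r / (1.0 + r);
      }
      double gc = chans(c, 0) * open;
      g_tot += gc;
      ge_tot += gc * chans(c, 1);
      if ((int)chans(c, 2) == 1) i_ca += gc * (v - chans(c, 1));
    }

    // synaptic conductances
    double block = 1.0 / (1.0 + (1.0 / 3.57) * std::exp(-0.062 * v));
    for (int s = 0; s < n_syn; ++s) {
      a_r[s] *= dec_r[s];
      a_d[s] *= dec_d[s];
      double gs = norm[s] * (a_d[s] - a_r[s]);
      if (gs < 0) gs = 0;
      if ((int)syn_params(s, 3) == 1) gs *= block;
      g_tot += gs;
      ge_tot += gs * syn_params(s, 2);
    }

    double i_const = bias_pa;
    if (t >= inj_on && t < inj_off) i_const += inj_amp;

    double vinf = (ge_tot + i_const) / g_tot;
    v = vinf + (v - vinf) * std::exp(-dt * g_tot / capacitance);
    if (!std::isfinite(v) || std::fabs(v) > 200.0)
      stop("membrane integration blew up (|V| > 200 mV) at t = %f ms; "
           "check channel conductances", t);

    // calcium pool: exponential relaxation toward floor + influx (|I_Ca| in nA)
    ca = ca_floor + (ca - ca_floor) * ca_decay +
         ca_scale * std::fabs(i_ca) * 1e-3 * dt;
    if (ca < ca_floor) ca = ca_floor;

    if (record_v) vtr[k + 1] = v;
  }

  if (!record_v) vtr[0] = v;
  return List::create(_["v"] = vtr, _["v_final"] = v,
                      _["gates_final"] = NumericVector(g.begin(), g.end()),
                      _["ca_final"] = ca);
}
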