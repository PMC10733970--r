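// Branched-cable integrator with declarative channel kinetics.
//
// Units: v mV, t ms, conductances per compartment in uS, currents in nA,
// capacitance in nF, channel densities S/cm2, calcium mM.
//
// Scheme: staggered operator splitting. Gates advance by the exponential
// update rule at the current voltage; the voltage step solves the
// tree-structured linear system (theta = 0.5 Crank-Nicolson by default,
// theta = 1 implicit Euler) by Hines elimination. Compartments must be
// ordered so that parent index < child index (the R assembler guarantees
// this), which makes one reverse sweep + one forward sweep exact.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double V_TAB_LO = -150.0, V_TAB_HI = 60.0, V_TAB_STEP = 0.05;
const int V_TAB_N = (int)((V_TAB_HI - V_TAB_LO) / V_TAB_STEP) + 1;

struct GateKin {
  int form;            // 0 bg, 1 alpha_beta, 2 inf_tau, 3 calcium_hill
  int power;
  std::vector<double> pars;
  std::vector<double> tab_inf, tab_dec; // voltage tables for forms 0..2

  void eval_direct(double v, double ca, double &inf, double &tau) const {
    switch (form) {
    case 0: { // vhalf_l, vhalf_t, a0t, zeta_l, zeta_t, gmt, tf, kT
      double vl = pars[0], vt = pars[1], a0 = pars[2], zl = pars[3],
             zt = pars[4], gm = pars[5], tf = pars[6], kT = pars[7];
      inf = 1.0 / (1.0 + std::exp(kT * zl * (v - vl)));
      tau = std::exp(kT * zt * gm * (v - vt)) /
            (tf * a0 * (1.0 + std::exp(kT * zt * (v - vt))));
      break;
    }
    case 1: { // a_form,a_rate,a_vhalf,a_slope, b_form,..., tau_min
      double al = rate(pars[0], pars[1], pars[2], pars[3], v);
      double be = rate(pars[4], pars[5], pars[6], pars[7], v);
      double tmin = pars.size() > 8 ? pars[8] : 0.0;
      inf = al / (al + be);
      tau = 1.0 / (al + be);
      if (tau < tmin) tau = tmin;
      break;
    }
    case 2: { // vhalf, slope, tau_min, tau_amp, tau_vhalf, tau_slope
      inf = 1.0 / (1.0 + std::exp((v - pars[0]) / pars[1]));
      tau = pars[2] + pars[3] / (std::exp((v - pars[4]) / pars[5]) +
                                 std::exp(-(v - pars[4]) / pars[5]));
      break;
    }
    default: { // n, khalf_mM, tau_ms, [vslope, vref]
      double kh = pars[1];
      if (pars.size() > 3 && pars[3] != 0.0) {
        double vref = pars.size() > 4 ? pars[4] : -20.0;
        kh *= std::exp(-(v - vref) / pars[3]);
      }
      double can = std::pow(ca > 0 ? ca : 0.0, pars[0]);
      double khn = std::pow(kh, pars[0]);
      inf = can / (can + khn);
      tau = pars[2];
    }
    }
  }

  static double rate(double form, double a, double vh, double k, double v) {
    if (form == 1.0) return a * std::exp((v - vh) / k);
    if (form == 2.0) return a / (1.0 + std::exp(-(v - vh) / k));
    double x = (v - vh) / k; // linoid
    if (std::fabs(x) < 1e-6) return a * k * (1.0 - x / 2.0);
    return a * (v - vh) / (1.0 - std::exp(-x));
  }

  void build_table(double dt) {
    if (form == 3) return;
    tab_inf.resize(V_TAB_N);
    tab_dec.resize(V_TAB_N); // exp(-dt/tau) pre-tabulated for the run's dt
    for (int i = 0; i < V_TAB_N; ++i) {
      double v = V_TAB_LO + i * V_TAB_STEP, inf, tau;
      eval_direct(v, 0.0, inf, tau);
      tab_inf[i] = inf;
      tab_dec[i] = std::exp(-dt / tau);
    }
  }

  // exponential-update coefficients: x <- inf + (x - inf) * dec
  inline void coeffs(double v, double ca, double dt, double &inf,
                     double &dec) const {
    if (form == 3) {
      double tau;
      eval_direct(v, ca, inf, tau);
      dec = std::exp(-dt / tau);
      return;
    }
    if (v <= V_TAB_LO) { inf = tab_inf[0]; dec = tab_dec[0]; return; }
    if (v >= V_TAB_HI) { inf = tab_inf[V_TAB_N-1]; dec = tab_dec[V_TAB_N-1]; return; }
    double x = (v - V_TAB_LO) / V_TAB_STEP;
    int i = (int)x;
    double f = x - i;
    inf = tab_inf[i] * (1 - f) + tab_inf[i + 1] * f;
    dec = tab_dec[i] * (1 - f) + tab_dec[i + 1] * f;
  }
};

struct Channel {
  std::vector<GateKin> gates;
  std::vector<double> density; // S/cm2 per compartment
  double erev;
  double ca_flux;
};

struct StepStim { int comp; double amp, t0, t1; };

struct Synapse {
  int comp;
  double tau_r, tau_d, g_uS, erev, factor;
  std::vector<double> times;
  size_t next_ev;
  double A, B; // rise / decay states
};

struct Model {
  int n;
  std::vector<int> parent;           // -1 for root
  std::vector<double> area, cap_nF, g_ax; // uS to parent
  std::vector<double> g_pas, e_pas;  // S/cm2, mV
  std::vector<Channel> chans;
  bool has_ca;
  double ca_tau, ca_rest, ca_gain;
  std::vector<int> gate_offset_chan; // offset of channel c's gates per comp
  int gates_per_comp;
};

Model build_model(const List &ml, double dt) {
  Model m;
  IntegerVector parent = ml["parent"];
  NumericVector area = ml["area_cm2"], cm = ml["cm_uF"], gax = ml["g_axial_uS"];
  NumericVector gpas = ml["g_pas"], epas = ml["e_pas"];
  m.n = parent.size();
  m.parent.assign(parent.begin(), parent.end());
  for (int i = 0; i < m.n; ++i) m.parent[i] -= 1; // R 1-based, root 0 -> -1
  m.area.assign(area.begin(), area.end());
  m.cap_nF.resize(m.n);
  for (int i = 0; i < m.n; ++i) m.cap_nF[i] = cm[i] * m.area[i] * 1e3;
  m.g_ax.assign(gax.begin(), gax.end());
  m.g_pas.assign(gpas.begin(), gpas.end());
  m.e_pas.assign(epas.begin(), epas.end());

  List chans = ml["channels"];
  m.gates_per_comp = 0;
  for (int c = 0; c < chans.size(); ++c) {
    List cl = chans[c];
    Channel ch;
    ch.erev = as<double>(cl["reversal"]);
    ch.ca_flux = as<double>(cl["ca_flux"]);
    NumericVector dens = cl["density"];
    ch.density.assign(dens.begin(), dens.end());
    List gl = cl["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List gg = gl[g];
      GateKin gk;
      gk.form = as<int>(gg["form"]);
      gk.power = as<int>(gg["power"]);
      NumericVector pars = gg["params"];
      gk.pars.assign(pars.begin(), pars.end());
      gk.build_table(dt);
      ch.gates.push_back(gk);
    }
    m.gate_offset_chan.push_back(m.gates_per_comp);
    m.gates_per_comp += (int)ch.gates.size();
    m.chans.push_back(ch);
  }

  List cap = ml["ca_pool"];
  m.has_ca = as<bool>(cap["present"]);
  m.ca_tau = as<double>(cap["decay_tau"]);
  m.ca_rest = as<double>(cap["rest"]);
  m.ca_gain = as<double>(cap["gain"]);
  return m;
}

struct State {
  std::vector<double> v, ca, gates; // gates: comp-major [comp*gpc + idx]
};

void init_state(const Model &m, State &s, double v0) {
  s.v.assign(m.n, v0);
  s.ca.assign(m.n, m.ca_rest);
  s.gates.assign((size_t)m.n * m.gates_per_comp, 0.0);
  for (int i = 0; i < m.n; ++i)
    for (size_t c = 0; c < m.chans.size(); ++c) {
      const Channel &ch = m.chans[c];
      for (size_t g = 0; g < ch.gates.size(); ++g) {
        double inf, tau;
        ch.gates[g].eval_direct(v0, m.ca_rest, inf, tau);
        s.gates[(size_t)i * m.gates_per_comp + m.gate_offset_chan[c] + g] = inf;
      }
    }
}

class Engine {
public:
  Model m;
  State s;
  std::vector<StepStim> stims;
  std::vector<Synapse> syns;
  double dt, theta;
  // scratch
  std::vector<double> diag, rhs, offd;

  void step(double t) {
    const int n = m.n;
    const int gpc = m.gates_per_comp;
    diag.assign(n, 0.0);
    rhs.assign(n, 0.0);

    // synapse state advance over [t, t+dt]; exact exponential decay with
    // event insertion at spike times
    for (auto &sy : syns) {
      double tcur = t;
      while (sy.next_ev < sy.times.size() && sy.times[sy.next_ev] < t + dt) {
        double te = sy.times[sy.next_ev];
        double d = te - tcur;
        if (d > 0) {
          sy.A *= std::exp(-d / sy.tau_r);
          sy.B *= std::exp(-d / sy.tau_d);
          tcur = te;
        }
        sy.A += sy.factor;
        sy.B += sy.factor;
        ++sy.next_ev;
      }
      double d = t + dt - tcur;
      sy.A *= std::exp(-d / sy.tau_r);
      sy.B *= std::exp(-d / sy.tau_d);
      double g = sy.g_uS * (sy.B - sy.A); // uS at end of step
      diag[sy.comp] += g;
      rhs[sy.comp] += g * sy.erev;
    }

    // gate advance (exponential update at current v) and membrane currents
    for (int i = 0; i < n; ++i) {
      double v = s.v[i], ca = s.ca[i];
      double gtot_uS = 0.0, ge_sum = 0.0; // sum g, sum g*E
      double *gv = &s.gates[(size_t)i * gpc];
      double ica_dens = 0.0;
      for (size_t c = 0; c < m.chans.size(); ++c) {
        const Channel &ch = m.chans[c];
        double dens = ch.density[i];
        if (dens <= 0.0) continue; // unused gates stay at their init value
        double open = 1.0;
        int off = m.gate_offset_chan[c];
        for (size_t g = 0; g < ch.gates.size(); ++g) {
          const GateKin &gk = ch.gates[g];
          double inf, dec;
          gk.coeffs(v, ca, dt, inf, dec);
          double x = inf + (gv[off + g] - inf) * dec;
          gv[off + g] = x;
          for (int p = 0; p < gk.power; ++p) open *= x;
        }
        double g_uS = dens * open * m.area[i] * 1e6;
        gtot_uS += g_uS;
        ge_sum += g_uS * ch.erev;
        if (ch.ca_flux > 0.0)
          ica_dens += ch.ca_flux * dens * open * (v - ch.erev);
      }
      double gp = m.g_pas[i] * m.area[i] * 1e6;
      gtot_uS += gp;
      ge_sum += gp * m.e_pas[i];
      diag[i] += gtot_uS;
      rhs[i] += ge_sum;
      // calcium pool update (uses pre-step voltage current estimate)
      if (m.has_ca) {
        double ca_inf = m.ca_rest - m.ca_gain * m.ca_tau * ica_dens;
        s.ca[i] = ca_inf + (s.ca[i] - ca_inf) * std::exp(-dt / m.ca_tau);
        if (s.ca[i] < 0) s.ca[i] = 0;
      }
    }

    // injected step currents, evaluated at t + theta*dt
    double ts = t + theta * dt;
    for (const auto &st : stims)
      if (ts >= st.t0 && ts < st.t1) rhs[st.comp] += st.amp;

    // assemble theta system:  (C/dt + theta*G) v_new = ...
    // membrane: I = -G*(v_theta - Eeff) with G=diag (membrane part),
    // Eeff*G = rhs; axial handled below.
    std::vector<double> A(n), b(n);
    offd.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      double cdt = m.cap_nF[i] / dt;
      A[i] = cdt + theta * diag[i];
      b[i] = cdt * s.v[i] + rhs[i] - (1.0 - theta) * diag[i] * s.v[i];
    }
    for (int i = 1; i < n; ++i) {
      int p = m.parent[i];
      if (p < 0) continue;
      double ga = m.g_ax[i];
      A[i] += theta * ga;
      A[p] += theta * ga;
      offd[i] = -theta * ga;
      double iax = ga * (s.v[p] - s.v[i]) * (1.0 - theta);
      b[i] += iax;
      b[p] -= iax;
    }
    // Hines elimination: children (higher index) into parents
    for (int i = n - 1; i >= 1; --i) {
      int p = m.parent[i];
      if (p < 0) continue;
      double f = offd[i] / A[i];
      A[p] -= f * offd[i];
      b[p] -= f * b[i];
    }
    s.v[0] = b[0] / A[0];
    for (int i = 1; i < n; ++i) {
      int p = m.parent[i];
      s.v[i] = (b[i] - offd[i] * s.v[p]) / A[i];
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cable_run")]]
List cable_run(List model, List config) {
  Engine e;
  e.dt = as<double>(config["dt"]);
  e.m = build_model(model, e.dt);
  e.theta = as<double>(config["theta"]);
  double t_stop = as<double>(config["t_stop"]);
  double v_init = as<double>(config["v_init"]);
  double settle = as<double>(config["settle_ms"]);
  IntegerVector rec = config["record_comps"]; // 1-based

  List stl = model["stimuli"];
  for (int i = 0; i < stl.size(); ++i) {
    List s = stl[i];
    StepStim st;
    st.comp = as<int>(s["comp"]) - 1;
    st.amp = as<double>(s["amp_nA"]);
    st.t0 = as<double>(s["delay"]);
    st.t1 = st.t0 + as<double>(s["duration"]);
    e.stims.push_back(st);
  }
  List syl = model["synapses"];
  for (int i = 0; i < syl.size(); ++i) {
    List s = syl[i];
    Synapse sy;
    sy.comp = as<int>(s["comp"]) - 1;
    sy.tau_r = as<double>(s["tau_rise"]);
    sy.tau_d = as<double>(s["tau_decay"]);
    sy.g_uS = as<double>(s["weight_nS"]) * 1e-3;
    sy.erev = as<double>(s["reversal"]);
    NumericVector tt = s["times"];
    sy.times.assign(tt.begin(), tt.end());
    std::sort(sy.times.begin(), sy.times.end());
    sy.next_ev = 0;
    sy.A = sy.B = 0.0;
    // peak normalization: single event of weight w reaches peak g = w
    double tp = (sy.tau_r * sy.tau_d) / (sy.tau_d - sy.tau_r) *
                std::log(sy.tau_d / sy.tau_r);
    sy.factor = 1.0 / (std::exp(-tp / sy.tau_d) - std::exp(-tp / sy.tau_r));
    e.syns.push_back(sy);
  }

  init_state(e.m, e.s, v_init);

  int n_settle = settle > 0 ? (int)std::ceil(settle / e.dt) : 0;
  for (int k = 0; k < n_settle; ++k) e.step(-settle + k * e.dt);
  // settling runs with stimuli/synapses gated by t<0 (no events before 0)

  int nt = (int)std::floor(t_stop / e.dt + 0.5) + 1;
  NumericMatrix vout(nt, rec.size());
  NumericVector tout(nt);
  for (int j = 0; j < rec.size(); ++j) vout(0, j) = e.s.v[rec[j] - 1];
  tout[0] = 0.0;
  for (int k = 1; k < nt; ++k) {
    e.step((k - 1) * e.dt);
    double t = k * e.dt;
    tout[k] = t;
    for (int j = 0; j < rec.size(); ++j) {
      double v = e.s.v[rec[j] - 1];
      if (!std::isfinite(v) || std::fabs(v) > 1e3)
        stop("numerical instability at t = %f ms (compartment %d)", t, rec[j]);
      vout(k, j) = v;
    }
  }

  return List::create(_["t"] = tout, _["v"] = vout,
                      _["v_final"] = NumericVector(e.s.v.begin(), e.s.v.end()),
                      _["ca_final"] = NumericVector(e.s.ca.begin(), e.s.ca.end()));
}
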