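// Semi-implicit cable-equation integrator on a compartment tree.
//
// Voltage is advanced by backward Euler on the tree (direct Hines solve);
// Hodgkin-Huxley gates and calcium pools are advanced by exact exponential
// updates between voltage solves (operator splitting). Linear membrane
// currents (passive leak, HH mechanisms, AMPA, the nonspecific NMDA
// component) are treated implicitly in V; Goldman-Hodgkin-Katz calcium
// currents are explicit current sources (they are small).
//
// Units: mV, ms, uS, nA, nF, mM, um. Spine conductances arrive in pS and
// are converted here once (1 pS = 1e-6 uS); spine currents are tracked in
// pA for the calcium balance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.332;   // C/mol
static const double GASCONST = 8.314462;   // J/(mol K)

struct GateDef {
  double power, vhalf, k;
  int tau_type;                 // 0 = constant, 1 = bell
  double tp[5];                 // const: tp[0]; bell: min, amp, vpeak, k1, k2
  double tscale;                // Q10 factor applied to tau
  double inf(double v) const { return 1.0 / (1.0 + std::exp(-(v - vhalf) / k)); }
  double tau(double v) const {
    if (tau_type == 0) return tscale * tp[0];
    return tscale * (tp[0] + tp[1] / (std::exp((v - tp[2]) / tp[3]) +
                                      std::exp(-(v - tp[2]) / tp[4])));
  }
};

struct MechDef {
  double erev;
  bool is_ca;
  std::vector<GateDef> gates;
  std::vector<double> gbar;     // uS per compartment
  std::vector<int> active;      // compartments with gbar > 0
  std::vector<int> powi;        // integer gate exponents
};

// integer power by repeated multiplication (gate exponents are small ints)
static inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

// effective GHK driving force in mV, normalized to the slope conductance
// at large negative V; vt2 = RT/(2F) in mV
static inline double ghk_vca(double v, double cai, double cae, double vt2) {
  double xi = v / vt2;
  double r = cai / cae;
  if (std::fabs(xi) < 1e-4) return vt2 * (r - 1.0) + v * (r + 1.0) / 2.0;
  double ex = std::exp(xi);
  return v * (r * ex - 1.0) / (ex - 1.0);
}

// peak-normalized dual-exponential conductance time course
static inline double dexp_g(double t, double taur, double taud, double norm) {
  if (t <= 0) return 0.0;
  return norm * (std::exp(-t / taud) - std::exp(-t / taur));
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List model, List stim, List control) {
  // ---- topology & passive ----
  IntegerVector parent = model["parent"];          // 0-based, -1 root
  NumericVector g_ax = model["g_axial_uS"];
  NumericVector cm = model["cm_nF"];
  NumericVector g_pas = model["g_pas_uS"];
  NumericVector e_pas = model["e_pas_mV"];
  const int n = parent.size();
  const double temp_K = as<double>(model["temp_K"]);
  const double vt = 1e3 * GASCONST * temp_K / FARADAY;   // RT/F, mV
  const double vt2 = vt / 2.0;

  // ---- backbone mechanisms ----
  List mechs = model["mechanisms"];
  const int nmech = mechs.size();
  std::vector<MechDef> M(nmech);
  for (int m = 0; m < nmech; ++m) {
    List mm = mechs[m];
    M[m].erev = as<double>(mm["erev_mV"]);
    M[m].is_ca = as<bool>(mm["is_calcium"]);
    NumericVector gb = mm["gbar_uS"];
    M[m].gbar.assign(gb.begin(), gb.end());
    List gl = mm["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List gg = gl[g];
      GateDef gd;
      gd.power = as<double>(gg["power"]);
      gd.vhalf = as<double>(gg["inf_vhalf"]);
      gd.k = as<double>(gg["inf_k"]);
      gd.tau_type = as<int>(gg["tau_type"]);
      NumericVector tp = gg["tau"];
      for (int i = 0; i < 5; ++i) gd.tp[i] = (i < tp.size()) ? tp[i] : 0.0;
      gd.tscale = as<double>(gg["tau_scale"]);
      M[m].gates.push_back(gd);
      M[m].powi.push_back((int)std::lround(gd.power));
    }
    for (int i = 0; i < (int)M[m].gbar.size(); ++i)
      if (M[m].gbar[i] > 0) M[m].active.push_back(i);
  }

  // ---- shaft calcium pools ----
  List shaft = model["shaft_ca"];
  bool shaft_on = as<bool>(shaft["enabled"]);
  NumericVector shaft_vol;                 // um^3 per compartment (shell)
  double sh_kappa = 20, sh_tau = 20, sh_ca0 = 7e-5, ca_e = 2.0;
  if (shaft_on) {
    shaft_vol = as<NumericVector>(shaft["vol_um3"]);
    sh_kappa = as<double>(shaft["kappa"]);
    sh_tau = as<double>(shaft["tau_ms"]);
    sh_ca0 = as<double>(shaft["ca0_mM"]);
  }
  ca_e = as<double>(model["ca_e_mM"]);

  // ---- spines ----
  List sp = model["spines"];
  IntegerVector head_comp = sp["head_comp"];       // 0-based
  NumericVector g_ampa_pS = sp["g_ampa_pS"];
  NumericVector g_nmda_pS = sp["g_nmda_pS"];
  NumericVector g_car_pS = sp["g_car_pS"];
  NumericVector act_time = sp["act_time"];         // ms, < 0 inactive
  const int nsp = head_comp.size();
  List nm = sp["nmda"];
  const double n_tau1 = as<double>(nm["tau1"]), n_tau2 = as<double>(nm["tau2"]),
               n_tau3 = as<double>(nm["tau3"]), n_a = as<double>(nm["a"]),
               n_norm = as<double>(nm["norm"]), n_erev = as<double>(nm["e_rev_mV"]),
               n_mg_ratio = as<double>(nm["mg_ratio"]),   // [Mg]/K0
               n_mg_slope = as<double>(nm["mg_slope"]),   // per mV
               n_ca_perm = as<double>(nm["ca_perm_ratio"]);
  List am = sp["ampa"];
  const double a_taur = as<double>(am["tau_rise_ms"]),
               a_taud = as<double>(am["tau_decay_ms"]),
               a_norm = as<double>(am["norm"]), a_erev = as<double>(am["e_rev_mV"]),
               a_caf = as<double>(am["ca_fraction"]);
  List rt = sp["rtype"];
  GateDef rm_g, rh_g;
  {
    List gl = rt["gates"];
    List g0 = gl[0], g1 = gl[1];
    rm_g.power = as<double>(g0["power"]); rm_g.vhalf = as<double>(g0["inf_vhalf"]);
    rm_g.k = as<double>(g0["inf_k"]); rm_g.tau_type = as<int>(g0["tau_type"]);
    NumericVector t0 = g0["tau"]; for (int i = 0; i < 5; ++i) rm_g.tp[i] = (i < t0.size()) ? t0[i] : 0;
    rm_g.tscale = as<double>(g0["tau_scale"]);
    rh_g.power = as<double>(g1["power"]); rh_g.vhalf = as<double>(g1["inf_vhalf"]);
    rh_g.k = as<double>(g1["inf_k"]); rh_g.tau_type = as<int>(g1["tau_type"]);
    NumericVector t1 = g1["tau"]; for (int i = 0; i < 5; ++i) rh_g.tp[i] = (i < t1.size()) ? t1[i] : 0;
    rh_g.tscale = as<double>(g1["tau_scale"]);
  }
  List spca = sp["calcium"];
  const double sp_ca0 = as<double>(spca["ca0_mM"]),
               sp_tau = as<double>(spca["tau_ca_ms"]),
               sp_kappa = as<double>(spca["kappa"]);
  NumericVector head_vol = sp["head_vol_um3"];

  // ---- stimulation ----
  NumericVector ic_comp_r = stim["iclamp_comp"];   // 1-based from R
  NumericVector ic_amp = stim["iclamp_amp_nA"];
  NumericVector ic_on = stim["iclamp_onset_ms"];
  NumericVector ic_dur = stim["iclamp_dur_ms"];

  // ---- control ----
  const double dt = as<double>(control["dt_ms"]);
  const double duration = as<double>(control["duration_ms"]);
  const double v_init = as<double>(control["v_init_mV"]);
  const double rec_dt = as<double>(control["record_dt_ms"]);
  IntegerVector rec_comp = control["record_comp"];     // 1-based
  const bool rec_spines = as<bool>(control["record_spines"]);
  const int soma_comp = as<int>(control["soma_comp"]) - 1;
  const double ap_thresh = as<double>(control["ap_threshold_mV"]);

  const int nsteps = (int)std::ceil(duration / dt);
  const int rec_every = std::max(1, (int)std::round(rec_dt / dt));
  const int nrec = nsteps / rec_every + 1;

  // ---- state (fresh from v_init, or warm-started from a rest state) ----
  std::vector<double> V(n, v_init);
  std::vector<std::vector<std::vector<double>>> gate(nmech);
  for (int m = 0; m < nmech; ++m) {
    gate[m].resize(M[m].gates.size());
    for (size_t g = 0; g < M[m].gates.size(); ++g)
      gate[m][g].assign(n, M[m].gates[g].inf(v_init));
  }
  std::vector<double> shaft_ca(n, sh_ca0);
  std::vector<double> sp_m(nsp), sp_h(nsp), sp_ca(nsp, sp_ca0);
  for (int s = 0; s < nsp; ++s) {
    sp_m[s] = rm_g.inf(v_init);
    sp_h[s] = rh_g.inf(v_init);
  }
  if (control.containsElementNamed("init_state") &&
      !Rf_isNull(control["init_state"])) {
    List ist = control["init_state"];
    NumericVector v0 = ist["v"];
    for (int i = 0; i < n; ++i) V[i] = v0[i];
    List g0 = ist["gates"];
    for (int m = 0; m < nmech; ++m) {
      List gm = g0[m];
      for (size_t g = 0; g < M[m].gates.size(); ++g) {
        NumericVector st = gm[g];
        for (int i = 0; i < n; ++i) gate[m][g][i] = st[i];
      }
    }
    NumericVector sc = ist["shaft_ca"];
    for (int i = 0; i < n; ++i) shaft_ca[i] = sc[i];
    if (nsp > 0) {
      NumericVector im = ist["sp_m"], ih = ist["sp_h"], ic = ist["sp_ca"];
      for (int s = 0; s < nsp; ++s) {
        sp_m[s] = im[s]; sp_h[s] = ih[s]; sp_ca[s] = ic[s];
      }
    }
  }

  // recordings
  NumericVector t_rec(nrec);
  NumericMatrix v_rec(nrec, rec_comp.size());
  NumericMatrix shaft_ca_rec(shaft_on ? nrec : 0,
                             shaft_on ? rec_comp.size() : 0);
  NumericMatrix spv_rec(rec_spines ? nrec : 0, rec_spines ? nsp : 0);
  NumericMatrix spca_rec(rec_spines ? nrec : 0, rec_spines ? nsp : 0);
  NumericVector soma_rec(nrec);
  // per-spine running extrema (full temporal resolution)
  NumericVector sp_peak_v(nsp, -1e30), sp_peak_ca(nsp, 0.0);
  NumericVector sp_tpeak_v(nsp, 0.0), sp_tpeak_ca(nsp, 0.0);
  NumericVector comp_peak_v(n, -1e30), comp_peak_ca(n, 0.0);
  double soma_max = -1e30, ap_time = -1.0;
  bool ap_detected = false;

  // children counts for diagonal assembly are implicit via elimination
  std::vector<double> d(n), off(n), rhs(n);

  int rec_i = 0;
  auto record = [&](double tnow) {
    t_rec[rec_i] = tnow;
    for (int j = 0; j < rec_comp.size(); ++j) {
      v_rec(rec_i, j) = V[rec_comp[j] - 1];
      if (shaft_on) shaft_ca_rec(rec_i, j) = shaft_ca[rec_comp[j] - 1];
    }
    if (rec_spines)
      for (int s = 0; s < nsp; ++s) {
        spv_rec(rec_i, s) = V[head_comp[s]];
        spca_rec(rec_i, s) = sp_ca[s];
      }
    soma_rec[rec_i] = V[soma_comp];
    ++rec_i;
  };
  record(0.0);

  std::vector<double> ica_shaft(n);      // nA, outward positive
  std::vector<double> sp_ica_pA(nsp, 0.0);
  const int rm_pow = (int)std::lround(rm_g.power);
  const int rh_pow = (int)std::lround(rh_g.power);
  double prev_soma = V[soma_comp];

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;        // state time before this step
    double tn = t + dt;

    // 1. gate updates (exponential, using V at time t)
    for (int m = 0; m < nmech; ++m) {
      for (size_t g = 0; g < M[m].gates.size(); ++g) {
        const GateDef &gd = M[m].gates[g];
        std::vector<double> &st = gate[m][g];
        for (int i : M[m].active) {
          double inf = gd.inf(V[i]);
          double tau = gd.tau(V[i]);
          st[i] = inf + (st[i] - inf) * std::exp(-dt / tau);
        }
      }
    }
    for (int s = 0; s < nsp; ++s) {
      double v = V[head_comp[s]];
      double inf = rm_g.inf(v), tau = rm_g.tau(v);
      sp_m[s] = inf + (sp_m[s] - inf) * std::exp(-dt / tau);
      inf = rh_g.inf(v); tau = rh_g.tau(v);
      sp_h[s] = inf + (sp_h[s] - inf) * std::exp(-dt / tau);
    }

    // 2. assemble membrane terms
    std::fill(ica_shaft.begin(), ica_shaft.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      d[i] = cm[i] / dt + g_pas[i];
      rhs[i] = cm[i] / dt * V[i] + g_pas[i] * e_pas[i];
    }
    for (int m = 0; m < nmech; ++m) {
      const MechDef &mm = M[m];
      for (int i : mm.active) {
        double go = mm.gbar[i];
        for (size_t g = 0; g < mm.gates.size(); ++g)
          go *= ipow(gate[m][g][i], mm.powi[g]);
        if (!mm.is_ca) {
          d[i] += go;
          rhs[i] += go * mm.erev;
        } else {
          double ica = go * ghk_vca(V[i], shaft_on ? shaft_ca[i] : sh_ca0,
                                    ca_e, vt2);   // nA
          rhs[i] -= ica;
          ica_shaft[i] += ica;
        }
      }
    }

    // spine synaptic and R-type currents (head compartments)
    std::fill(sp_ica_pA.begin(), sp_ica_pA.end(), 0.0);
    for (int s = 0; s < nsp; ++s) {
      int hc = head_comp[s];
      double v = V[hc];
      // R-type (GHK, explicit)
      double grt = 1e-6 * g_car_pS[s] *
        ipow(sp_m[s], rm_pow) * ipow(sp_h[s], rh_pow); // uS
      double i_rt = grt * ghk_vca(v, sp_ca[s], ca_e, vt2);             // nA
      rhs[hc] -= i_rt;
      sp_ica_pA[s] += 1e3 * i_rt;
      double ts = act_time[s];
      if (ts >= 0 && t >= ts) {
        double tel = t - ts;
        // AMPA: linear conductance, implicit; fixed Ca fraction
        double ga = 1e-6 * g_ampa_pS[s] * dexp_g(tel, a_taur, a_taud, a_norm);
        d[hc] += ga;
        rhs[hc] += ga * a_erev;
        sp_ica_pA[s] += 1e3 * a_caf * ga * (v - a_erev);  // explicit estimate
        // NMDA: unblocked fraction at V(t); nonspecific part implicit
        double gshape = (tel <= 0) ? 0.0 :
          n_norm * (n_a * std::exp(-tel / n_tau2) +
                    (1 - n_a) * std::exp(-tel / n_tau3) -
                    std::exp(-tel / n_tau1));
        double gn = 1e-6 * g_nmda_pS[s] * gshape /
          (1.0 + n_mg_ratio * std::exp(-n_mg_slope * v));  // uS, unblocked
        d[hc] += gn;
        rhs[hc] += gn * n_erev;
        double i_nca = gn * n_ca_perm * ghk_vca(v, sp_ca[s], ca_e, vt2); // nA
        rhs[hc] -= i_nca;
        sp_ica_pA[s] += 1e3 * i_nca;
      }
    }

    // current injections
    for (int j = 0; j < ic_comp_r.size(); ++j) {
      if (t >= ic_on[j] && t < ic_on[j] + ic_dur[j])
        rhs[(int)ic_comp_r[j] - 1] += ic_amp[j];
    }

    // 3. Hines solve (parent index < child index)
    for (int i = 0; i < n; ++i) {
      off[i] = 0.0;
      int p = parent[i];
      if (p >= 0) {
        off[i] = -g_ax[i];
        d[i] += g_ax[i];
        d[p] += g_ax[i];
      }
    }
    for (int i = n - 1; i > 0; --i) {
      int p = parent[i];
      if (p < 0) continue;
      double f = off[i] / d[i];
      d[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      V[i] = (p < 0) ? rhs[i] / d[i] : (rhs[i] - off[i] * V[p]) / d[i];
    }

    // divergence check
    if (!std::isfinite(V[soma_comp]) || std::fabs(V[soma_comp]) > 500) {
      stop("numerical divergence at t = %f ms (soma compartment)", tn);
    }

    // 4. calcium updates (exponential integrator, current held over step)
    for (int s = 0; s < nsp; ++s) {
      double influx = -(sp_ica_pA[s] * 1e-12) /
        (2 * FARADAY * head_vol[s] * 1e-15 * sp_kappa);   // mM/ms
      double ca_inf = sp_ca0 + sp_tau * influx;
      sp_ca[s] = ca_inf + (sp_ca[s] - ca_inf) * std::exp(-dt / sp_tau);
      if (sp_ca[s] < 0) sp_ca[s] = 0;
      if (sp_ca[s] > sp_peak_ca[s]) { sp_peak_ca[s] = sp_ca[s]; sp_tpeak_ca[s] = tn; }
      double v = V[head_comp[s]];
      if (v > sp_peak_v[s]) { sp_peak_v[s] = v; sp_tpeak_v[s] = tn; }
    }
    if (shaft_on) {
      for (int i = 0; i < n; ++i) {
        if (shaft_vol[i] <= 0) continue;
        double influx = -(ica_shaft[i] * 1e-9) /
          (2 * FARADAY * shaft_vol[i] * 1e-15 * sh_kappa);
        double ca_inf = sh_ca0 + sh_tau * influx;
        shaft_ca[i] = ca_inf + (shaft_ca[i] - ca_inf) * std::exp(-dt / sh_tau);
        if (shaft_ca[i] < 0) shaft_ca[i] = 0;
        if (shaft_ca[i] > comp_peak_ca[i]) comp_peak_ca[i] = shaft_ca[i];
      }
    }
    for (int i = 0; i < n; ++i)
      if (V[i] > comp_peak_v[i]) comp_peak_v[i] = V[i];

    // AP detection at soma (upward threshold crossing)
    double vs = V[soma_comp];
    if (vs > soma_max) soma_max = vs;
    if (!ap_detected && prev_soma < ap_thresh && vs >= ap_thresh) {
      ap_detected = true;
      ap_time = tn;
    }
    prev_soma = vs;

    if ((step + 1) % rec_every == 0 && rec_i < nrec) record(tn);
  }

  List gates_out(nmech);
  for (int m = 0; m < nmech; ++m) {
    List gm(M[m].gates.size());
    for (size_t g = 0; g < M[m].gates.size(); ++g)
      gm[g] = NumericVector(gate[m][g].begin(), gate[m][g].end());
    gates_out[m] = gm;
  }
  List final_state = List::create(
    _["v"] = NumericVector(V.begin(), V.end()),
    _["gates"] = gates_out,
    _["shaft_ca"] = NumericVector(shaft_ca.begin(), shaft_ca.end()),
    _["sp_m"] = NumericVector(sp_m.begin(), sp_m.end()),
    _["sp_h"] = NumericVector(sp_h.begin(), sp_h.end()),
    _["sp_ca"] = NumericVector(sp_ca.begin(), sp_ca.end()));

  return List::create(
    _["t"] = t_rec[Range(0, rec_i - 1)],
    _["final_state"] = final_state,
    _["v"] = v_rec(Range(0, rec_i - 1), _),
    _["shaft_ca"] = shaft_on ? shaft_ca_rec(Range(0, rec_i - 1), _) : NumericMatrix(0),
    _["spine_v"] = rec_spines ? spv_rec(Range(0, rec_i - 1), _) : NumericMatrix(0),
    _["spine_ca"] = rec_spines ? spca_rec(Range(0, rec_i - 1), _) : NumericMatrix(0),
    _["soma_v"] = soma_rec[Range(0, rec_i - 1)],
    _["spine_peak_v"] = sp_peak_v, _["spine_tpeak_v"] = sp_tpeak_v,
    _["spine_peak_ca"] = sp_peak_ca, _["spine_tpeak_ca"] = sp_tpeak_ca,
    _["comp_peak_v"] = comp_peak_v, _["comp_peak_ca"] = comp_peak_ca,
    _["soma_peak_v"] = soma_max,
    _["ap_detected"] = ap_detected, _["ap_time_ms"] = ap_time);
}
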