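#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closed-loop four-chamber lumped circulation.
// State: 8 volumes (LV, RV, LA, RA, Ao, Pa, Ve, Pve) in mL.
// Chamber pressure (mmHg):
//   p = p_passive(V) + (1/3) T_drive(t) ln(1 + V_wall/V) + p_pericardium
// with the passive law a thin-wall sphere under equibiaxial Guccione wall
// response and the active term a one-fibre-type law in the tension drive
// (kPa). Valves are Bernoulli orifices q = A sqrt(2 dp / rho) (no
// regurgitation), tubes power-law p = p_ref (V/V_ref)^(k/3), peripheries
// linear resistors. Fixed-step RK4.

static const double KPA2MMHG = 7.50062;
static const double MMHG2PA = 133.322;
static const double RHO = 1050.0;  // kg/m^3

struct Circ {
  // chambers: 0 LV, 1 RV, 2 LA, 3 RA
  double a[4], bf[4], bt[4], V0[4], Vwall[4];
  // tubes: 0 Ao, 1 Pa, 2 Ve, 3 Pve
  double p_ref[4], V_ref[4], ktube[4];
  double A_mv, A_av, A_tv, A_pv, A_so, A_po;
  double r_sys, r_pulm;               // mmHg s / mL
  double k_peri, A_peri, V_peri_ref;  // kPa/mm, mm^2, mL
  // active drive, sampled on a periodic grid over one beat
  const double *drive; int nd; double dt_drive, bcl;

  inline double p_passive(int c, double V) const {
    double lam = std::cbrt(V / V0[c]);
    if (lam < 0.5) lam = 0.5;
    if (lam > 3.0) lam = 3.0;
    double Eff = 0.5 * (lam * lam - 1);
    double Enn = 0.5 * (std::pow(lam, -4.0) - 1);
    double Q = bf[c] * Eff * Eff + bt[c] * (Eff * Eff + Enn * Enn);
    if (Q > 50) Q = 50;
    double eQ = std::exp(Q);
    double S_ff = a[c] * bf[c] * Eff * eQ;
    double S_ss = a[c] * bt[c] * Eff * eQ;
    double S_nn = a[c] * bt[c] * Enn * eQ;
    double sig = 0.5 * lam * lam * (S_ff + S_ss) - std::pow(lam, -4.0) * S_nn;
    double r0 = std::cbrt(3.0 * V0[c] * 1000.0 / (4.0 * M_PI));
    double h0 = Vwall[c] * 1000.0 / (4.0 * M_PI * r0 * r0);
    double p_kpa = 2.0 * sig * h0 / (r0 * lam * lam * lam);
    return p_kpa * KPA2MMHG;
  }

  inline double drive_at(int c, double t) const {
    double tau = t - bcl * std::floor(t / bcl);
    double x = tau / dt_drive;
    int i = (int)x;
    double f = x - i;
    int i1 = (i + 1) % nd;
    if (i >= nd) { i = nd - 1; i1 = 0; }
    return drive[i + nd * c] * (1 - f) + drive[i1 + nd * c] * f;
  }

  inline double valve(double A, double dp) const {
    if (dp <= 0) return 0.0;
    return A * std::sqrt(2.0 * dp * MMHG2PA / RHO);  // mL/s
  }

  void pressures(double t, const double *V, double *p_ch,
                 double *p_tube) const {
    double Vtot = V[0] + V[1] + V[2] + V[3];
    double p_peri = 0.0;
    if (Vtot > V_peri_ref)
      p_peri = k_peri * (Vtot - V_peri_ref) * 1000.0 / A_peri * KPA2MMHG;
    for (int c = 0; c < 4; ++c) {
      double act = (1.0 / 3.0) * drive_at(c, t) *
        std::log(1.0 + Vwall[c] / std::max(V[c], 1.0)) * KPA2MMHG;
      p_ch[c] = p_passive(c, V[c]) + act + p_peri;
    }
    for (int u = 0; u < 4; ++u)
      p_tube[u] = p_ref[u] * std::pow(V[4 + u] / V_ref[u], ktube[u] / 3.0);
  }

  void flows(const double *p_ch, const double *p_tube, double *q) const {
    // q: 0 MV, 1 AV, 2 TV, 3 PV, 4 SO, 5 PO, 6 sys, 7 pulm
    q[0] = valve(A_mv, p_ch[2] - p_ch[0]);
    q[1] = valve(A_av, p_ch[0] - p_tube[0]);
    q[2] = valve(A_tv, p_ch[3] - p_ch[1]);
    q[3] = valve(A_pv, p_ch[1] - p_tube[1]);
    q[4] = valve(A_so, p_tube[2] - p_ch[3]);
    q[5] = valve(A_po, p_tube[3] - p_ch[2]);
    q[6] = (p_tube[0] - p_tube[2]) / r_sys;
    q[7] = (p_tube[1] - p_tube[3]) / r_pulm;
  }

  void rhs(double t, const double *V, double *dV) const {
    double p_ch[4], p_tube[4], q[8];
    pressures(t, V, p_ch, p_tube);
    flows(p_ch, p_tube, q);
    // flows in mL/s, time in ms
    dV[0] = (q[0] - q[1]) / 1000.0;  // LV
    dV[1] = (q[2] - q[3]) / 1000.0;  // RV
    dV[2] = (q[5] - q[0]) / 1000.0;  // LA
    dV[3] = (q[4] - q[2]) / 1000.0;  // RA
    dV[4] = (q[1] - q[6]) / 1000.0;  // Ao
    dV[5] = (q[3] - q[7]) / 1000.0;  // Pa
    dV[6] = (q[6] - q[4]) / 1000.0;  // Ve
    dV[7] = (q[7] - q[5]) / 1000.0;  // Pve
  }
};

// [[Rcpp::export(name = ".circ_run_cpp")]]
List circ_run_cpp(List pars, NumericMatrix drive, NumericVector y0,
                  int n_beats, double bcl, double dt_out, double dt_int) {
  Circ C;
  NumericVector a = pars["a"], bf = pars["bf"], bt = pars["bt"],
    V0 = pars["V0"], Vwall = pars["Vwall"],
    p_ref = pars["p_ref"], V_ref = pars["V_ref"], ktube = pars["ktube"];
  for (int i = 0; i < 4; ++i) {
    C.a[i] = a[i]; C.bf[i] = bf[i]; C.bt[i] = bt[i];
    C.V0[i] = V0[i]; C.Vwall[i] = Vwall[i];
    C.p_ref[i] = p_ref[i]; C.V_ref[i] = V_ref[i]; C.ktube[i] = ktube[i];
  }
  C.A_mv = pars["A_mv"]; C.A_av = pars["A_av"]; C.A_tv = pars["A_tv"];
  C.A_pv = pars["A_pv"]; C.A_so = pars["A_so"]; C.A_po = pars["A_po"];
  C.r_sys = pars["r_sys"]; C.r_pulm = pars["r_pulm"];
  C.k_peri = pars["k_peri"]; C.A_peri = pars["A_peri"];
  C.V_peri_ref = pars["V_peri_ref"];
  C.drive = drive.begin(); C.nd = drive.nrow();
  C.dt_drive = bcl / drive.nrow(); C.bcl = bcl;

  int steps_per_out = (int)std::round(dt_out / dt_int);
  int n_out = (int)std::round(n_beats * bcl / dt_out) + 1;
  NumericVector time(n_out);
  NumericMatrix Vout(n_out, 8), Pch(n_out, 4), Ptube(n_out, 4), Q(n_out, 8);
  double V[8], dV[8], k1[8], k2[8], k3[8], k4[8], tmp[8];
  for (int i = 0; i < 8; ++i) V[i] = y0[i];
  bool success = true;
  int n_done = 0;
  double t = 0.0;
  for (int io = 0; io < n_out; ++io) {
    double p_ch[4], p_tube[4], q[8];
    C.pressures(t, V, p_ch, p_tube);
    C.flows(p_ch, p_tube, q);
    time[io] = t;
    for (int i = 0; i < 8; ++i) Vout(io, i) = V[i];
    for (int i = 0; i < 4; ++i) { Pch(io, i) = p_ch[i]; Ptube(io, i) = p_tube[i]; }
    for (int i = 0; i < 8; ++i) Q(io, i) = q[i];
    n_done = io + 1;
    bool bad = false;
    for (int i = 0; i < 8; ++i)
      if (!std::isfinite(V[i]) || V[i] <= 0) bad = true;
    if (bad) { success = false; break; }
    if (io == n_out - 1) break;
    for (int s = 0; s < steps_per_out; ++s) {
      C.rhs(t, V, k1);
      for (int i = 0; i < 8; ++i) tmp[i] = V[i] + 0.5 * dt_int * k1[i];
      C.rhs(t + 0.5 * dt_int, tmp, k2);
      for (int i = 0; i < 8; ++i) tmp[i] = V[i] + 0.5 * dt_int * k2[i];
      C.rhs(t + 0.5 * dt_int, tmp, k3);
      for (int i = 0; i < 8; ++i) tmp[i] = V[i] + dt_int * k3[i];
      C.rhs(t + dt_int, tmp, k4);
      for (int i = 0; i < 8; ++i)
        V[i] += dt_int / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      t += dt_int;
    }
    t = (io + 1) * dt_out;  // avoid drift
  }
  (void)dV;
  return List::create(_["time"] = time, _["V"] = Vout, _["p_chamber"] = Pch,
                      _["p_tube"] = Ptube, _["q"] = Q,
                      _["success"] = success, _["n_out"] = n_done);
}
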