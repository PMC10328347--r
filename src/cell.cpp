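#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// RK4 integration of the calcium-driven active-tension surrogate.
// States: c = calcium-bound troponin fraction (CaTRPN), p = permissive
// fraction, w/s = weakly/strongly bound crossbridge fractions (u = 1-w-s).
//   c' = k_trpn * buffer_scale * ((Ca/ca50)^n_trpn * (1 - c) - c)
//   p' = k_u * (c^n_tm / (c^n_tm + trpn50^n_tm) - p)
//   w' = a1*u - d1*w - a2*w + d2*s,  s' = a2*w - d2*s
// with a1 = kb*nu*p, a2 = kb*mu, and off-rates chosen so that sustained
// p = 1 gives the steady state s = r_s, w = r_w * s:
//   d1 = kb*nu*(1 - r_s*(1 + r_w)) / (r_w * r_s),  d2 = kb*mu*r_w.
// Isometric tension T = T_ref * s / r_s, optionally scaled by the
// velocity factor clamp(1 - A_eff*tanh(phi*v), 0, 1).

struct CellPars {
  double k_trpn, buffer_scale, ca50, n_trpn, trpn50, n_tm, k_u;
  double kb, nu, mu, r_s, r_w, T_ref, A_eff, phi;
  double d1, d2;
};

static inline void derivs(double ca, double c, double p, double w, double s,
                          const CellPars &pp, double *dc, double *dp,
                          double *dw, double *ds) {
  double x = std::pow(ca / pp.ca50, pp.n_trpn);
  *dc = pp.k_trpn * pp.buffer_scale * (x * (1 - c) - c);
  // Hill regulation normalised so that full troponin occupancy (c = 1)
  // gives a fully permissive thin filament: then sustained saturating
  // calcium drives s -> r_s and T -> T_ref exactly.
  double cn = std::pow(c > 0 ? c : 0, pp.n_tm);
  double t50n = std::pow(pp.trpn50, pp.n_tm);
  double pinf = cn * (1 + t50n) / (cn + t50n);
  if (pinf > 1) pinf = 1;
  *dp = pp.k_u * (pinf - p);
  double u = 1 - w - s;
  double a1 = pp.kb * pp.nu * p;
  double a2 = pp.kb * pp.mu;
  *dw = a1 * u - pp.d1 * w - a2 * w + pp.d2 * s;
  *ds = a2 * w - pp.d2 * s;
}

// [[Rcpp::export(name = ".tension_integrate_cpp")]]
List tension_integrate_cpp(NumericVector ca, double dt,
                           List params, NumericVector velocity,
                           NumericVector state0) {
  CellPars pp;
  pp.k_trpn = params["k_trpn"];
  pp.buffer_scale = params["buffer_scale"];
  pp.ca50 = params["ca50"];
  pp.n_trpn = params["n_trpn"];
  pp.trpn50 = params["trpn50"];
  pp.n_tm = params["n_tm"];
  pp.k_u = params["k_u"];
  pp.kb = params["kb"];
  pp.nu = params["nu"];
  pp.mu = params["mu"];
  pp.r_s = params["r_s"];
  pp.r_w = params["r_w"];
  pp.T_ref = params["T_ref"];
  pp.A_eff = params["A_eff"];
  pp.phi = params["phi"];
  double ustar = 1 - pp.r_s * (1 + pp.r_w);
  if (ustar <= 0) stop("r_s*(1 + r_w) must be < 1");
  pp.d1 = pp.kb * pp.nu * ustar / (pp.r_w * pp.r_s);
  pp.d2 = pp.kb * pp.mu * pp.r_w;

  int nt = ca.size();
  bool has_v = velocity.size() == nt;
  double c = state0[0], p = state0[1], w = state0[2], s = state0[3];
  NumericVector T(nt);
  NumericMatrix states(nt, 4);
  for (int i = 0; i < nt; ++i) {
    states(i, 0) = c; states(i, 1) = p; states(i, 2) = w; states(i, 3) = s;
    double vfac = 1.0;
    if (has_v) {
      vfac = 1 - pp.A_eff * std::tanh(pp.phi * velocity[i]);
      if (vfac < 0) vfac = 0;
      if (vfac > 1) vfac = 1;
    }
    T[i] = pp.T_ref * s / pp.r_s * vfac;
    if (i == nt - 1) break;
    double ca0 = ca[i], ca1 = ca[i + 1], cam = 0.5 * (ca0 + ca1);
    double k1c, k1p, k1w, k1s, k2c, k2p, k2w, k2s;
    double k3c, k3p, k3w, k3s, k4c, k4p, k4w, k4s;
    derivs(ca0, c, p, w, s, pp, &k1c, &k1p, &k1w, &k1s);
    derivs(cam, c + 0.5 * dt * k1c, p + 0.5 * dt * k1p,
           w + 0.5 * dt * k1w, s + 0.5 * dt * k1s, pp,
           &k2c, &k2p, &k2w, &k2s);
    derivs(cam, c + 0.5 * dt * k2c, p + 0.5 * dt * k2p,
           w + 0.5 * dt * k2w, s + 0.5 * dt * k2s, pp,
           &k3c, &k3p, &k3w, &k3s);
    derivs(ca1, c + dt * k3c, p + dt * k3p, w + dt * k3w, s + dt * k3s,
           pp, &k4c, &k4p, &k4w, &k4s);
    c += dt / 6 * (k1c + 2 * k2c + 2 * k3c + k4c);
    p += dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p);
    w += dt / 6 * (k1w + 2 * k2w + 2 * k3w + k4w);
    s += dt / 6 * (k1s + 2 * k2s + 2 * k3s + k4s);
    if (c < -1e-9 || p < -1e-9 || w < -1e-9 || s < -1e-9)
      stop("unstable integration: negative state at step %d (t = %.3f ms)",
           i + 1, (i + 1) * dt);
    if (c < 0) c = 0;
    if (p < 0) p = 0;
    if (w < 0) w = 0;
    if (s < 0) s = 0;
  }
  return List::create(_["tension"] = T, _["states"] = states);
}
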