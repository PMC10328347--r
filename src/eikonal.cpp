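#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Anisotropic Eikonal solver on a regular grid (2-D or 3-D), iterative
// Gauss-Seidel sweeps over the 2^d sweep orderings until the solution is
// stationary. The local solver minimises, over each admissible neighbour
// segment [A,B], t = (1-l)*tA + l*tB + sqrt(e' W e) with e the vector from
// the segment point to the node and W the inverse squared-velocity tensor
// W = ff'/cf^2 + (I - ff')/ct^2, which has the closed form
// e'We = (e.f)^2 (1/cf^2 - 1/ct^2) + |e|^2 / ct^2.

static const double INF = std::numeric_limits<double>::infinity();

struct Metric {
  double fx, fy, fz, icf2, ict2;  // fibre direction and inverse sq speeds
  inline double q(double ex, double ey, double ez) const {
    double ef = ex * fx + ey * fy + ez * fz;
    double e2 = ex * ex + ey * ey + ez * ez;
    double v = ef * ef * (icf2 - ict2) + e2 * ict2;
    return v > 0 ? v : 0;
  }
};

// minimise over l in [0,1]: f(l) = tA + l*dt + sqrt(q0 + 2 q1 l + q2 l^2)
static inline double seg_solve(double tA, double tB, double q0, double q1,
                               double q2) {
  double dt = tB - tA;
  double best = std::min(tA + std::sqrt(q0), tB + std::sqrt(q0 + 2 * q1 + q2));
  // interior stationary points: (q1 + q2 l)^2 = dt^2 (q0 + 2 q1 l + q2 l^2)
  double a = q2 * (q2 - dt * dt);
  double b = 2 * q1 * (q2 - dt * dt);
  double c = q1 * q1 - dt * dt * q0;
  if (std::fabs(a) > 1e-300) {
    double disc = b * b - 4 * a * c;
    if (disc >= 0) {
      double sd = std::sqrt(disc);
      for (int s = -1; s <= 1; s += 2) {
        double l = (-b + s * sd) / (2 * a);
        if (l > 0 && l < 1) {
          double rad = q0 + 2 * q1 * l + q2 * l * l;
          if (rad >= 0) {
            double val = tA + l * dt + std::sqrt(rad);
            if (val < best) best = val;
          }
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".eikonal_solve_cpp")]]
NumericVector eikonal_solve_cpp(IntegerVector dims, double h,
                                LogicalVector conducting,
                                NumericMatrix fibre,
                                NumericVector cf, NumericVector ct,
                                IntegerVector src_nodes,
                                NumericVector src_t0,
                                double tol = 1e-9, int max_iter = 1000) {
  int nx = dims[0], ny = dims[1], nz = dims.size() > 2 ? dims[2] : 1;
  int n = nx * ny * nz;
  std::vector<Metric> met(n);
  for (int i = 0; i < n; ++i) {
    met[i].fx = fibre(i, 0);
    met[i].fy = fibre(i, 1);
    met[i].fz = fibre.ncol() > 2 ? fibre(i, 2) : 0.0;
    met[i].icf2 = 1.0 / (cf[i] * cf[i]);
    met[i].ict2 = 1.0 / (ct[i] * ct[i]);
  }

  // neighbour offsets (Chebyshev distance 1) and admissible segment pairs
  std::vector<int> ox, oy, oz;
  for (int dz = (nz > 1 ? -1 : 0); dz <= (nz > 1 ? 1 : 0); ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  int nn = (int)ox.size();
  std::vector<std::pair<int,int> > pairs;
  for (int a = 0; a < nn; ++a)
    for (int b = a + 1; b < nn; ++b) {
      int ddx = std::abs(ox[a] - ox[b]);
      int ddy = std::abs(oy[a] - oy[b]);
      int ddz = std::abs(oz[a] - oz[b]);
      if (std::max(ddx, std::max(ddy, ddz)) == 1)
        pairs.push_back(std::make_pair(a, b));
    }

  std::vector<double> t(n, INF);
  for (int s = 0; s < src_nodes.size(); ++s) {
    int idx = src_nodes[s];
    if (idx >= 0 && idx < n && conducting[idx])
      t[idx] = std::min(t[idx], src_t0[s]);
  }

  std::vector<double> tn(nn);
  std::vector<bool> ok(nn);
  std::vector<int> nbr(nn);

  int n_ord = (nz > 1 ? 8 : 4);
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_change = 0.0;
    for (int ord = 0; ord < n_ord; ++ord) {
      bool rx = ord & 1, ry = ord & 2, rz = ord & 4;
      for (int kk = 0; kk < nz; ++kk) {
        int k = rz ? nz - 1 - kk : kk;
        for (int jj = 0; jj < ny; ++jj) {
          int j = ry ? ny - 1 - jj : jj;
          for (int ii = 0; ii < nx; ++ii) {
            int i = rx ? nx - 1 - ii : ii;
            int idx = i + nx * (j + ny * k);
            if (!conducting[idx]) continue;
            // gather finite conducting neighbours
            for (int m = 0; m < nn; ++m) {
              int x2 = i + ox[m], y2 = j + oy[m], z2 = k + oz[m];
              ok[m] = false;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                  z2 < 0 || z2 >= nz) continue;
              int id2 = x2 + nx * (y2 + ny * z2);
              if (!conducting[id2] || !std::isfinite(t[id2])) continue;
              ok[m] = true; nbr[m] = id2; tn[m] = t[id2];
            }
            const Metric &W = met[idx];
            double best = t[idx];
            // edge updates
            for (int m = 0; m < nn; ++m) {
              if (!ok[m]) continue;
              double ex = -h * ox[m], ey = -h * oy[m], ez = -h * oz[m];
              double val = tn[m] + std::sqrt(W.q(ex, ey, ez));
              if (val < best) best = val;
            }
            // segment updates
            for (size_t pp = 0; pp < pairs.size(); ++pp) {
              int a = pairs[pp].first, b = pairs[pp].second;
              if (!ok[a] || !ok[b]) continue;
              double px = -h * ox[a], py = -h * oy[a], pz = -h * oz[a];
              double qx = -h * (ox[b] - ox[a]);
              double qy = -h * (oy[b] - oy[a]);
              double qz = -h * (oz[b] - oz[a]);
              double q0 = W.q(px, py, pz);
              double q2 = W.q(qx, qy, qz);
              double ef_p = px * W.fx + py * W.fy + pz * W.fz;
              double ef_q = qx * W.fx + qy * W.fy + qz * W.fz;
              double dot_pq = px * qx + py * qy + pz * qz;
              double q1 = ef_p * ef_q * (W.icf2 - W.ict2) + dot_pq * W.ict2;
              double val = seg_solve(tn[a], tn[b], q0, q1, q2);
              if (val < best) best = val;
            }
            if (best < t[idx]) {
              double change = std::isfinite(t[idx]) ? t[idx] - best : INF;
              t[idx] = best;
              if (change > max_change) max_change = change;
            }
          }
        }
      }
    }
    if (max_change < tol) break;
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = t[i];
  return out;
}
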