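// Pathline integration through a cell-centred velocity field with an
// embedded adaptive Runge-Kutta scheme (Dormand-Prince 4(5)). Velocity and
// local shear rate are interpolated trilinearly on the (wall-padded)
// rectilinear grid; step size is controlled so the per-step error estimate
// stays below an absolute spatial tolerance.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Field {
  const double *xs, *ys, *zs;
  int nx, ny, nz;
  const double *u, *v, *w, *g;

  int locate(const double* c, int n, double x) const {
    // interval index i with c[i] <= x <= c[i+1], clamped
    if (x <= c[0]) return 0;
    if (x >= c[n - 1]) return n - 2;
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (c[mid] <= x) lo = mid; else hi = mid;
    }
    return lo;
  }

  inline double frac(const double* c, int i, double x) const {
    double t = (x - c[i]) / (c[i + 1] - c[i]);
    if (t < 0) t = 0; if (t > 1) t = 1;
    return t;
  }

  void tri(double x, double y, double z, double* out, bool with_gamma) const {
    int i = locate(xs, nx, x), j = locate(ys, ny, y), k = locate(zs, nz, z);
    double tx = frac(xs, i, x), ty = frac(ys, j, y), tz = frac(zs, k, z);
    double wgt[8];
    wgt[0] = (1-tx)*(1-ty)*(1-tz); wgt[1] = tx*(1-ty)*(1-tz);
    wgt[2] = (1-tx)*ty*(1-tz);     wgt[3] = tx*ty*(1-tz);
    wgt[4] = (1-tx)*(1-ty)*tz;     wgt[5] = tx*(1-ty)*tz;
    wgt[6] = (1-tx)*ty*tz;         wgt[7] = tx*ty*tz;
    int id[8];
    for (int c = 0; c < 8; ++c) {
      int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
      id[c] = ii + nx * (jj + ny * kk);
    }
    double uu = 0, vv = 0, ww = 0, gg = 0;
    for (int c = 0; c < 8; ++c) {
      uu += wgt[c] * u[id[c]];
      vv += wgt[c] * v[id[c]];
      ww += wgt[c] * w[id[c]];
      if (with_gamma) gg += wgt[c] * g[id[c]];
    }
    out[0] = uu; out[1] = vv; out[2] = ww;
    if (with_gamma) out[3] = gg;
  }
};

// Dormand-Prince coefficients
const double C2 = 1.0/5, C3 = 3.0/10, C4 = 4.0/5, C5 = 8.0/9;
const double A21 = 1.0/5;
const double A31 = 3.0/40, A32 = 9.0/40;
const double A41 = 44.0/45, A42 = -56.0/15, A43 = 32.0/9;
const double A51 = 19372.0/6561, A52 = -25360.0/2187, A53 = 64448.0/6561, A54 = -212.0/729;
const double A61 = 9017.0/3168, A62 = -355.0/33, A63 = 46732.0/5247, A64 = 49.0/176, A65 = -5103.0/18656;
const double B1 = 35.0/384, B3 = 500.0/1113, B4 = 125.0/192, B5 = -2187.0/6784, B6 = 11.0/84;
const double E1 = 71.0/57600, E3 = -71.0/16695, E4 = 71.0/1920, E5 = -17253.0/339200, E6 = 22.0/525, E7 = -1.0/40;

} // namespace

// dir = -1: backward in time (toward the inlet); dir = +1: forward.
// Units: coordinates um, velocity um/s, time s, tolerance um.
// Termination codes: 1 plane, 2 stagnation, 3 time_cap, 4 exited, 5 time_end,
// 6 max_steps.
// [[Rcpp::export(name = ".cpp_trace")]]
List cpp_trace(NumericVector xs, NumericVector ys, NumericVector zs,
               NumericVector u, NumericVector v, NumericVector w,
               NumericVector gam, NumericMatrix seeds, double dir,
               double atol, double h_max, double t_cap, double eps_stag,
               double x_stop_lo, double x_stop_hi, double t_end,
               int max_steps) {
  Field f;
  f.xs = REAL(xs); f.ys = REAL(ys); f.zs = REAL(zs);
  f.nx = xs.size(); f.ny = ys.size(); f.nz = zs.size();
  f.u = REAL(u); f.v = REAL(v); f.w = REAL(w); f.g = REAL(gam);

  const double ylo = f.ys[0], yhi = f.ys[f.ny - 1];
  const double zlo = f.zs[0], zhi = f.zs[f.nz - 1];

  int nseed = seeds.nrow();
  List out(nseed);

  for (int s = 0; s < nseed; ++s) {
    double y0[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
    std::vector<double> rec; // t, x, y, z, gamma per accepted sample
    double fv[4];
    f.tri(y0[0], y0[1], y0[2], fv, true);
    double t = 0.0;
    rec.insert(rec.end(), {t, y0[0], y0[1], y0[2], fv[3]});
    int reason = 6;
    double speed0 = std::sqrt(fv[0]*fv[0] + fv[1]*fv[1] + fv[2]*fv[2]);
    if (speed0 < eps_stag) {
      reason = 2;
    } else {
      double h = std::min(h_max, 1e-4);
      double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], tmp[3], y5[3];
      // FSAL: k1 from current point
      f.tri(y0[0], y0[1], y0[2], fv, false);
      for (int d = 0; d < 3; ++d) k1[d] = dir * fv[d];
      int step = 0;
      while (step < max_steps) {
        bool clipped = false;
        if (t_end > 0 && t + h >= t_end) { h = t_end - t; clipped = true; }
        if (h <= 0) { reason = 5; break; }

        auto eval = [&](const double* yy, double* kk) {
          f.tri(yy[0], yy[1], yy[2], fv, false);
          for (int d = 0; d < 3; ++d) kk[d] = dir * fv[d];
        };
        for (int d = 0; d < 3; ++d) tmp[d] = y0[d] + h * A21 * k1[d];
        eval(tmp, k2);
        for (int d = 0; d < 3; ++d) tmp[d] = y0[d] + h * (A31*k1[d] + A32*k2[d]);
        eval(tmp, k3);
        for (int d = 0; d < 3; ++d) tmp[d] = y0[d] + h * (A41*k1[d] + A42*k2[d] + A43*k3[d]);
        eval(tmp, k4);
        for (int d = 0; d < 3; ++d) tmp[d] = y0[d] + h * (A51*k1[d] + A52*k2[d] + A53*k3[d] + A54*k4[d]);
        eval(tmp, k5);
        for (int d = 0; d < 3; ++d) tmp[d] = y0[d] + h * (A61*k1[d] + A62*k2[d] + A63*k3[d] + A64*k4[d] + A65*k5[d]);
        eval(tmp, k6);
        for (int d = 0; d < 3; ++d) y5[d] = y0[d] + h * (B1*k1[d] + B3*k3[d] + B4*k4[d] + B5*k5[d] + B6*k6[d]);
        eval(y5, k7);
        double err = 0.0;
        for (int d = 0; d < 3; ++d) {
          double e = h * (E1*k1[d] + E3*k3[d] + E4*k4[d] + E5*k5[d] + E6*k6[d] + E7*k7[d]);
          err = std::max(err, std::fabs(e));
        }
        double ratio = err / atol;
        if (ratio <= 1.0) {
          // accept
          t += h;
          for (int d = 0; d < 3; ++d) y0[d] = y5[d];
          for (int d = 0; d < 3; ++d) k1[d] = k7[d]; // FSAL
          f.tri(y0[0], y0[1], y0[2], fv, true);
          rec.insert(rec.end(), {t, y0[0], y0[1], y0[2], fv[3]});
          ++step;
          double speed = std::sqrt(fv[0]*fv[0] + fv[1]*fv[1] + fv[2]*fv[2]);
          if (clipped && t >= t_end) { reason = 5; break; }
          if (y0[0] <= x_stop_lo || y0[0] >= x_stop_hi) { reason = 1; break; }
          if (y0[1] < ylo || y0[1] > yhi || y0[2] < zlo || y0[2] > zhi) { reason = 4; break; }
          if (speed < eps_stag) { reason = 2; break; }
          if (t >= t_cap) { reason = 3; break; }
        }
        double fac = (ratio > 1e-30) ? 0.9 * std::pow(ratio, -0.2) : 5.0;
        if (fac < 0.2) fac = 0.2; if (fac > 5.0) fac = 5.0;
        h = std::min(h * fac, h_max);
        if (h < 1e-14) { reason = 2; break; } // cannot advance
      }
      if (step >= max_steps) reason = 6;
    }
    int n = (int)(rec.size() / 5);
    NumericMatrix M(n, 5);
    for (int r = 0; r < n; ++r)
      for (int c = 0; c < 5; ++c) M(r, c) = rec[5 * r + c];
    colnames(M) = CharacterVector::create("t", "x", "y", "z", "gamma");
    out[s] = List::create(_["samples"] = M, _["reason"] = reason);
  }
  return out;
}
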