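// Steady incompressible Navier-Stokes on a rectilinear staggered grid using
// SIMPLE pressure-velocity coupling. Convection is first-order upwind (cell
// Peclet numbers are < 1 at the Reynolds numbers of interest), diffusion is
// central. The obstacle is a voxel mask: any velocity face touching a solid
// cell is a no-slip face. Inlet: fixed profile; outlet: zero-gradient
// velocity rescaled each outer iteration to conserve the volumetric flow.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {
struct Grid {
  int Nx, Ny, Nz;
  std::vector<double> dx, dy, dz, xc, yc, zc;
  std::vector<double> xf, yf, zf;
};

inline int idc(const Grid& g, int i, int j, int k) {
  return i + g.Nx * (j + g.Ny * k);
}
} // namespace

// [[Rcpp::export(name = ".cpp_simple_solve")]]
List cpp_simple_solve(NumericVector xf_, NumericVector yf_, NumericVector zf_,
                      LogicalVector solid_, NumericMatrix uin,
                      double rho, double mu, double Q,
                      double tol, int max_outer, double alpha_u, double alpha_p,
                      int n_sweep_mom, int n_sweep_p, double omega) {
  Grid g;
  g.Nx = xf_.size() - 1; g.Ny = yf_.size() - 1; g.Nz = zf_.size() - 1;
  const int Nx = g.Nx, Ny = g.Ny, Nz = g.Nz;
  g.xf.assign(xf_.begin(), xf_.end());
  g.yf.assign(yf_.begin(), yf_.end());
  g.zf.assign(zf_.begin(), zf_.end());
  for (int i = 0; i < Nx; ++i) { g.dx.push_back(g.xf[i+1]-g.xf[i]); g.xc.push_back(0.5*(g.xf[i]+g.xf[i+1])); }
  for (int j = 0; j < Ny; ++j) { g.dy.push_back(g.yf[j+1]-g.yf[j]); g.yc.push_back(0.5*(g.yf[j]+g.yf[j+1])); }
  for (int k = 0; k < Nz; ++k) { g.dz.push_back(g.zf[k+1]-g.zf[k]); g.zc.push_back(0.5*(g.zf[k]+g.zf[k+1])); }

  std::vector<char> solid(Nx * Ny * Nz);
  for (int c = 0; c < Nx * Ny * Nz; ++c) solid[c] = solid_[c] ? 1 : 0;

  const int nu = (Nx + 1) * Ny * Nz, nv = Nx * (Ny + 1) * Nz, nw = Nx * Ny * (Nz + 1);
  auto idu = [&](int i, int j, int k) { return i + (Nx + 1) * (j + Ny * k); };
  auto idv = [&](int i, int j, int k) { return i + Nx * (j + (Ny + 1) * k); };
  auto idw = [&](int i, int j, int k) { return i + Nx * (j + Ny * k); }; // k in 0..Nz

  std::vector<double> u(nu, 0.0), v(nv, 0.0), w(nw, 0.0);
  std::vector<double> p(Nx * Ny * Nz, 0.0), pp(Nx * Ny * Nz, 0.0);
  std::vector<double> du(nu, 0.0), dv(nv, 0.0), dw(nw, 0.0);
  std::vector<char> ufix(nu, 0), vfix(nv, 0), wfix(nw, 0);

  // fixed faces: walls, inlet, outlet (handled separately), solid-adjacent
  for (int k = 0; k < Nz; ++k)
    for (int j = 0; j < Ny; ++j) {
      ufix[idu(0, j, k)] = 1;        // inlet
      ufix[idu(Nx, j, k)] = 2;       // outlet (updated by copy+scale)
      for (int i = 1; i < Nx; ++i)
        if (solid[idc(g, i - 1, j, k)] || solid[idc(g, i, j, k)]) ufix[idu(i, j, k)] = 1;
    }
  for (int k = 0; k < Nz; ++k)
    for (int i = 0; i < Nx; ++i) {
      vfix[idv(i, 0, k)] = 1; vfix[idv(i, Ny, k)] = 1;   // side walls
      for (int j = 1; j < Ny; ++j)
        if (solid[idc(g, i, j - 1, k)] || solid[idc(g, i, j, k)]) vfix[idv(i, j, k)] = 1;
    }
  auto idwf = idw;
  for (int j = 0; j < Ny; ++j)
    for (int i = 0; i < Nx; ++i) {
      wfix[idwf(i, j, 0)] = 1; wfix[idwf(i, j, Nz)] = 1;
      for (int k = 1; k < Nz; ++k)
        if (solid[idc(g, i, j, k - 1)] || solid[idc(g, i, j, k)]) wfix[idwf(i, j, k)] = 1;
    }

  // initialize u with the inlet profile wherever the column is fluid
  for (int k = 0; k < Nz; ++k)
    for (int j = 0; j < Ny; ++j) {
      double ui = uin(j, k);
      for (int i = 0; i <= Nx; ++i) {
        int iu = idu(i, j, k);
        if (i > 0 && i < Nx && ufix[iu] == 1) u[iu] = 0.0; else u[iu] = ui;
      }
    }

  const double Uref = std::fabs(Q) / ((g.yf[Ny] - g.yf[0]) * (g.zf[Nz] - g.zf[0]));
  const double mass_scale = rho * std::fabs(Q);
  const double mom_scale = rho * std::fabs(Q) * Uref;

  // coefficient arrays reused per component
  std::vector<double> aE, aW, aN, aS, aT, aB, aP, bb;
  auto resize_all = [&](int n) {
    aE.assign(n, 0); aW.assign(n, 0); aN.assign(n, 0); aS.assign(n, 0);
    aT.assign(n, 0); aB.assign(n, 0); aP.assign(n, 0); bb.assign(n, 0);
  };

  std::vector<double> res_hist;
  bool converged = false;
  int it_done = 0;

  for (int outer = 0; outer < max_outer; ++outer) {
    // ---- outlet: zero-gradient copy, scaled to conserve Q ----
    double flux_out = 0.0;
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j) {
        double val = u[idu(Nx - 1, j, k)];
        u[idu(Nx, j, k)] = val;
        flux_out += val * g.dy[j] * g.dz[k];
      }
    if (flux_out > 0.2 * std::fabs(Q)) {
      double sc = Q / flux_out;
      if (sc > 2.0) sc = 2.0; if (sc < 0.5) sc = 0.5;  // transient guard
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j) u[idu(Nx, j, k)] *= sc;
    } else {
      // transiently reversed/blocked outlet: impose a uniform outflow
      double area = (g.yf[Ny] - g.yf[0]) * (g.zf[Nz] - g.zf[0]);
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j) u[idu(Nx, j, k)] = Q / area;
    }

    double res_u = 0, res_v = 0, res_w = 0;

    // ================= u momentum =================
    resize_all(nu);
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 1; i < Nx; ++i) {
          int iu = idu(i, j, k);
          if (ufix[iu]) continue;
          double Ae = g.dy[j] * g.dz[k];
          double dxu = g.xc[i] - g.xc[i - 1];
          // x neighbours (u faces i-1, i+1)
          double Fe = rho * 0.5 * (u[iu] + u[idu(i + 1, j, k)]) * Ae;
          double Fw = rho * 0.5 * (u[idu(i - 1, j, k)] + u[iu]) * Ae;
          double De = mu * Ae / g.dx[i], Dw = mu * Ae / g.dx[i - 1];
          double ae = De + std::max(-Fe, 0.0), aw = Dw + std::max(Fw, 0.0);
          // y neighbours
          double Axy = dxu * g.dz[k];
          double vn = 0.5 * (v[idv(i - 1, j + 1, k)] + v[idv(i, j + 1, k)]);
          double vs = 0.5 * (v[idv(i - 1, j, k)] + v[idv(i, j, k)]);
          double Fn = rho * vn * Axy, Fs = rho * vs * Axy;
          double dn = (j + 1 < Ny) ? (g.yc[j + 1] - g.yc[j]) : (g.yf[Ny] - g.yc[Ny - 1]);
          double ds = (j > 0) ? (g.yc[j] - g.yc[j - 1]) : (g.yc[0] - g.yf[0]);
          double Dn = mu * Axy / dn, Ds = mu * Axy / ds;
          double an = Dn + std::max(-Fn, 0.0), as_ = Ds + std::max(Fs, 0.0);
          // z neighbours
          double Axz = dxu * g.dy[j];
          double wt = 0.5 * (w[idwf(i - 1, j, k + 1)] + w[idwf(i, j, k + 1)]);
          double wbm = 0.5 * (w[idwf(i - 1, j, k)] + w[idwf(i, j, k)]);
          double Ft = rho * wt * Axz, Fb = rho * wbm * Axz;
          double dt_ = (k + 1 < Nz) ? (g.zc[k + 1] - g.zc[k]) : (g.zf[Nz] - g.zc[Nz - 1]);
          double db = (k > 0) ? (g.zc[k] - g.zc[k - 1]) : (g.zc[0] - g.zf[0]);
          double Dt = mu * Axz / dt_, Db = mu * Axz / db;
          double at = Dt + std::max(-Ft, 0.0), ab = Db + std::max(Fb, 0.0);

          double netF = (Fe - Fw) + (Fn - Fs) + (Ft - Fb);
          if (netF < 0) netF = 0;  // vanishes at convergence; keeps aP positive
          double ap = ae + aw + an + as_ + at + ab + netF;
          double src = (p[idc(g, i - 1, j, k)] - p[idc(g, i, j, k)]) * Ae;

          // wall / fixed-neighbour handling: neighbour u values of 0 at walls
          // enter through an/at links when j/k at boundary (value read as 0)
          double unb = 0;
          unb += ae * u[idu(i + 1, j, k)] + aw * u[idu(i - 1, j, k)];
          unb += (j + 1 < Ny ? an * u[idu(i, j + 1, k)] : 0.0);
          unb += (j > 0 ? as_ * u[idu(i, j - 1, k)] : 0.0);
          unb += (k + 1 < Nz ? at * u[idu(i, j, k + 1)] : 0.0);
          unb += (k > 0 ? ab * u[idu(i, j, k - 1)] : 0.0);
          res_u += std::fabs(ap * u[iu] - unb - src);

          aE[iu] = ae; aW[iu] = aw; aN[iu] = an; aS[iu] = as_;
          aT[iu] = at; aB[iu] = ab;
          aP[iu] = ap / alpha_u;
          bb[iu] = src + (1.0 - alpha_u) * aP[iu] * u[iu];
          du[iu] = Ae / aP[iu];
        }
    for (int s = 0; s < n_sweep_mom; ++s)
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j)
          for (int i = 1; i < Nx; ++i) {
            int iu = idu(i, j, k);
            if (ufix[iu]) continue;
            double unb = aE[iu] * u[idu(i + 1, j, k)] + aW[iu] * u[idu(i - 1, j, k)];
            if (j + 1 < Ny) unb += aN[iu] * u[idu(i, j + 1, k)];
            if (j > 0)      unb += aS[iu] * u[idu(i, j - 1, k)];
            if (k + 1 < Nz) unb += aT[iu] * u[idu(i, j, k + 1)];
            if (k > 0)      unb += aB[iu] * u[idu(i, j, k - 1)];
            u[iu] = (unb + bb[iu]) / aP[iu];
          }

    // ================= v momentum =================
    resize_all(nv);
    for (int k = 0; k < Nz; ++k)
      for (int j = 1; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int iv = idv(i, j, k);
          if (vfix[iv]) continue;
          double dyv = g.yc[j] - g.yc[j - 1];
          double Ax = dyv * g.dz[k];     // faces normal to x
          double Ay = g.dx[i] * g.dz[k]; // faces normal to y
          double Az = g.dx[i] * dyv;     // faces normal to z
          double ue = 0.5 * (u[idu(i + 1, j - 1, k)] + u[idu(i + 1, j, k)]);
          double uw = 0.5 * (u[idu(i, j - 1, k)] + u[idu(i, j, k)]);
          double Fe = rho * ue * Ax, Fw = rho * uw * Ax;
          double de = (i + 1 < Nx) ? (g.xc[i + 1] - g.xc[i]) : (g.xf[Nx] - g.xc[Nx - 1]);
          double dw_ = (i > 0) ? (g.xc[i] - g.xc[i - 1]) : (g.xc[0] - g.xf[0]);
          double ae = mu * Ax / de + std::max(-Fe, 0.0);
          double aw = mu * Ax / dw_ + std::max(Fw, 0.0);
          double vn = 0.5 * (v[iv] + v[idv(i, j + 1, k)]);
          double vs = 0.5 * (v[idv(i, j - 1, k)] + v[iv]);
          double Fn = rho * vn * Ay, Fs = rho * vs * Ay;
          double an = mu * Ay / g.dy[j] + std::max(-Fn, 0.0);
          double as_ = mu * Ay / g.dy[j - 1] + std::max(Fs, 0.0);
          double wt = 0.5 * (w[idwf(i, j - 1, k + 1)] + w[idwf(i, j, k + 1)]);
          double wb = 0.5 * (w[idwf(i, j - 1, k)] + w[idwf(i, j, k)]);
          double Ft = rho * wt * Az, Fb = rho * wb * Az;
          double dt_ = (k + 1 < Nz) ? (g.zc[k + 1] - g.zc[k]) : (g.zf[Nz] - g.zc[Nz - 1]);
          double db = (k > 0) ? (g.zc[k] - g.zc[k - 1]) : (g.zc[0] - g.zf[0]);
          double at = mu * Az / dt_ + std::max(-Ft, 0.0);
          double ab = mu * Az / db + std::max(Fb, 0.0);

          if (i + 1 == Nx) ae = 0.0;  // outlet: zero-gradient, drop link
          double netF = (Fe - Fw) + (Fn - Fs) + (Ft - Fb);
          if (netF < 0) netF = 0;
          double ap = ae + aw + an + as_ + at + ab + netF;
          double src = (p[idc(g, i, j - 1, k)] - p[idc(g, i, j, k)]) * Ay;

          double vnb = an * v[idv(i, j + 1, k)] + as_ * v[idv(i, j - 1, k)];
          if (i + 1 < Nx) vnb += ae * v[idv(i + 1, j, k)];
          if (i > 0)      vnb += aw * v[idv(i - 1, j, k)];
          if (k + 1 < Nz) vnb += at * v[idv(i, j, k + 1)];
          if (k > 0)      vnb += ab * v[idv(i, j, k - 1)];
          res_v += std::fabs(ap * v[iv] - vnb - src);

          aE[iv] = ae;
          aW[iv] = aw; aN[iv] = an; aS[iv] = as_; aT[iv] = at; aB[iv] = ab;
          aP[iv] = ap / alpha_u;
          bb[iv] = src + (1.0 - alpha_u) * aP[iv] * v[iv];
          dv[iv] = Ay / aP[iv];
        }
    for (int s = 0; s < n_sweep_mom; ++s)
      for (int k = 0; k < Nz; ++k)
        for (int j = 1; j < Ny; ++j)
          for (int i = 0; i < Nx; ++i) {
            int iv = idv(i, j, k);
            if (vfix[iv]) continue;
            double vnb = aN[iv] * v[idv(i, j + 1, k)] + aS[iv] * v[idv(i, j - 1, k)];
            if (i + 1 < Nx) vnb += aE[iv] * v[idv(i + 1, j, k)];
            if (i > 0)      vnb += aW[iv] * v[idv(i - 1, j, k)];
            if (k + 1 < Nz) vnb += aT[iv] * v[idv(i, j, k + 1)];
            if (k > 0)      vnb += aB[iv] * v[idv(i, j, k - 1)];
            v[iv] = (vnb + bb[iv]) / aP[iv];
          }

    // ================= w momentum =================
    resize_all(nw);
    for (int k = 1; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int iw = idwf(i, j, k);
          if (wfix[iw]) continue;
          double dzw = g.zc[k] - g.zc[k - 1];
          double Ax = g.dy[j] * dzw;
          double Ay = g.dx[i] * dzw;
          double Az = g.dx[i] * g.dy[j];
          double ue = 0.5 * (u[idu(i + 1, j, k - 1)] + u[idu(i + 1, j, k)]);
          double uw = 0.5 * (u[idu(i, j, k - 1)] + u[idu(i, j, k)]);
          double Fe = rho * ue * Ax, Fw = rho * uw * Ax;
          double de = (i + 1 < Nx) ? (g.xc[i + 1] - g.xc[i]) : (g.xf[Nx] - g.xc[Nx - 1]);
          double dw_ = (i > 0) ? (g.xc[i] - g.xc[i - 1]) : (g.xc[0] - g.xf[0]);
          double ae = mu * Ax / de + std::max(-Fe, 0.0);
          double aw = mu * Ax / dw_ + std::max(Fw, 0.0);
          double vn = 0.5 * (v[idv(i, j + 1, k - 1)] + v[idv(i, j + 1, k)]);
          double vs = 0.5 * (v[idv(i, j, k - 1)] + v[idv(i, j, k)]);
          double Fn = rho * vn * Ay, Fs = rho * vs * Ay;
          double dn = (j + 1 < Ny) ? (g.yc[j + 1] - g.yc[j]) : (g.yf[Ny] - g.yc[Ny - 1]);
          double ds = (j > 0) ? (g.yc[j] - g.yc[j - 1]) : (g.yc[0] - g.yf[0]);
          double an = mu * Ay / dn + std::max(-Fn, 0.0);
          double as_ = mu * Ay / ds + std::max(Fs, 0.0);
          double wt = 0.5 * (w[iw] + w[idwf(i, j, k + 1)]);
          double wb = 0.5 * (w[idwf(i, j, k - 1)] + w[iw]);
          double Ft = rho * wt * Az, Fb = rho * wb * Az;
          double at = mu * Az / g.dz[k] + std::max(-Ft, 0.0);
          double ab = mu * Az / g.dz[k - 1] + std::max(Fb, 0.0);

          if (i + 1 == Nx) ae = 0.0;  // outlet: zero-gradient, drop link
          double netF = (Fe - Fw) + (Fn - Fs) + (Ft - Fb);
          if (netF < 0) netF = 0;
          double ap = ae + aw + an + as_ + at + ab + netF;
          double src = (p[idc(g, i, j, k - 1)] - p[idc(g, i, j, k)]) * Az;

          double wnb = at * w[idwf(i, j, k + 1)] + ab * w[idwf(i, j, k - 1)];
          if (i + 1 < Nx) wnb += ae * w[idwf(i + 1, j, k)];
          if (i > 0)      wnb += aw * w[idwf(i - 1, j, k)];
          if (j + 1 < Ny) wnb += an * w[idwf(i, j + 1, k)];
          if (j > 0)      wnb += as_ * w[idwf(i, j - 1, k)];
          res_w += std::fabs(ap * w[iw] - wnb - src);

          aE[iw] = ae;
          aW[iw] = aw; aN[iw] = an; aS[iw] = as_; aT[iw] = at; aB[iw] = ab;
          aP[iw] = ap / alpha_u;
          bb[iw] = src + (1.0 - alpha_u) * aP[iw] * w[iw];
          dw[iw] = Az / aP[iw];
        }
    for (int s = 0; s < n_sweep_mom; ++s)
      for (int k = 1; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j)
          for (int i = 0; i < Nx; ++i) {
            int iw = idwf(i, j, k);
            if (wfix[iw]) continue;
            double wnb = aT[iw] * w[idwf(i, j, k + 1)] + aB[iw] * w[idwf(i, j, k - 1)];
            if (i + 1 < Nx) wnb += aE[iw] * w[idwf(i + 1, j, k)];
            if (i > 0)      wnb += aW[iw] * w[idwf(i - 1, j, k)];
            if (j + 1 < Ny) wnb += aN[iw] * w[idwf(i, j + 1, k)];
            if (j > 0)      wnb += aS[iw] * w[idwf(i, j - 1, k)];
            w[iw] = (wnb + bb[iw]) / aP[iw];
          }

    // ---- outlet refresh after momentum ----
    flux_out = 0.0;
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j) {
        double val = u[idu(Nx - 1, j, k)];
        u[idu(Nx, j, k)] = val;
        flux_out += val * g.dy[j] * g.dz[k];
      }
    if (flux_out > 0.2 * std::fabs(Q)) {
      double sc = Q / flux_out;
      if (sc > 2.0) sc = 2.0; if (sc < 0.5) sc = 0.5;
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j) u[idu(Nx, j, k)] *= sc;
    } else {
      double area = (g.yf[Ny] - g.yf[0]) * (g.zf[Nz] - g.zf[0]);
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j) u[idu(Nx, j, k)] = Q / area;
    }

    // ================= pressure correction =================
    int ncell = Nx * Ny * Nz;
    std::vector<double> pe(ncell, 0), pw(ncell, 0), pn(ncell, 0), ps(ncell, 0),
        pt(ncell, 0), pb(ncell, 0), pap(ncell, 0), pbsrc(ncell, 0);
    double mass_res = 0.0;
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int c = idc(g, i, j, k);
          pp[c] = 0.0;
          if (solid[c]) continue;
          double Ae = g.dy[j] * g.dz[k], Ay = g.dx[i] * g.dz[k], Az = g.dx[i] * g.dy[j];
          double de_ = (i + 1 <= Nx) ? du[idu(i + 1, j, k)] : 0.0;
          double dw_ = du[idu(i, j, k)];
          double dn_ = dv[idv(i, j + 1, k)];
          double ds_ = dv[idv(i, j, k)];
          double dt_ = dw[idwf(i, j, k + 1)];
          double db_ = dw[idwf(i, j, k)];
          pe[c] = rho * Ae * de_; pw[c] = rho * Ae * dw_;
          pn[c] = rho * Ay * dn_; ps[c] = rho * Ay * ds_;
          pt[c] = rho * Az * dt_; pb[c] = rho * Az * db_;
          // zero links across solids / fixed faces (d = 0 there already)
          double imbalance = rho * (u[idu(i, j, k)] * Ae - u[idu(i + 1, j, k)] * Ae
                                  + v[idv(i, j, k)] * Ay - v[idv(i, j + 1, k)] * Ay
                                  + w[idwf(i, j, k)] * Az - w[idwf(i, j, k + 1)] * Az);
          pbsrc[c] = imbalance;
          mass_res += std::fabs(imbalance);
          pap[c] = pe[c] + pw[c] + pn[c] + ps[c] + pt[c] + pb[c];
          if (pap[c] <= 0) pap[c] = 1.0; // isolated cell guard
        }
    for (int s = 0; s < n_sweep_p; ++s)
      for (int k = 0; k < Nz; ++k)
        for (int j = 0; j < Ny; ++j)
          for (int i = 0; i < Nx; ++i) {
            int c = idc(g, i, j, k);
            if (solid[c]) continue;
            double nb = 0.0;
            if (i + 1 < Nx) nb += pe[c] * pp[idc(g, i + 1, j, k)];
            if (i > 0)      nb += pw[c] * pp[idc(g, i - 1, j, k)];
            if (j + 1 < Ny) nb += pn[c] * pp[idc(g, i, j + 1, k)];
            if (j > 0)      nb += ps[c] * pp[idc(g, i, j - 1, k)];
            if (k + 1 < Nz) nb += pt[c] * pp[idc(g, i, j, k + 1)];
            if (k > 0)      nb += pb[c] * pp[idc(g, i, j, k - 1)];
            double pnew = (nb + pbsrc[c]) / pap[c];
            pp[c] = pp[c] + omega * (pnew - pp[c]);
          }
    // reference: first fluid cell
    double pref = 0.0;
    for (int c = 0; c < ncell; ++c) if (!solid[c]) { pref = pp[c]; break; }

    // ---- corrections ----
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int c = idc(g, i, j, k);
          if (!solid[c]) p[c] += alpha_p * (pp[c] - pref);
        }
    for (int k = 0; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 1; i < Nx; ++i) {
          int iu = idu(i, j, k);
          if (ufix[iu]) continue;
          u[iu] += du[iu] * (pp[idc(g, i - 1, j, k)] - pp[idc(g, i, j, k)]);
        }
    for (int k = 0; k < Nz; ++k)
      for (int j = 1; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int iv = idv(i, j, k);
          if (vfix[iv]) continue;
          v[iv] += dv[iv] * (pp[idc(g, i, j - 1, k)] - pp[idc(g, i, j, k)]);
        }
    for (int k = 1; k < Nz; ++k)
      for (int j = 0; j < Ny; ++j)
        for (int i = 0; i < Nx; ++i) {
          int iw = idwf(i, j, k);
          if (wfix[iw]) continue;
          w[iw] += dw[iw] * (pp[idc(g, i, j, k - 1)] - pp[idc(g, i, j, k)]);
        }

    double rm = mass_res / mass_scale;
    double ru = res_u / mom_scale, rv = res_v / mom_scale, rw = res_w / mom_scale;
    res_hist.push_back(rm); res_hist.push_back(ru);
    res_hist.push_back(rv); res_hist.push_back(rw);
    it_done = outer + 1;
    double worst = std::max(std::max(rm, ru), std::max(rv, rw));
    if (outer > 2 && worst < tol) { converged = true; break; }
    if (outer % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix hist(it_done, 4);
  for (int r = 0; r < it_done; ++r)
    for (int c = 0; c < 4; ++c) hist(r, c) = res_hist[4 * r + c];
  colnames(hist) = CharacterVector::create("mass", "umom", "vmom", "wmom");

  return List::create(
    _["u"] = NumericVector(u.begin(), u.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["w"] = NumericVector(w.begin(), w.end()),
    _["p"] = NumericVector(p.begin(), p.end()),
    _["residuals"] = hist,
    _["iterations"] = it_done,
    _["converged"] = converged);
}
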