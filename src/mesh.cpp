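// Geometry kernels: iso-surfacing of rectilinear scalar volumes by marching
// tetrahedra (Kuhn cube subdivision -> watertight, consistently oriented
// meshes), mesh measures, Taubin smoothing, ray casting and polygon
// signed-distance fields.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline double det3(const double a[3], const double b[3], const double c[3]) {
  return a[0] * (b[1] * c[2] - b[2] * c[1])
       - a[1] * (b[0] * c[2] - b[2] * c[0])
       + a[2] * (b[0] * c[1] - b[1] * c[0]);
}

struct MeshBuilder {
  std::vector<double> verts;              // xyz triples
  std::vector<int> faces;                 // 0-based triples
  std::unordered_map<uint64_t, int> edge_vertex;

  int edge_point(uint64_t ida, uint64_t idb,
                 const double* pa, const double* pb,
                 double fa, double fb, double level) {
    if (ida > idb) { std::swap(ida, idb); std::swap(pa, pb); std::swap(fa, fb); }
    uint64_t key = ida * 0x100000000ULL ^ idb; // ids < 2^32, a<b unique pairing
    key = ida; key = key << 32 | idb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int idx = (int)(verts.size() / 3);
    for (int d = 0; d < 3; ++d) verts.push_back(pa[d] + t * (pb[d] - pa[d]));
    edge_vertex.emplace(key, idx);
    return idx;
  }

  void add_tri(int a, int b, int c, const double* grad) {
    // the field is linear within a tetrahedron, so orienting the triangle
    // normal against the tet's field gradient (outward = toward lower field
    // values) is exact and globally consistent
    const double* p0 = &verts[3 * a];
    const double* p1 = &verts[3 * b];
    const double* p2 = &verts[3 * c];
    double e1[3], e2[3], n[3];
    for (int d = 0; d < 3; ++d) { e1[d] = p1[d] - p0[d]; e2[d] = p2[d] - p0[d]; }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double dot = n[0] * grad[0] + n[1] * grad[1] + n[2] * grad[2];
    if (dot > 0) std::swap(b, c);
    faces.push_back(a); faces.push_back(b); faces.push_back(c);
  }
};

// the six Kuhn tetrahedra of a unit cube: monotone vertex paths 0 -> 7
// local corner numbering: bit0 = x, bit1 = y, bit2 = z
const int KUHN[6][4] = {
  {0, 1, 3, 7},  // x, y, z
  {0, 1, 5, 7},  // x, z, y
  {0, 2, 3, 7},  // y, x, z
  {0, 2, 6, 7},  // y, z, x
  {0, 4, 5, 7},  // z, x, y
  {0, 4, 6, 7}   // z, y, x
};

} // namespace

// [[Rcpp::export(name = ".cpp_marching_tetrahedra")]]
List cpp_marching_tetrahedra(NumericVector field, NumericVector xs,
                             NumericVector ys, NumericVector zs,
                             double level) {
  IntegerVector dims = field.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (xs.size() != nx || ys.size() != ny || zs.size() != nz)
    stop("grid coordinate lengths do not match field dimensions");
  const double* f = REAL(field);
  auto node = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
  };

  MeshBuilder mb;
  double cp[8][3];
  double cf[8];
  uint64_t cid[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          cid[c] = node(ii, jj, kk);
          cf[c] = f[cid[c]];
          // nodes on (or numerically at) the iso-level produce coincident
          // duplicate vertices and degenerate, arbitrarily oriented
          // triangles; nudge them just off the level
          double band = 1e-6 * (1.0 + std::fabs(level));
          if (std::fabs(cf[c] - level) < band) cf[c] = level + band;
          cp[c][0] = xs[ii]; cp[c][1] = ys[jj]; cp[c][2] = zs[kk];
          (cf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = KUHN[t];
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (cf[T[v]] > level) in_idx[nin++] = T[v]; else out_idx[nout++] = T[v];
          }
          if (nin == 0 || nin == 4) continue;
          // gradient of the linear interpolant over this tet (Cramer's rule)
          double grad[3];
          {
            const double* q0 = cp[T[0]];
            double M[3][3], rhs[3];
            for (int r = 0; r < 3; ++r) {
              rhs[r] = cf[T[r + 1]] - cf[T[0]];
              for (int d = 0; d < 3; ++d) M[r][d] = cp[T[r + 1]][d] - q0[d];
            }
            double det = det3(M[0], M[1], M[2]);
            if (det == 0) det = 1e-300;
            double Mx[3][3], My[3][3], Mz[3][3];
            for (int r = 0; r < 3; ++r)
              for (int d = 0; d < 3; ++d) {
                Mx[r][d] = (d == 0) ? rhs[r] : M[r][d];
                My[r][d] = (d == 1) ? rhs[r] : M[r][d];
                Mz[r][d] = (d == 2) ? rhs[r] : M[r][d];
              }
            grad[0] = det3(Mx[0], Mx[1], Mx[2]) / det;
            grad[1] = det3(My[0], My[1], My[2]) / det;
            grad[2] = det3(Mz[0], Mz[1], Mz[2]) / det;
          }
          if (nin == 1) {
            int A = in_idx[0];
            int e0 = mb.edge_point(cid[A], cid[out_idx[0]], cp[A], cp[out_idx[0]], cf[A], cf[out_idx[0]], level);
            int e1 = mb.edge_point(cid[A], cid[out_idx[1]], cp[A], cp[out_idx[1]], cf[A], cf[out_idx[1]], level);
            int e2 = mb.edge_point(cid[A], cid[out_idx[2]], cp[A], cp[out_idx[2]], cf[A], cf[out_idx[2]], level);
            mb.add_tri(e0, e1, e2, grad);
          } else if (nin == 3) {
            int D = out_idx[0];
            int e0 = mb.edge_point(cid[in_idx[0]], cid[D], cp[in_idx[0]], cp[D], cf[in_idx[0]], cf[D], level);
            int e1 = mb.edge_point(cid[in_idx[1]], cid[D], cp[in_idx[1]], cp[D], cf[in_idx[1]], cf[D], level);
            int e2 = mb.edge_point(cid[in_idx[2]], cid[D], cp[in_idx[2]], cp[D], cf[in_idx[2]], cf[D], level);
            mb.add_tri(e0, e1, e2, grad);
          } else { // nin == 2: quad split into two triangles
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int q0 = mb.edge_point(cid[A], cid[C], cp[A], cp[C], cf[A], cf[C], level);
            int q1 = mb.edge_point(cid[A], cid[D], cp[A], cp[D], cf[A], cf[D], level);
            int q2 = mb.edge_point(cid[B], cid[D], cp[B], cp[D], cf[B], cf[D], level);
            int q3 = mb.edge_point(cid[B], cid[C], cp[B], cp[C], cf[B], cf[C], level);
            mb.add_tri(q0, q1, q2, grad);
            mb.add_tri(q0, q2, q3, grad);
          }
        }
      }

  int nv = (int)(mb.verts.size() / 3), nf = (int)(mb.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) V(v, d) = mb.verts[3 * v + d];
  for (int t = 0; t < nf; ++t)
    for (int d = 0; d < 3; ++d) F(t, d) = mb.faces[3 * t + d] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export(name = ".cpp_mesh_volume")]]
double cpp_mesh_volume(NumericMatrix V, IntegerMatrix F) {
  double vol = 0.0;
  for (int t = 0; t < F.nrow(); ++t) {
    double a[3], b[3], c[3];
    for (int d = 0; d < 3; ++d) {
      a[d] = V(F(t, 0) - 1, d);
      b[d] = V(F(t, 1) - 1, d);
      c[d] = V(F(t, 2) - 1, d);
    }
    vol += det3(a, b, c);
  }
  return vol / 6.0;
}

// [[Rcpp::export(name = ".cpp_vertex_normals")]]
NumericMatrix cpp_vertex_normals(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow();
  NumericMatrix N(nv, 3);
  for (int t = 0; t < F.nrow(); ++t) {
    int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    double e1[3], e2[3], n[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = V(ib, d) - V(ia, d);
      e2[d] = V(ic, d) - V(ia, d);
    }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];   // magnitude = 2*area (area weight)
    for (int d = 0; d < 3; ++d) {
      N(ia, d) += n[d]; N(ib, d) += n[d]; N(ic, d) += n[d];
    }
  }
  for (int v = 0; v < nv; ++v) {
    double m = std::sqrt(N(v,0)*N(v,0) + N(v,1)*N(v,1) + N(v,2)*N(v,2));
    if (m > 0) for (int d = 0; d < 3; ++d) N(v, d) /= m;
  }
  return N;
}

// [[Rcpp::export(name = ".cpp_vertex_areas")]]
NumericVector cpp_vertex_areas(NumericMatrix V, IntegerMatrix F) {
  NumericVector A(V.nrow());
  for (int t = 0; t < F.nrow(); ++t) {
    int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    double e1[3], e2[3], n[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = V(ib, d) - V(ia, d);
      e2[d] = V(ic, d) - V(ia, d);
    }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double area = 0.5 * std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    A[ia] += area / 3.0; A[ib] += area / 3.0; A[ic] += area / 3.0;
  }
  return A;
}

// [[Rcpp::export(name = ".cpp_edge_audit")]]
List cpp_edge_audit(IntegerMatrix F) {
  // watertight + consistently oriented iff every undirected edge is used by
  // exactly two faces, once in each direction
  std::unordered_map<uint64_t, int> fwd;
  for (int t = 0; t < F.nrow(); ++t) {
    int v[3] = {F(t,0) - 1, F(t,1) - 1, F(t,2) - 1};
    for (int e = 0; e < 3; ++e) {
      uint64_t a = v[e], b = v[(e + 1) % 3];
      fwd[(a << 32) | b]++;
    }
  }
  int boundary = 0, nonmanifold = 0;
  for (auto& kv : fwd) {
    if (kv.second > 1) nonmanifold++;
    uint64_t a = kv.first >> 32, b = kv.first & 0xffffffffULL;
    auto it = fwd.find((b << 32) | a);
    if (it == fwd.end()) boundary++;
  }
  return List::create(_["watertight"] = (boundary == 0 && nonmanifold == 0),
                      _["n_boundary_edges"] = boundary,
                      _["n_nonmanifold_edges"] = nonmanifold);
}

// [[Rcpp::export(name = ".cpp_taubin_smooth")]]
NumericMatrix cpp_taubin_smooth(NumericMatrix V, IntegerMatrix F,
                                int iterations, double lambda, double mu,
                                double z_weight, LogicalVector pin_z) {
  int nv = V.nrow();
  std::vector<std::vector<int>> adj(nv);
  for (int t = 0; t < F.nrow(); ++t) {
    int v[3] = {F(t,0) - 1, F(t,1) - 1, F(t,2) - 1};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], b = v[(e + 1) % 3];
      adj[a].push_back(b);
      adj[b].push_back(a);
    }
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> P(nv * 3), Pn(nv * 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) P[3 * v + d] = V(v, d);

  auto pass = [&](double factor) {
    for (int v = 0; v < nv; ++v) {
      if (adj[v].empty()) {
        for (int d = 0; d < 3; ++d) Pn[3*v+d] = P[3*v+d];
        continue;
      }
      double acc[3] = {0, 0, 0}, wsum = 0;
      for (int u : adj[v]) {
        double dx = P[3*u] - P[3*v], dy = P[3*u+1] - P[3*v+1], dz = P[3*u+2] - P[3*v+2];
        double len = std::sqrt(dx*dx + dy*dy + dz*dz) + 1e-12;
        double w = 1.0 + z_weight * std::fabs(dz) / len;
        wsum += w;
        acc[0] += w * dx; acc[1] += w * dy; acc[2] += w * dz;
      }
      for (int d = 0; d < 3; ++d)
        Pn[3*v+d] = P[3*v+d] + factor * acc[d] / wsum;
      if (pin_z[v]) Pn[3*v+2] = P[3*v+2];
    }
    P.swap(Pn);
  };

  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }

  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) out(v, d) = P[3 * v + d];
  return out;
}

namespace {
// Moller-Trumbore; returns t >= 0 of nearest hit along dir, or +Inf
double ray_hit(const double* o, const double* dir,
               const NumericMatrix& V, const IntegerMatrix& F) {
  double best = R_PosInf;
  const double eps = 1e-12;
  for (int t = 0; t < F.nrow(); ++t) {
    double v0[3], e1[3], e2[3];
    int ia = F(t,0) - 1, ib = F(t,1) - 1, ic = F(t,2) - 1;
    for (int d = 0; d < 3; ++d) {
      v0[d] = V(ia, d);
      e1[d] = V(ib, d) - v0[d];
      e2[d] = V(ic, d) - v0[d];
    }
    double p[3] = {dir[1]*e2[2] - dir[2]*e2[1],
                   dir[2]*e2[0] - dir[0]*e2[2],
                   dir[0]*e2[1] - dir[1]*e2[0]};
    double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
    if (std::fabs(det) < eps) continue;
    double inv = 1.0 / det;
    double s[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
    double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
    if (u < -1e-6 || u > 1 + 1e-6) continue;
    double q[3] = {s[1]*e1[2] - s[2]*e1[1],
                   s[2]*e1[0] - s[0]*e1[2],
                   s[0]*e1[1] - s[1]*e1[0]};
    double v = (dir[0]*q[0] + dir[1]*q[1] + dir[2]*q[2]) * inv;
    if (v < -1e-6 || u + v > 1 + 1e-6) continue;
    double th = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
    if (th >= -1e-9 && th < best) best = std::max(th, 0.0);
  }
  return best;
}
} // namespace

// [[Rcpp::export(name = ".cpp_ray_distances")]]
NumericMatrix cpp_ray_distances(NumericMatrix origins, NumericMatrix dirs,
                                NumericMatrix V, IntegerMatrix F) {
  // column 1: distance along +dir, column 2: distance along -dir (Inf if none)
  int n = origins.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double o[3] = {origins(i,0), origins(i,1), origins(i,2)};
    double d[3] = {dirs(i,0), dirs(i,1), dirs(i,2)};
    double dm[3] = {-d[0], -d[1], -d[2]};
    out(i, 0) = ray_hit(o, d, V, F);
    out(i, 1) = ray_hit(o, dm, V, F);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_points_in_mesh")]]
LogicalVector cpp_points_in_mesh(NumericMatrix pts, NumericMatrix V,
                                 IntegerMatrix F) {
  // ray-parity test; slightly irrational direction avoids edge-aligned rays
  int n = pts.nrow();
  LogicalVector inside(n);
  double dir[3] = {0.998277, 0.041237, 0.041731};
  for (int i = 0; i < n; ++i) {
    double o[3] = {pts(i,0), pts(i,1), pts(i,2)};
    int crossings = 0;
    const double eps = 1e-12;
    for (int t = 0; t < F.nrow(); ++t) {
      double v0[3], e1[3], e2[3];
      int ia = F(t,0) - 1, ib = F(t,1) - 1, ic = F(t,2) - 1;
      for (int d = 0; d < 3; ++d) {
        v0[d] = V(ia, d);
        e1[d] = V(ib, d) - v0[d];
        e2[d] = V(ic, d) - v0[d];
      }
      double p[3] = {dir[1]*e2[2] - dir[2]*e2[1],
                     dir[2]*e2[0] - dir[0]*e2[2],
                     dir[0]*e2[1] - dir[1]*e2[0]};
      double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double s[3] = {o[0] - v0[0], o[1] - v0[1], o[2] - v0[2]};
      double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
      if (u < 0 || u > 1) continue;
      double q[3] = {s[1]*e1[2] - s[2]*e1[1],
                     s[2]*e1[0] - s[0]*e1[2],
                     s[0]*e1[1] - s[1]*e1[0]};
      double v = (dir[0]*q[0] + dir[1]*q[1] + dir[2]*q[2]) * inv;
      if (v < 0 || u + v > 1) continue;
      double th = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
      if (th > 0) crossings++;
    }
    inside[i] = (crossings % 2) == 1;
  }
  return inside;
}

// [[Rcpp::export(name = ".cpp_polygon_sdf")]]
NumericMatrix cpp_polygon_sdf(List polys, NumericVector xs, NumericVector ys) {
  // exact signed distance from grid points to a set of closed polygons;
  // sign by even-odd rule over all polygons (negative inside material)
  int nx = xs.size(), ny = ys.size();
  NumericMatrix out(nx, ny);
  int np = polys.size();
  std::vector<NumericMatrix> P;
  for (int p = 0; p < np; ++p) P.push_back(as<NumericMatrix>(polys[p]));

  for (int j = 0; j < ny; ++j) {
    double py = ys[j];
    for (int i = 0; i < nx; ++i) {
      double px = xs[i];
      double best = R_PosInf;
      int crossings = 0;
      for (int p = 0; p < np; ++p) {
        const NumericMatrix& poly = P[p];
        int m = poly.nrow();
        for (int a = 0; a < m; ++a) {
          int b = (a + 1) % m;
          double ax = poly(a,0), ay = poly(a,1);
          double bx = poly(b,0), by = poly(b,1);
          double ex = bx - ax, ey = by - ay;
          double len2 = ex*ex + ey*ey;
          double t = len2 > 0 ? ((px-ax)*ex + (py-ay)*ey) / len2 : 0.0;
          if (t < 0) t = 0; if (t > 1) t = 1;
          double dx = px - (ax + t*ex), dy = py - (ay + t*ey);
          double d2 = dx*dx + dy*dy;
          if (d2 < best) best = d2;
          // even-odd horizontal ray crossing (half-open rule)
          if ((ay > py) != (by > py)) {
            double xint = ax + (py - ay) / (by - ay) * ex;
            if (xint > px) crossings++;
          }
        }
      }
      double d = std::sqrt(best);
      out(i, j) = (crossings % 2) ? -d : d;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_points_in_polygons")]]
LogicalVector cpp_points_in_polygons(List polys, NumericMatrix pts) {
  int n = pts.nrow(), np = polys.size();
  std::vector<NumericMatrix> P;
  for (int p = 0; p < np; ++p) P.push_back(as<NumericMatrix>(polys[p]));
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    int crossings = 0;
    for (int p = 0; p < np; ++p) {
      const NumericMatrix& poly = P[p];
      int m = poly.nrow();
      for (int a = 0; a < m; ++a) {
        int b = (a + 1) % m;
        double ay = poly(a,1), by = poly(b,1);
        if ((ay > py) != (by > py)) {
          double xint = poly(a,0) + (py - ay) / (by - ay) * (poly(b,0) - poly(a,0));
          if (xint > px) crossings++;
        }
      }
    }
    inside[i] = (crossings % 2) == 1;
  }
  return inside;
}
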