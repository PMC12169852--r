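#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Point-to-mesh closest-point queries on a uniform grid, plus a triangle-
// triangle intersection scan. Meshes are copied into flat row-major arrays
// once per call; all hot loops work on raw pointers.
// ---------------------------------------------------------------------------

// Closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection, 5.1.5). Result written to out[3].
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cpv[3];
  for (int i = 0; i < 3; ++i) cpv[i] = p[i] - c[i];
  double d5 = ab[0] * cpv[0] + ab[1] * cpv[1] + ab[2] * cpv[2];
  double d6 = ac[0] * cpv[0] + ac[1] * cpv[1] + ac[2] * cpv[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

struct FlatMesh {
  std::vector<double> v;  // nv x 3, row-major
  std::vector<int> f;     // nf x 3, row-major, 0-based
  int nv, nf;
};

static void flatten(const NumericMatrix &V, const IntegerMatrix &F,
                    FlatMesh &m) {
  m.nv = V.nrow();
  m.nf = F.nrow();
  m.v.resize((size_t)m.nv * 3);
  m.f.resize((size_t)m.nf * 3);
  for (int i = 0; i < m.nv; ++i)
    for (int d = 0; d < 3; ++d) m.v[(size_t)i * 3 + d] = V(i, d);
  for (int i = 0; i < m.nf; ++i)
    for (int d = 0; d < 3; ++d) {
      int idx = F(i, d) - 1;  // R is 1-based
      if (idx < 0 || idx >= m.nv) stop("face index out of range");
      m.f[(size_t)i * 3 + d] = idx;
    }
}

struct TriGrid {
  double lo[3];
  double h;
  int n[3];
  std::vector<int> cell_start;  // CSR offsets, ncell + 1
  std::vector<int> cell_tris;
};

static inline int cell_index(const TriGrid &g, int ix, int iy, int iz) {
  return (iz * g.n[1] + iy) * g.n[0] + ix;
}

static void build_grid(const FlatMesh &m, TriGrid &g) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < m.nv; ++i)
    for (int d = 0; d < 3; ++d) {
      double x = m.v[(size_t)i * 3 + d];
      if (x < lo[d]) lo[d] = x;
      if (x > hi[d]) hi[d] = x;
    }
  double mean_ext = 0.0;
  for (int t = 0; t < m.nf; ++t) {
    const double *a = &m.v[(size_t)m.f[(size_t)t * 3] * 3];
    const double *b = &m.v[(size_t)m.f[(size_t)t * 3 + 1] * 3];
    const double *c = &m.v[(size_t)m.f[(size_t)t * 3 + 2] * 3];
    double ext = 0.0;
    for (int d = 0; d < 3; ++d) {
      double mx = std::max(a[d], std::max(b[d], c[d]));
      double mn = std::min(a[d], std::min(b[d], c[d]));
      ext = std::max(ext, mx - mn);
    }
    mean_ext += ext;
  }
  mean_ext /= std::max(m.nf, 1);
  double h = std::max(2.0 * mean_ext, 1e-12);
  for (int d = 0; d < 3; ++d) {
    double span = std::max(hi[d] - lo[d], 1e-12);
    int nd = (int)std::ceil(span / h);
    g.n[d] = std::max(1, std::min(nd, 64));
  }
  for (int d = 0; d < 3; ++d)
    h = std::max(h, (hi[d] - lo[d]) / g.n[d] * (1.0 + 1e-9));
  g.h = h;
  for (int d = 0; d < 3; ++d) g.lo[d] = lo[d];
  int ncell = g.n[0] * g.n[1] * g.n[2];
  std::vector<int> counts(ncell, 0);
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1) {
      g.cell_start.assign(ncell + 1, 0);
      for (int c = 0; c < ncell; ++c)
        g.cell_start[c + 1] = g.cell_start[c] + counts[c];
      g.cell_tris.assign(g.cell_start[ncell], 0);
      std::fill(counts.begin(), counts.end(), 0);
    }
    for (int t = 0; t < m.nf; ++t) {
      int cmin[3], cmax[3];
      for (int d = 0; d < 3; ++d) {
        double a = m.v[(size_t)m.f[(size_t)t * 3] * 3 + d];
        double b = m.v[(size_t)m.f[(size_t)t * 3 + 1] * 3 + d];
        double c = m.v[(size_t)m.f[(size_t)t * 3 + 2] * 3 + d];
        double mx = std::max(a, std::max(b, c));
        double mn = std::min(a, std::min(b, c));
        int i0 = (int)std::floor((mn - g.lo[d]) / g.h);
        int i1 = (int)std::floor((mx - g.lo[d]) / g.h);
        cmin[d] = std::max(0, std::min(i0, g.n[d] - 1));
        cmax[d] = std::max(0, std::min(i1, g.n[d] - 1));
      }
      for (int iz = cmin[2]; iz <= cmax[2]; ++iz)
        for (int iy = cmin[1]; iy <= cmax[1]; ++iy)
          for (int ix = cmin[0]; ix <= cmax[0]; ++ix) {
            int c = cell_index(g, ix, iy, iz);
            if (pass == 0) counts[c]++;
            else g.cell_tris[g.cell_start[c] + counts[c]++] = t;
          }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix queries, NumericMatrix V,
                        IntegerMatrix F) {
  FlatMesh m;
  flatten(V, F, m);
  if (m.nf == 0) stop("target mesh has no faces");
  TriGrid g;
  build_grid(m, g);
  int nq = queries.nrow();
  NumericMatrix cp(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);
  std::vector<char> seen(m.nf, 0);
  std::vector<int> touched;
  touched.reserve(512);
  int max_shell = g.n[0] + g.n[1] + g.n[2];  // generous upper bound
  for (int q = 0; q < nq; ++q) {
    double p[3] = {queries(q, 0), queries(q, 1), queries(q, 2)};
    double d0sq = 0.0;
    int c0[3];
    for (int d = 0; d < 3; ++d) {
      double hib = g.lo[d] + g.h * g.n[d];
      double pcd = std::min(std::max(p[d], g.lo[d]), hib);
      double diff = p[d] - pcd;
      d0sq += diff * diff;
      int ci = (int)std::floor((pcd - g.lo[d]) / g.h);
      c0[d] = std::max(0, std::min(ci, g.n[d] - 1));
    }
    double best = R_PosInf;  // squared distance
    int best_f = -1;
    double best_pt[3] = {0.0, 0.0, 0.0};
    touched.clear();
    for (int r = 0; r <= max_shell; ++r) {
      // projection bound: dist(p, shell-r cell) >= sqrt(((r-1)h)^2 + d0^2)
      double lb = (r > 1) ? (r - 1) * g.h : 0.0;
      double lbsq = lb * lb + d0sq;
      if (best <= lbsq) break;
      int x0 = c0[0] - r, x1 = c0[0] + r;
      int y0 = c0[1] - r, y1 = c0[1] + r;
      int z0 = c0[2] - r, z1 = c0[2] + r;
      for (int iz = std::max(z0, 0); iz <= std::min(z1, g.n[2] - 1); ++iz)
        for (int iy = std::max(y0, 0); iy <= std::min(y1, g.n[1] - 1); ++iy)
          for (int ix = std::max(x0, 0); ix <= std::min(x1, g.n[0] - 1); ++ix) {
            int cheb = std::max(std::abs(ix - c0[0]),
                                std::max(std::abs(iy - c0[1]),
                                         std::abs(iz - c0[2])));
            if (cheb != r) continue;  // shell cells only
            int c = cell_index(g, ix, iy, iz);
            for (int k = g.cell_start[c]; k < g.cell_start[c + 1]; ++k) {
              int t = g.cell_tris[k];
              if (seen[t]) continue;
              seen[t] = 1;
              touched.push_back(t);
              const double *a = &m.v[(size_t)m.f[(size_t)t * 3] * 3];
              const double *b = &m.v[(size_t)m.f[(size_t)t * 3 + 1] * 3];
              const double *cc = &m.v[(size_t)m.f[(size_t)t * 3 + 2] * 3];
              double out[3];
              closest_on_triangle(p, a, b, cc, out);
              double dsq = 0.0;
              for (int d = 0; d < 3; ++d) {
                double diff = p[d] - out[d];
                dsq += diff * diff;
              }
              if (dsq < best) {
                best = dsq;
                best_f = t;
                for (int d = 0; d < 3; ++d) best_pt[d] = out[d];
              }
            }
          }
    }
    for (size_t i = 0; i < touched.size(); ++i) seen[touched[i]] = 0;
    for (int d = 0; d < 3; ++d) cp(q, d) = best_pt[d];
    dist[q] = std::sqrt(best);
    face[q] = best_f + 1;  // back to 1-based
  }
  return List::create(_["points"] = cp, _["dist"] = dist, _["face"] = face);
}

// ------------------------- triangle-triangle test --------------------------
// Moller (1997) interval-overlap test. Coplanar pairs are reported as
// non-intersecting (adequate for detecting genuine self-penetration).

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static bool tri_tri_overlap(const double *v0, const double *v1,
                            const double *v2, const double *u0,
                            const double *u1, const double *u2) {
  double e1[3], e2[3], n1[3];
  for (int i = 0; i < 3; ++i) { e1[i] = v1[i] - v0[i]; e2[i] = v2[i] - v0[i]; }
  cross3(e1, e2, n1);
  double d1 = -dot3(n1, v0);
  double du0 = dot3(n1, u0) + d1;
  double du1 = dot3(n1, u1) + d1;
  double du2 = dot3(n1, u2) + d1;
  double eps = 1e-12 * std::sqrt(dot3(n1, n1));
  if (std::fabs(du0) < eps) du0 = 0.0;
  if (std::fabs(du1) < eps) du1 = 0.0;
  if (std::fabs(du2) < eps) du2 = 0.0;
  if (du0 * du1 > 0.0 && du0 * du2 > 0.0) return false;

  double f1[3], f2[3], n2[3];
  for (int i = 0; i < 3; ++i) { f1[i] = u1[i] - u0[i]; f2[i] = u2[i] - u0[i]; }
  cross3(f1, f2, n2);
  double d2 = -dot3(n2, u0);
  double dv0 = dot3(n2, v0) + d2;
  double dv1 = dot3(n2, v1) + d2;
  double dv2 = dot3(n2, v2) + d2;
  double eps2 = 1e-12 * std::sqrt(dot3(n2, n2));
  if (std::fabs(dv0) < eps2) dv0 = 0.0;
  if (std::fabs(dv1) < eps2) dv1 = 0.0;
  if (std::fabs(dv2) < eps2) dv2 = 0.0;
  if (dv0 * dv1 > 0.0 && dv0 * dv2 > 0.0) return false;

  double dir[3];
  cross3(n1, n2, dir);
  double dmax = std::fabs(dir[0]);
  int axis = 0;
  if (std::fabs(dir[1]) > dmax) { dmax = std::fabs(dir[1]); axis = 1; }
  if (std::fabs(dir[2]) > dmax) { dmax = std::fabs(dir[2]); axis = 2; }
  if (dmax < 1e-300) return false;  // coplanar: ignored

  double vp0 = v0[axis], vp1 = v1[axis], vp2 = v2[axis];
  double up0 = u0[axis], up1 = u1[axis], up2 = u2[axis];

  // lone = vertex on its own side of the other plane; interval endpoints are
  // the crossings of the two edges from the lone vertex
  auto isect = [](double lone, double pa, double pb, double dl, double da,
                  double db, double *iso) {
    iso[0] = lone + (pa - lone) * dl / (dl - da);
    iso[1] = lone + (pb - lone) * dl / (dl - db);
    if (iso[0] > iso[1]) std::swap(iso[0], iso[1]);
  };
  auto interval = [&isect](double p0, double p1, double p2, double x0,
                           double x1, double x2, double *iso) -> bool {
    if (x0 * x1 > 0.0) isect(p2, p0, p1, x2, x0, x1, iso);
    else if (x0 * x2 > 0.0) isect(p1, p0, p2, x1, x0, x2, iso);
    else if (x1 * x2 > 0.0 || x0 != 0.0) isect(p0, p1, p2, x0, x1, x2, iso);
    else if (x1 != 0.0) isect(p1, p0, p2, x1, x0, x2, iso);
    else if (x2 != 0.0) isect(p2, p0, p1, x2, x0, x1, iso);
    else return false;  // coplanar: ignored
    return true;
  };
  double i1[2], i2[2];
  if (!interval(vp0, vp1, vp2, dv0, dv1, dv2, i1)) return false;
  if (!interval(up0, up1, up2, du0, du1, du2, i2)) return false;
  return i1[1] > i2[0] && i2[1] > i1[0];
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_self_intersections(NumericMatrix V, IntegerMatrix F,
                                     int max_pairs = 1000) {
  FlatMesh m;
  flatten(V, F, m);
  // triangle AABBs
  std::vector<double> bmin((size_t)m.nf * 3), bmax((size_t)m.nf * 3);
  for (int t = 0; t < m.nf; ++t)
    for (int d = 0; d < 3; ++d) {
      double a = m.v[(size_t)m.f[(size_t)t * 3] * 3 + d];
      double b = m.v[(size_t)m.f[(size_t)t * 3 + 1] * 3 + d];
      double c = m.v[(size_t)m.f[(size_t)t * 3 + 2] * 3 + d];
      bmin[(size_t)t * 3 + d] = std::min(a, std::min(b, c));
      bmax[(size_t)t * 3 + d] = std::max(a, std::max(b, c));
    }
  std::vector<int> hits;
  for (int s = 0; s < m.nf && (int)hits.size() / 2 < max_pairs; ++s) {
    const int *fs = &m.f[(size_t)s * 3];
    for (int t = s + 1; t < m.nf; ++t) {
      bool overlap = true;
      for (int d = 0; d < 3; ++d)
        if (bmin[(size_t)s * 3 + d] > bmax[(size_t)t * 3 + d] ||
            bmin[(size_t)t * 3 + d] > bmax[(size_t)s * 3 + d]) {
          overlap = false;
          break;
        }
      if (!overlap) continue;
      const int *ft = &m.f[(size_t)t * 3];
      bool shared = false;
      for (int i = 0; i < 3 && !shared; ++i)
        for (int j = 0; j < 3; ++j)
          if (fs[i] == ft[j]) { shared = true; break; }
      if (shared) continue;  // adjacent faces touch legitimately
      if (tri_tri_overlap(&m.v[(size_t)fs[0] * 3], &m.v[(size_t)fs[1] * 3],
                          &m.v[(size_t)fs[2] * 3], &m.v[(size_t)ft[0] * 3],
                          &m.v[(size_t)ft[1] * 3], &m.v[(size_t)ft[2] * 3])) {
        hits.push_back(s + 1);
        hits.push_back(t + 1);
        if ((int)hits.size() / 2 >= max_pairs) break;
      }
    }
  }
  IntegerMatrix out((int)hits.size() / 2, 2);
  for (int i = 0; i < out.nrow(); ++i) {
    out(i, 0) = hits[(size_t)i * 2];
    out(i, 1) = hits[(size_t)i * 2 + 1];
  }
  return out;
}
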