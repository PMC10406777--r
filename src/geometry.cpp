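#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- point-in-tetrahedron location with uniform spatial bins ----
//
// Barycentric coordinates inside tet (v1..v4) are obtained from the 3x3
// system M * b123 = p - v4 with M = [v1-v4 | v2-v4 | v3-v4]; b4 = 1 - sum.
// Containment: all components >= -tol. Ties on shared faces resolve to the
// lowest tet index because candidates are scanned in ascending order.

struct TetGeom {
  double inv[9];   // row-major inverse of M
  double v4[3];
  bool degenerate;
};

static void tet_precompute(const NumericMatrix& verts, const IntegerMatrix& tets,
                           std::vector<TetGeom>& geo) {
  const int T = tets.nrow();
  geo.resize(T);
  for (int t = 0; t < T; ++t) {
    double M[9];
    int i4 = tets(t, 3) - 1;
    for (int c = 0; c < 3; ++c) {
      int ic = tets(t, c) - 1;
      for (int r = 0; r < 3; ++r) M[3 * r + c] = verts(ic, r) - verts(i4, r);
    }
    double det = M[0] * (M[4] * M[8] - M[5] * M[7])
               - M[1] * (M[3] * M[8] - M[5] * M[6])
               + M[2] * (M[3] * M[7] - M[4] * M[6]);
    TetGeom g;
    g.degenerate = std::fabs(det) < 1e-12;
    if (!g.degenerate) {
      double id = 1.0 / det;
      g.inv[0] =  (M[4] * M[8] - M[5] * M[7]) * id;
      g.inv[1] = -(M[1] * M[8] - M[2] * M[7]) * id;
      g.inv[2] =  (M[1] * M[5] - M[2] * M[4]) * id;
      g.inv[3] = -(M[3] * M[8] - M[5] * M[6]) * id;
      g.inv[4] =  (M[0] * M[8] - M[2] * M[6]) * id;
      g.inv[5] = -(M[0] * M[5] - M[2] * M[3]) * id;
      g.inv[6] =  (M[3] * M[7] - M[4] * M[6]) * id;
      g.inv[7] = -(M[0] * M[7] - M[1] * M[6]) * id;
      g.inv[8] =  (M[0] * M[4] - M[1] * M[3]) * id;
    }
    for (int r = 0; r < 3; ++r) g.v4[r] = verts(i4, r);
    geo[t] = g;
  }
}

// [[Rcpp::export]]
List cpp_locate_points(NumericMatrix verts, IntegerMatrix tets,
                       NumericMatrix pts, double tol) {
  const int T = tets.nrow(), P = pts.nrow();
  IntegerVector tet_id(P, 0);
  NumericMatrix bary(P, 4);
  if (T == 0 || P == 0) return List::create(_["tet"] = tet_id, _["bary"] = bary);

  std::vector<TetGeom> geo;
  tet_precompute(verts, tets, geo);

  // mesh bounding box
  double lo[3], hi[3];
  for (int r = 0; r < 3; ++r) { lo[r] = R_PosInf; hi[r] = R_NegInf; }
  for (int v = 0; v < verts.nrow(); ++v)
    for (int r = 0; r < 3; ++r) {
      if (verts(v, r) < lo[r]) lo[r] = verts(v, r);
      if (verts(v, r) > hi[r]) hi[r] = verts(v, r);
    }
  int nb = (int)std::cbrt((double)T) + 1;
  if (nb < 1) nb = 1;
  if (nb > 64) nb = 64;
  double bw[3];
  for (int r = 0; r < 3; ++r) {
    double ext = hi[r] - lo[r];
    bw[r] = (ext > 0) ? ext / nb : 1.0;
  }
  auto bin_of = [&](double x, int axis) {
    int b = (int)std::floor((x - lo[axis]) / bw[axis]);
    if (b < 0) b = 0;
    if (b >= nb) b = nb - 1;
    return b;
  };
  std::vector< std::vector<int> > bins(nb * nb * nb);
  for (int t = 0; t < T; ++t) {
    double tlo[3], thi[3];
    for (int r = 0; r < 3; ++r) { tlo[r] = R_PosInf; thi[r] = R_NegInf; }
    for (int c = 0; c < 4; ++c) {
      int iv = tets(t, c) - 1;
      for (int r = 0; r < 3; ++r) {
        double x = verts(iv, r);
        if (x < tlo[r]) tlo[r] = x;
        if (x > thi[r]) thi[r] = x;
      }
    }
    int b0[3], b1[3];
    for (int r = 0; r < 3; ++r) { b0[r] = bin_of(tlo[r], r); b1[r] = bin_of(thi[r], r); }
    for (int bz = b0[2]; bz <= b1[2]; ++bz)
      for (int by = b0[1]; by <= b1[1]; ++by)
        for (int bx = b0[0]; bx <= b1[0]; ++bx)
          bins[(bz * nb + by) * nb + bx].push_back(t);
  }
  // candidates were pushed in ascending tet order, so each bin is sorted
  for (int p = 0; p < P; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < lo[0] - tol || x > hi[0] + tol || y < lo[1] - tol || y > hi[1] + tol ||
        z < lo[2] - tol || z > hi[2] + tol) continue;
    const std::vector<int>& cand =
      bins[(bin_of(z, 2) * nb + bin_of(y, 1)) * nb + bin_of(x, 0)];
    for (size_t c = 0; c < cand.size(); ++c) {
      const TetGeom& g = geo[cand[c]];
      if (g.degenerate) continue;
      double d0 = x - g.v4[0], d1 = y - g.v4[1], d2 = z - g.v4[2];
      double b1_ = g.inv[0] * d0 + g.inv[1] * d1 + g.inv[2] * d2;
      if (b1_ < -tol || b1_ > 1 + tol) continue;
      double b2_ = g.inv[3] * d0 + g.inv[4] * d1 + g.inv[5] * d2;
      if (b2_ < -tol) continue;
      double b3_ = g.inv[6] * d0 + g.inv[7] * d1 + g.inv[8] * d2;
      if (b3_ < -tol) continue;
      double b4_ = 1.0 - b1_ - b2_ - b3_;
      if (b4_ < -tol) continue;
      tet_id[p] = cand[c] + 1;
      bary(p, 0) = b1_; bary(p, 1) = b2_; bary(p, 2) = b3_; bary(p, 3) = b4_;
      break;
    }
  }
  return List::create(_["tet"] = tet_id, _["bary"] = bary);
}

// exhaustive variant used to validate the binned search
// [[Rcpp::export]]
List cpp_locate_points_bruteforce(NumericMatrix verts, IntegerMatrix tets,
                                  NumericMatrix pts, double tol) {
  const int T = tets.nrow(), P = pts.nrow();
  IntegerVector tet_id(P, 0);
  NumericMatrix bary(P, 4);
  std::vector<TetGeom> geo;
  tet_precompute(verts, tets, geo);
  for (int p = 0; p < P; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    for (int t = 0; t < T; ++t) {
      const TetGeom& g = geo[t];
      if (g.degenerate) continue;
      double d0 = x - g.v4[0], d1 = y - g.v4[1], d2 = z - g.v4[2];
      double b1_ = g.inv[0] * d0 + g.inv[1] * d1 + g.inv[2] * d2;
      double b2_ = g.inv[3] * d0 + g.inv[4] * d1 + g.inv[5] * d2;
      double b3_ = g.inv[6] * d0 + g.inv[7] * d1 + g.inv[8] * d2;
      double b4_ = 1.0 - b1_ - b2_ - b3_;
      if (b1_ >= -tol && b2_ >= -tol && b3_ >= -tol && b4_ >= -tol) {
        tet_id[p] = t + 1;
        bary(p, 0) = b1_; bary(p, 1) = b2_; bary(p, 2) = b3_; bary(p, 3) = b4_;
        break;
      }
    }
  }
  return List::create(_["tet"] = tet_id, _["bary"] = bary);
}

// ---- exact Euclidean feature transform (Felzenszwalb-Huttenlocher) ----
//
// For every voxel, squared physical distance to the nearest "site" voxel
// center and the linear index (0-based) of that site. Separable per-axis
// lower-envelope-of-parabolas passes with feature index propagation; exact
// for anisotropic spacing.

static void ft_1d(const std::vector<double>& f, const std::vector<int>& feat_in,
                  double step, int n,
                  std::vector<double>& d, std::vector<int>& feat_out,
                  std::vector<int>& v, std::vector<double>& zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * step;
    if (k < 0) {
      k = 0; v[0] = q; zbuf[0] = -INF; zbuf[1] = INF;
    } else {
      double s;
      while (true) {
        int p = v[k];
        double xp = p * step;
        s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * xq - 2 * xp);
        if (s <= zbuf[k]) { --k; if (k < 0) break; } else break;
      }
      ++k;
      v[k] = q; zbuf[k] = s; zbuf[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) { d[q] = INF; feat_out[q] = -1; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (zbuf[j + 1] < xq) ++j;
    double dx = xq - v[j] * step;
    d[q] = dx * dx + f[v[j]];
    feat_out[q] = feat_in[v[j]];
  }
}

// [[Rcpp::export]]
List cpp_feature_transform(LogicalVector site, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  std::vector<int> F(n);
  bool any_site = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (site[i]) { D[i] = 0.0; F[i] = (int)i; any_site = true; }
    else { D[i] = INF; F[i] = -1; }
  }
  if (!any_site) stop("feature transform: no site voxels");
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dline(nmax), zbuf(nmax + 1);
  std::vector<int> fin(nmax), fout(nmax), v(nmax);
  // x-axis
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) { f[x] = D[base + x]; fin[x] = F[base + x]; }
      ft_1d(f, fin, spacing[0], nx, dline, fout, v, zbuf);
      for (int x = 0; x < nx; ++x) { D[base + x] = dline[x]; F[base + x] = fout[x]; }
    }
  // y-axis
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) { f[y] = D[base + (R_xlen_t)y * nx]; fin[y] = F[base + (R_xlen_t)y * nx]; }
      ft_1d(f, fin, spacing[1], ny, dline, fout, v, zbuf);
      for (int y = 0; y < ny; ++y) { D[base + (R_xlen_t)y * nx] = dline[y]; F[base + (R_xlen_t)y * nx] = fout[y]; }
    }
  // z-axis
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) { f[z] = D[base + z * nxy]; fin[z] = F[base + z * nxy]; }
      ft_1d(f, fin, spacing[2], nz, dline, fout, v, zbuf);
      for (int z = 0; z < nz; ++z) { D[base + z * nxy] = dline[z]; F[base + z * nxy] = fout[z]; }
    }
  NumericVector dist2(n);
  IntegerVector feat(n);
  for (R_xlen_t i = 0; i < n; ++i) { dist2[i] = D[i]; feat[i] = F[i] + 1; } // 1-based
  return List::create(_["dist2"] = dist2, _["feat"] = feat);
}

// ---- trilinear sampling at continuous 0-based index coordinates ----

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector data, IntegerVector dim,
                            NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int P = pts.nrow();
  NumericVector out(P);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double eps = 1e-6;  // voxel units; boundary centers stay in-field
  for (int p = 0; p < P; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!(x >= -eps && x <= nx - 1 + eps && y >= -eps && y <= ny - 1 + eps &&
          z >= -eps && z <= nz - 1 + eps)) {
      out[p] = fill;
      continue;
    }
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--; if (y0 == ny - 1) y0--; if (z0 == nz - 1) z0--;
    if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1, z1 = (nz == 1) ? z0 : z0 + 1;
    if (nx == 1) fx = 0; if (ny == 1) fy = 0; if (nz == 1) fz = 0;
    double c000 = data[z0 * nxy + (R_xlen_t)y0 * nx + x0];
    double c100 = data[z0 * nxy + (R_xlen_t)y0 * nx + x1];
    double c010 = data[z0 * nxy + (R_xlen_t)y1 * nx + x0];
    double c110 = data[z0 * nxy + (R_xlen_t)y1 * nx + x1];
    double c001 = data[z1 * nxy + (R_xlen_t)y0 * nx + x0];
    double c101 = data[z1 * nxy + (R_xlen_t)y0 * nx + x1];
    double c011 = data[z1 * nxy + (R_xlen_t)y1 * nx + x0];
    double c111 = data[z1 * nxy + (R_xlen_t)y1 * nx + x1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    out[p] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
  }
  return out;
}

// ---- thin-plate spline evaluation, 3D biharmonic kernel U(r) = r ----

// [[Rcpp::export]]
NumericMatrix cpp_tps_apply(NumericMatrix pts, NumericMatrix src,
                            NumericMatrix A, NumericMatrix W) {
  const int P = pts.nrow(), L = src.nrow();
  NumericMatrix out(P, 3);
  for (int p = 0; p < P; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double o0 = A(0, 0) + A(1, 0) * x + A(2, 0) * y + A(3, 0) * z;
    double o1 = A(0, 1) + A(1, 1) * x + A(2, 1) * y + A(3, 1) * z;
    double o2 = A(0, 2) + A(1, 2) * x + A(2, 2) * y + A(3, 2) * z;
    for (int l = 0; l < L; ++l) {
      double dx = x - src(l, 0), dy = y - src(l, 1), dz = z - src(l, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      o0 += W(l, 0) * r; o1 += W(l, 1) * r; o2 += W(l, 2) * r;
    }
    out(p, 0) = o0; out(p, 1) = o1; out(p, 2) = o2;
  }
  return out;
}

// ---- deterministic farthest-point sampling ----

// [[Rcpp::export]]
IntegerVector cpp_farthest_points(NumericMatrix coords, int count, int start) {
  const int n = coords.nrow();
  IntegerVector sel(count);
  std::vector<double> mind(n, std::numeric_limits<double>::infinity());
  int cur = start - 1;
  for (int s = 0; s < count; ++s) {
    sel[s] = cur + 1;
    double cx = coords(cur, 0), cy = coords(cur, 1), cz = coords(cur, 2);
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      double dx = coords(i, 0) - cx, dy = coords(i, 1) - cy, dz = coords(i, 2) - cz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > bestd) { bestd = mind[i]; best = i; }
    }
    cur = best;
  }
  return sel;
}
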