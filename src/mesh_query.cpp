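// Spatially-indexed closest-point queries on a triangle soup, with
// angle-weighted pseudonormals for the sign of point-to-surface distances,
// and a column-parity rasterisation used as an independent volume oracle.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline void normalize3(double* a) {
  double n = norm3(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}

// Region codes for the closest point on a triangle:
// 0 = face interior, 1/2/3 = vertex a/b/c, 4 = edge ab, 5 = edge bc, 6 = edge ca.
static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out, int& region) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2]; region = 1; return;
  }
  double bp[3]; sub3(p, b, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) {
    out[0] = b[0]; out[1] = b[1]; out[2] = b[2]; region = 2; return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double t = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ab[k];
    region = 4; return;
  }
  double cp[3]; sub3(p, c, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) {
    out[0] = c[0]; out[1] = c[1]; out[2] = c[2]; region = 3; return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double t = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + t * ac[k];
    region = 6; return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + t * (c[k] - b[k]);
    region = 5; return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  region = 0;
}

struct MeshIndex {
  int nv, nf;
  const double* V;          // 3 x nv column-major from R (nv x 3 matrix)
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::vector<double> fn;   // face normals, 3 per face
  std::vector<double> vn;   // angle-weighted vertex pseudonormals
  std::unordered_map<long long, int> edge_id;
  std::vector<double> en;   // edge pseudonormals
  // uniform grid
  double x0, y0, z0, cell;
  int nx, ny, nz;
  std::vector<int> cell_start;  // CSR
  std::vector<int> cell_tris;
};

static long long ekey(int i, int j) {
  if (i > j) std::swap(i, j);
  return (long long)i * 0x100000000LL + j;
}

static void build_index(const NumericMatrix& V, const IntegerMatrix& F,
                        MeshIndex& M) {
  M.nv = V.nrow(); M.nf = F.nrow();
  M.vx.resize(M.nv); M.vy.resize(M.nv); M.vz.resize(M.nv);
  for (int i = 0; i < M.nv; ++i) {
    M.vx[i] = V(i, 0); M.vy[i] = V(i, 1); M.vz[i] = V(i, 2);
  }
  M.fa.resize(M.nf); M.fb.resize(M.nf); M.fc.resize(M.nf);
  for (int f = 0; f < M.nf; ++f) {
    M.fa[f] = F(f, 0) - 1; M.fb[f] = F(f, 1) - 1; M.fc[f] = F(f, 2) - 1;
  }
  M.fn.assign(3 * M.nf, 0.0);
  M.vn.assign(3 * M.nv, 0.0);
  M.en.clear(); M.edge_id.clear();
  for (int f = 0; f < M.nf; ++f) {
    int ia = M.fa[f], ib = M.fb[f], ic = M.fc[f];
    double a[3] = {M.vx[ia], M.vy[ia], M.vz[ia]};
    double b[3] = {M.vx[ib], M.vy[ib], M.vz[ib]};
    double c[3] = {M.vx[ic], M.vy[ic], M.vz[ic]};
    double ab[3], ac[3], n[3];
    sub3(b, a, ab); sub3(c, a, ac); cross3(ab, ac, n);
    normalize3(n);
    M.fn[3 * f] = n[0]; M.fn[3 * f + 1] = n[1]; M.fn[3 * f + 2] = n[2];
    // angle weights at each corner
    int idx[3] = {ia, ib, ic};
    for (int k = 0; k < 3; ++k) {
      const double* p0 = (k == 0) ? a : (k == 1) ? b : c;
      const double* p1 = (k == 0) ? b : (k == 1) ? c : a;
      const double* p2 = (k == 0) ? c : (k == 1) ? a : b;
      double e1[3], e2[3];
      sub3(p1, p0, e1); sub3(p2, p0, e2);
      double n1 = norm3(e1), n2 = norm3(e2);
      double cs = (n1 > 0 && n2 > 0) ? dot3(e1, e2) / (n1 * n2) : 1.0;
      cs = std::max(-1.0, std::min(1.0, cs));
      double ang = std::acos(cs);
      for (int d = 0; d < 3; ++d) M.vn[3 * idx[k] + d] += ang * n[d];
    }
    int eia[3] = {ia, ib, ic}, eib[3] = {ib, ic, ia};
    for (int k = 0; k < 3; ++k) {
      long long key = ekey(eia[k], eib[k]);
      auto it = M.edge_id.find(key);
      int id;
      if (it == M.edge_id.end()) {
        id = (int)(M.en.size() / 3);
        M.edge_id[key] = id;
        M.en.push_back(0.0); M.en.push_back(0.0); M.en.push_back(0.0);
      } else id = it->second;
      for (int d = 0; d < 3; ++d) M.en[3 * id + d] += n[d];
    }
  }
  for (int i = 0; i < M.nv; ++i) normalize3(&M.vn[3 * i]);
  for (size_t e = 0; e < M.en.size() / 3; ++e) normalize3(&M.en[3 * e]);

  // uniform grid sized so a triangle typically spans one cell
  double lo[3] = {M.vx[0], M.vy[0], M.vz[0]};
  double hi[3] = {M.vx[0], M.vy[0], M.vz[0]};
  for (int i = 1; i < M.nv; ++i) {
    lo[0] = std::min(lo[0], M.vx[i]); hi[0] = std::max(hi[0], M.vx[i]);
    lo[1] = std::min(lo[1], M.vy[i]); hi[1] = std::max(hi[1], M.vy[i]);
    lo[2] = std::min(lo[2], M.vz[i]); hi[2] = std::max(hi[2], M.vz[i]);
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diag <= 0) diag = 1.0;
  double mean_ext = 0.0;
  for (int f = 0; f < M.nf; ++f) {
    int ia = M.fa[f], ib = M.fb[f], ic = M.fc[f];
    for (int d = 0; d < 3; ++d) {
      const std::vector<double>& vv = (d == 0) ? M.vx : (d == 1) ? M.vy : M.vz;
      double mn = std::min(vv[ia], std::min(vv[ib], vv[ic]));
      double mx = std::max(vv[ia], std::max(vv[ib], vv[ic]));
      mean_ext = std::max(mean_ext, 0.0);
      mean_ext += (mx - mn) / (3.0 * M.nf);
    }
  }
  M.cell = std::max(std::max(mean_ext, diag / 128.0), 1e-9);
  M.x0 = lo[0] - 0.5 * M.cell; M.y0 = lo[1] - 0.5 * M.cell; M.z0 = lo[2] - 0.5 * M.cell;
  M.nx = std::max(1, (int)std::floor((hi[0] - M.x0) / M.cell) + 1);
  M.ny = std::max(1, (int)std::floor((hi[1] - M.y0) / M.cell) + 1);
  M.nz = std::max(1, (int)std::floor((hi[2] - M.z0) / M.cell) + 1);
  long long ncell = (long long)M.nx * M.ny * M.nz;
  std::vector<int> counts(ncell + 1, 0);
  auto cell_range = [&](int f, int& ix0, int& ix1, int& iy0, int& iy1,
                        int& iz0, int& iz1) {
    int ia = M.fa[f], ib = M.fb[f], ic = M.fc[f];
    double mnx = std::min(M.vx[ia], std::min(M.vx[ib], M.vx[ic]));
    double mxx = std::max(M.vx[ia], std::max(M.vx[ib], M.vx[ic]));
    double mny = std::min(M.vy[ia], std::min(M.vy[ib], M.vy[ic]));
    double mxy = std::max(M.vy[ia], std::max(M.vy[ib], M.vy[ic]));
    double mnz = std::min(M.vz[ia], std::min(M.vz[ib], M.vz[ic]));
    double mxz = std::max(M.vz[ia], std::max(M.vz[ib], M.vz[ic]));
    ix0 = std::max(0, std::min(M.nx - 1, (int)((mnx - M.x0) / M.cell)));
    ix1 = std::max(0, std::min(M.nx - 1, (int)((mxx - M.x0) / M.cell)));
    iy0 = std::max(0, std::min(M.ny - 1, (int)((mny - M.y0) / M.cell)));
    iy1 = std::max(0, std::min(M.ny - 1, (int)((mxy - M.y0) / M.cell)));
    iz0 = std::max(0, std::min(M.nz - 1, (int)((mnz - M.z0) / M.cell)));
    iz1 = std::max(0, std::min(M.nz - 1, (int)((mxz - M.z0) / M.cell)));
  };
  for (int f = 0; f < M.nf; ++f) {
    int ix0, ix1, iy0, iy1, iz0, iz1;
    cell_range(f, ix0, ix1, iy0, iy1, iz0, iz1);
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix)
          counts[(long long)ix + M.nx * ((long long)iy + (long long)M.ny * iz) + 1]++;
  }
  for (long long i = 0; i < ncell; ++i) counts[i + 1] += counts[i];
  M.cell_start.assign(counts.begin(), counts.end());
  M.cell_tris.assign(counts[ncell], 0);
  std::vector<int> fill(counts.begin(), counts.end() - 1);
  for (int f = 0; f < M.nf; ++f) {
    int ix0, ix1, iy0, iy1, iz0, iz1;
    cell_range(f, ix0, ix1, iy0, iy1, iz0, iz1);
    for (int iz = iz0; iz <= iz1; ++iz)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int ix = ix0; ix <= ix1; ++ix) {
          long long cc = (long long)ix + M.nx * ((long long)iy + (long long)M.ny * iz);
          M.cell_tris[fill[cc]++] = f;
        }
  }
}

// Closest point on the surface for each query row of Q.
// Returns the foot point, unsigned distance, nearest face (1-based) and the
// sign of the offset against the surface pseudonormal at the foot point.
// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  MeshIndex M;
  build_index(V, F, M);
  int nq = Q.nrow();
  NumericMatrix P(nq, 3), NN(nq, 3);
  NumericVector dist(nq), sgn(nq);
  IntegerVector tri(nq);
  std::vector<int> stamp((size_t)M.nf, -1);
  int max_ring = std::max(M.nx, std::max(M.ny, M.nz)) + 1;

  for (int q = 0; q < nq; ++q) {
    double p[3] = {Q(q, 0), Q(q, 1), Q(q, 2)};
    int cx = std::max(0, std::min(M.nx - 1, (int)((p[0] - M.x0) / M.cell)));
    int cy = std::max(0, std::min(M.ny - 1, (int)((p[1] - M.y0) / M.cell)));
    int cz = std::max(0, std::min(M.nz - 1, (int)((p[2] - M.z0) / M.cell)));
    double best = R_PosInf, bestp[3] = {0, 0, 0};
    int bestf = -1, bestreg = 0;
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (bestf >= 0 && (double)(ring - 1) * M.cell > best) break;
      int ix0 = std::max(0, cx - ring), ix1 = std::min(M.nx - 1, cx + ring);
      int iy0 = std::max(0, cy - ring), iy1 = std::min(M.ny - 1, cy + ring);
      int iz0 = std::max(0, cz - ring), iz1 = std::min(M.nz - 1, cz + ring);
      for (int iz = iz0; iz <= iz1; ++iz)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int ix = ix0; ix <= ix1; ++ix) {
            // only the shell of the ring
            if (ring > 0 &&
                std::abs(ix - cx) != ring && std::abs(iy - cy) != ring &&
                std::abs(iz - cz) != ring) continue;
            long long cc = (long long)ix + M.nx * ((long long)iy + (long long)M.ny * iz);
            for (int s = M.cell_start[cc]; s < M.cell_start[cc + 1]; ++s) {
              int f = M.cell_tris[s];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              int ia = M.fa[f], ib = M.fb[f], ic = M.fc[f];
              double a[3] = {M.vx[ia], M.vy[ia], M.vz[ia]};
              double b[3] = {M.vx[ib], M.vy[ib], M.vz[ib]};
              double c[3] = {M.vx[ic], M.vy[ic], M.vz[ic]};
              double cp[3]; int reg;
              closest_pt_triangle(p, a, b, c, cp, reg);
              double d[3]; sub3(p, cp, d);
              double dd = norm3(d);
              if (dd < best) {
                best = dd; bestf = f; bestreg = reg;
                bestp[0] = cp[0]; bestp[1] = cp[1]; bestp[2] = cp[2];
              }
            }
          }
      if (bestf >= 0 && ring == max_ring) break;
    }
    const double* n = &M.fn[3 * bestf];
    int ia = M.fa[bestf], ib = M.fb[bestf], ic = M.fc[bestf];
    if (bestreg == 1) n = &M.vn[3 * ia];
    else if (bestreg == 2) n = &M.vn[3 * ib];
    else if (bestreg == 3) n = &M.vn[3 * ic];
    else if (bestreg >= 4) {
      long long key = (bestreg == 4) ? ekey(ia, ib)
                    : (bestreg == 5) ? ekey(ib, ic) : ekey(ic, ia);
      n = &M.en[3 * M.edge_id[key]];
    }
    double off[3] = {p[0] - bestp[0], p[1] - bestp[1], p[2] - bestp[2]};
    P(q, 0) = bestp[0]; P(q, 1) = bestp[1]; P(q, 2) = bestp[2];
    NN(q, 0) = n[0]; NN(q, 1) = n[1]; NN(q, 2) = n[2];
    dist[q] = best;
    sgn[q] = (dot3(off, n) >= 0.0) ? 1.0 : -1.0;
    tri[q] = bestf + 1;
  }
  return List::create(_["point"] = P, _["distance"] = dist,
                      _["sign"] = sgn, _["face"] = tri,
                      _["normal"] = NN);
}

// Independent volume oracle: rasterise the closed surface into vertical
// columns on an h x h grid, pair the z-crossings by parity, integrate.
// [[Rcpp::export(name = ".cpp_column_volume")]]
double cpp_column_volume(NumericMatrix V, IntegerMatrix F, double h) {
  int nv = V.nrow(), nf = F.nrow();
  if (nv == 0 || nf == 0) return 0.0;
  double mnx = V(0, 0), mxx = V(0, 0), mny = V(0, 1), mxy = V(0, 1);
  for (int i = 1; i < nv; ++i) {
    mnx = std::min(mnx, V(i, 0)); mxx = std::max(mxx, V(i, 0));
    mny = std::min(mny, V(i, 1)); mxy = std::max(mxy, V(i, 1));
  }
  // fixed fractional offset keeps column centres off mesh edges
  double x0 = mnx - 0.2371870 * h, y0 = mny - 0.3141593 * h;
  int nx = (int)std::floor((mxx - x0) / h) + 1;
  int ny = (int)std::floor((mxy - y0) / h) + 1;
  std::vector<std::vector<double> > cols((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    double ax = V(ia, 0), ay = V(ia, 1), az = V(ia, 2);
    double bx = V(ib, 0), by = V(ib, 1), bz = V(ib, 2);
    double cx = V(ic, 0), cy = V(ic, 1), cz = V(ic, 2);
    double denom = (bx - ax) * (cy - ay) - (cx - ax) * (by - ay);
    double scale = std::max(std::abs(bx - ax) + std::abs(cx - ax),
                            std::abs(by - ay) + std::abs(cy - ay));
    if (std::abs(denom) < 1e-13 * scale * scale) continue;  // vertical face
    double tmnx = std::min(ax, std::min(bx, cx)), tmxx = std::max(ax, std::max(bx, cx));
    double tmny = std::min(ay, std::min(by, cy)), tmxy = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::ceil((tmnx - x0) / h - 0.5));
    int i1 = std::min(nx - 1, (int)std::floor((tmxx - x0) / h - 0.5));
    int j0 = std::max(0, (int)std::ceil((tmny - y0) / h - 0.5));
    int j1 = std::min(ny - 1, (int)std::floor((tmxy - y0) / h - 0.5));
    for (int j = j0; j <= j1; ++j) {
      double py = y0 + (j + 0.5) * h;
      for (int i = i0; i <= i1; ++i) {
        double px = x0 + (i + 0.5) * h;
        double wb = ((px - ax) * (cy - ay) - (cx - ax) * (py - ay)) / denom;
        double wc = ((bx - ax) * (py - ay) - (px - ax) * (by - ay)) / denom;
        double wa = 1.0 - wb - wc;
        if (wa < -1e-12 || wb < -1e-12 || wc < -1e-12) continue;
        cols[(size_t)i + (size_t)nx * j].push_back(wa * az + wb * bz + wc * cz);
      }
    }
  }
  double vol = 0.0;
  for (size_t cidx = 0; cidx < cols.size(); ++cidx) {
    std::vector<double>& z = cols[cidx];
    if (z.size() < 2) continue;
    std::sort(z.begin(), z.end());
    size_t npair = z.size() / 2;
    for (size_t k = 0; k < npair; ++k) vol += z[2 * k + 1] - z[2 * k];
  }
  return vol * h * h;
}
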