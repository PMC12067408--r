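// Isosurface extraction (marching tetrahedra on a 6-tet cube decomposition,
// shared main diagonal so shared-face diagonals agree between neighbouring
// cells -> watertight meshes), closest-point projection onto a triangle
// soup, and 6-connected component labelling.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cube corners, bit layout (dx, dy, dz)
static const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
// six tetrahedra sharing the c0-c6 diagonal
static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                               {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_map;
};

// [[Rcpp::export]]
List cpp_marching_tetra(const arma::cube& field, double iso,
                        const arma::vec& spacing, const arma::vec& origin) {
  const int nx = field.n_rows, ny = field.n_cols, nz = field.n_slices;
  MeshAcc m;
  const uint64_t NG = (uint64_t)nx * ny * nz;
  auto gid = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  auto val = [&](int i, int j, int k) {
    double v = field(i, j, k) - iso;
    if (std::fabs(v) < 1e-12) v = 1e-12;  // avoid degenerate on-node crossings
    return v;
  };
  auto edge_vertex = [&](int ia, int ja, int ka, double va, int ib, int jb,
                         int kb, double vb) -> int {
    uint64_t ga = gid(ia, ja, ka), gb = gid(ib, jb, kb);
    uint64_t key = ga < gb ? ga * NG + gb : gb * NG + ga;
    auto it = m.edge_map.find(key);
    if (it != m.edge_map.end()) return it->second;
    double s = va / (va - vb);
    double x = origin(0) + (ia + s * (ib - ia)) * spacing(0);
    double y = origin(1) + (ja + s * (jb - ja)) * spacing(1);
    double z = origin(2) + (ka + s * (kb - ka)) * spacing(2);
    int id = (int)m.vx.size();
    m.vx.push_back(x);
    m.vy.push_back(y);
    m.vz.push_back(z);
    m.edge_map.emplace(key, id);
    return id;
  };
  int ci[4], cj[4], ck[4];
  double cv[4];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // skip cells with no crossing
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          double v = val(i + CX[c], j + CY[c], k + CZ[c]);
          if (v < 0) any_neg = true; else any_pos = true;
        }
        if (!any_neg || !any_pos) continue;
        for (int tt = 0; tt < 6; ++tt) {
          int inside[4], outside[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[tt][c];
            ci[c] = i + CX[cc];
            cj[c] = j + CY[cc];
            ck[c] = k + CZ[cc];
            cv[c] = val(ci[c], cj[c], ck[c]);
            if (cv[c] < 0) inside[nin++] = c; else outside[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          auto ev = [&](int a, int b) {
            return edge_vertex(ci[a], cj[a], ck[a], cv[a], ci[b], cj[b], ck[b],
                               cv[b]);
          };
          auto emit = [&](int v0, int v1, int v2, int in_idx) {
            // orient: normal away from the inside corner
            double ax = m.vx[v1] - m.vx[v0], ay = m.vy[v1] - m.vy[v0],
                   az = m.vz[v1] - m.vz[v0];
            double bx = m.vx[v2] - m.vx[v0], by = m.vy[v2] - m.vy[v0],
                   bz = m.vz[v2] - m.vz[v0];
            double nxn = ay * bz - az * by, nyn = az * bx - ax * bz,
                   nzn = ax * by - ay * bx;
            double px = origin(0) + ci[in_idx] * spacing(0) - m.vx[v0];
            double py = origin(1) + cj[in_idx] * spacing(1) - m.vy[v0];
            double pz = origin(2) + ck[in_idx] * spacing(2) - m.vz[v0];
            if (nxn * px + nyn * py + nzn * pz > 0) std::swap(v1, v2);
            m.tri.push_back(v0);
            m.tri.push_back(v1);
            m.tri.push_back(v2);
          };
          if (nin == 1) {
            int a = inside[0];
            emit(ev(a, outside[0]), ev(a, outside[1]), ev(a, outside[2]), a);
          } else if (nin == 3) {
            int a = outside[0];
            emit(ev(inside[0], a), ev(inside[1], a), ev(inside[2], a),
                 inside[0]);
          } else {  // nin == 2: quad -> two triangles
            int a = inside[0], b = inside[1], c = outside[0], d = outside[1];
            int vac = ev(a, c), vad = ev(a, d), vbc = ev(b, c), vbd = ev(b, d);
            emit(vac, vad, vbd, a);
            emit(vac, vbd, vbc, a);
          }
        }
      }
  int nv = (int)m.vx.size(), nt = (int)m.tri.size() / 3;
  arma::mat V(nv, 3);
  for (int q = 0; q < nv; ++q) {
    V(q, 0) = m.vx[q];
    V(q, 1) = m.vy[q];
    V(q, 2) = m.vz[q];
  }
  arma::imat F(nt, 3);
  for (int q = 0; q < nt; ++q) {
    F(q, 0) = m.tri[3 * q] + 1;  // 1-based for R
    F(q, 1) = m.tri[3 * q + 1] + 1;
    F(q, 2) = m.tri[3 * q + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// closest point on a triangle (Eberly-style region walk)
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Nearest point on a triangle soup for each query, via a uniform grid over
// triangle bounding boxes with expanding-shell search.
// [[Rcpp::export]]
List cpp_project_points(const arma::mat& pts, const arma::mat& V,
                        const arma::imat& F) {
  const int nt = F.n_rows, np = pts.n_rows;
  arma::vec lo = arma::min(V, 0).t(), hi = arma::max(V, 0).t();
  // mean triangle edge length sets the cell size
  double esum = 0;
  for (int q = 0; q < std::min(nt, 2000); ++q) {
    arma::rowvec a = V.row(F(q, 0) - 1), b = V.row(F(q, 1) - 1);
    esum += arma::norm(a - b, 2);
  }
  double cell = std::max(1e-6, 2.0 * esum / std::min(nt, 2000));
  int gx = std::max(1, std::min(128, (int)std::ceil((hi(0) - lo(0)) / cell)));
  int gy = std::max(1, std::min(128, (int)std::ceil((hi(1) - lo(1)) / cell)));
  int gz = std::max(1, std::min(128, (int)std::ceil((hi(2) - lo(2)) / cell)));
  double cx = (hi(0) - lo(0)) / gx + 1e-12, cy = (hi(1) - lo(1)) / gy + 1e-12,
         cz = (hi(2) - lo(2)) / gz + 1e-12;
  std::vector<std::vector<int>> bins((size_t)gx * gy * gz);
  auto bin_of = [&](double x, double y, double z, int& bi, int& bj, int& bk) {
    bi = (int)std::floor((x - lo(0)) / cx);
    bj = (int)std::floor((y - lo(1)) / cy);
    bk = (int)std::floor((z - lo(2)) / cz);
    bi = std::max(0, std::min(gx - 1, bi));
    bj = std::max(0, std::min(gy - 1, bj));
    bk = std::max(0, std::min(gz - 1, bk));
  };
  for (int q = 0; q < nt; ++q) {
    arma::rowvec a = V.row(F(q, 0) - 1), b = V.row(F(q, 1) - 1),
                 c = V.row(F(q, 2) - 1);
    int i0, j0, k0, i1, j1, k1;
    bin_of(std::min({a(0), b(0), c(0)}), std::min({a(1), b(1), c(1)}),
           std::min({a(2), b(2), c(2)}), i0, j0, k0);
    bin_of(std::max({a(0), b(0), c(0)}), std::max({a(1), b(1), c(1)}),
           std::max({a(2), b(2), c(2)}), i1, j1, k1);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i)
          bins[(size_t)i + (size_t)gx * (j + (size_t)gy * k)].push_back(q);
  }
  arma::mat proj(np, 3);
  arma::vec dist(np);
  arma::ivec tri(np);
  double best[3], cand[3];
  for (int p = 0; p < np; ++p) {
    double px[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    int bi, bj, bk;
    bin_of(px[0], px[1], px[2], bi, bj, bk);
    double bestd = INFINITY;
    int bestt = -1;
    int max_ring = std::max({gx, gy, gz});
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once a hit exists, finish the ring that guarantees correctness
      if (bestt >= 0) {
        double safe = (ring - 1) * std::min({cx, cy, cz});
        if (safe > std::sqrt(bestd)) break;
      }
      for (int k = bk - ring; k <= bk + ring; ++k) {
        if (k < 0 || k >= gz) continue;
        for (int j = bj - ring; j <= bj + ring; ++j) {
          if (j < 0 || j >= gy) continue;
          for (int i = bi - ring; i <= bi + ring; ++i) {
            if (i < 0 || i >= gx) continue;
            if (std::max({std::abs(i - bi), std::abs(j - bj),
                          std::abs(k - bk)}) != ring)
              continue;
            for (int q : bins[(size_t)i + (size_t)gx * (j + (size_t)gy * k)]) {
              const double* a = V.colptr(0);  // column-major access below
              double A[3] = {V(F(q, 0) - 1, 0), V(F(q, 0) - 1, 1),
                             V(F(q, 0) - 1, 2)};
              double B[3] = {V(F(q, 1) - 1, 0), V(F(q, 1) - 1, 1),
                             V(F(q, 1) - 1, 2)};
              double C[3] = {V(F(q, 2) - 1, 0), V(F(q, 2) - 1, 1),
                             V(F(q, 2) - 1, 2)};
              (void)a;
              closest_on_tri(px, A, B, C, cand);
              double d = (cand[0] - px[0]) * (cand[0] - px[0]) +
                         (cand[1] - px[1]) * (cand[1] - px[1]) +
                         (cand[2] - px[2]) * (cand[2] - px[2]);
              if (d < bestd) {
                bestd = d;
                bestt = q;
                best[0] = cand[0];
                best[1] = cand[1];
                best[2] = cand[2];
              }
            }
          }
        }
      }
    }
    proj(p, 0) = best[0];
    proj(p, 1) = best[1];
    proj(p, 2) = best[2];
    dist(p) = std::sqrt(bestd);
    tri(p) = bestt + 1;
  }
  return List::create(_["points"] = proj, _["distance"] = dist,
                      _["triangle"] = tri);
}

// 6-connected component labels of a binary mask (0 = background).
// [[Rcpp::export]]
arma::icube cpp_label_components(const arma::cube& mask) {
  const int nx = mask.n_rows, ny = mask.n_cols, nz = mask.n_slices;
  arma::icube lab(nx, ny, nz, arma::fill::zeros);
  std::vector<long> stack;
  int cur = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0}, dy[6] = {0, 0, 1, -1, 0, 0},
            dz[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (mask(i, j, k) <= 0.5 || lab(i, j, k) != 0) continue;
        cur++;
        stack.clear();
        stack.push_back(i + (long)nx * (j + (long)ny * k));
        lab(i, j, k) = cur;
        while (!stack.empty()) {
          long q = stack.back();
          stack.pop_back();
          int qi = q % nx, qj = (q / nx) % ny, qk = q / ((long)nx * ny);
          for (int d = 0; d < 6; ++d) {
            int ii = qi + dx[d], jj = qj + dy[d], kk = qk + dz[d];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            if (mask(ii, jj, kk) > 0.5 && lab(ii, jj, kk) == 0) {
              lab(ii, jj, kk) = cur;
              stack.push_back(ii + (long)nx * (jj + (long)ny * kk));
            }
          }
        }
      }
  return lab;
}
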