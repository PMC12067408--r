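// Low-level grid numerics: interpolation, distance transforms, separable
// Gaussian smoothing, and the label-consistency registration objectives.
// Volumes are arma::cube in R array layout (x fastest); physical coordinate
// of voxel (i,j,k) (0-based) is origin + (i,j,k) * spacing (voxel centres).
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
arma::vec cpp_trilinear(const arma::cube& vol, const arma::vec& spacing,
                        const arma::vec& origin, const arma::mat& pts,
                        double outside) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  const int n = pts.n_rows;
  arma::vec out(n);
  for (int p = 0; p < n; ++p) {
    double u = (pts(p, 0) - origin(0)) / spacing(0);
    double v = (pts(p, 1) - origin(1)) / spacing(1);
    double w = (pts(p, 2) - origin(2)) / spacing(2);
    if (u < 0 || v < 0 || w < 0 || u > nx - 1 || v > ny - 1 || w > nz - 1) {
      out(p) = outside;
      continue;
    }
    int i = (int)std::floor(u), j = (int)std::floor(v), k = (int)std::floor(w);
    if (i == nx - 1) i--;
    if (j == ny - 1) j--;
    if (k == nz - 1) k--;
    double fu = u - i, fv = v - j, fw = w - k;
    double c00 = vol(i, j, k) * (1 - fu) + vol(i + 1, j, k) * fu;
    double c10 = vol(i, j + 1, k) * (1 - fu) + vol(i + 1, j + 1, k) * fu;
    double c01 = vol(i, j, k + 1) * (1 - fu) + vol(i + 1, j, k + 1) * fu;
    double c11 = vol(i, j + 1, k + 1) * (1 - fu) + vol(i + 1, j + 1, k + 1) * fu;
    out(p) = (c00 * (1 - fv) + c10 * fv) * (1 - fw) +
             (c01 * (1 - fv) + c11 * fv) * fw;
  }
  return out;
}

// [[Rcpp::export]]
arma::vec cpp_nearest(const arma::cube& vol, const arma::vec& spacing,
                      const arma::vec& origin, const arma::mat& pts,
                      double outside) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  const int n = pts.n_rows;
  arma::vec out(n);
  for (int p = 0; p < n; ++p) {
    double u = (pts(p, 0) - origin(0)) / spacing(0);
    double v = (pts(p, 1) - origin(1)) / spacing(1);
    double w = (pts(p, 2) - origin(2)) / spacing(2);
    int i = (int)std::lround(u), j = (int)std::lround(v), k = (int)std::lround(w);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      out(p) = outside;
    else
      out(p) = vol(i, j, k);
  }
  return out;
}

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// on samples at positions x_i = i * h.
static void sqedt_1d(const double* f, double* d, int n, double h,
                     int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared distance (mm^2) from every voxel to the nearest mask==1 voxel.
// [[Rcpp::export]]
arma::cube cpp_sqedt(const arma::cube& mask, const arma::vec& spacing) {
  const int nx = mask.n_rows, ny = mask.n_cols, nz = mask.n_slices;
  const double BIG = 1e30;
  arma::cube d(nx, ny, nz);
  for (arma::uword t = 0; t < mask.n_elem; ++t)
    d(t) = mask(t) > 0.5 ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d(i, j, k);
      sqedt_1d(f.data(), out.data(), nx, spacing(0), v.data(), z.data());
      for (int i = 0; i < nx; ++i) d(i, j, k) = out[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d(i, j, k);
      sqedt_1d(f.data(), out.data(), ny, spacing(1), v.data(), z.data());
      for (int j = 0; j < ny; ++j) d(i, j, k) = out[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d(i, j, k);
      sqedt_1d(f.data(), out.data(), nz, spacing(2), v.data(), z.data());
      for (int k = 0; k < nz; ++k) d(i, j, k) = out[k];
    }
  return d;
}

static void gauss_kernel(double sigma, std::vector<double>& ker) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  ker.assign(2 * r + 1, 0.0);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    double w = std::exp(-0.5 * i * i / (sigma * sigma));
    ker[i + r] = w;
    s += w;
  }
  for (auto& w : ker) w /= s;
}

// Separable Gaussian smoothing, sigma per axis in voxel units, reflected
// boundaries. sigma <= 0 skips the axis.
// [[Rcpp::export]]
arma::cube cpp_gauss_smooth(const arma::cube& vol, const arma::vec& sigma) {
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  arma::cube a = vol, b(nx, ny, nz);
  std::vector<double> ker;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };
  for (int ax = 0; ax < 3; ++ax) {
    if (sigma(ax) <= 0) continue;
    gauss_kernel(sigma(ax), ker);
    int r = ((int)ker.size() - 1) / 2;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double s = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = reflect(i + t, nx);
            else if (ax == 1) jj = reflect(j + t, ny);
            else kk = reflect(k + t, nz);
            s += ker[t + r] * a(ii, jj, kk);
          }
          b(i, j, k) = s;
        }
    a = b;
  }
  return a;
}

// ---- registration objectives ------------------------------------------
// Channels: smoothed one-hot label images, channel 0 = background. A point
// mapped outside the moving grid samples the background prior (1,0,0,...,0)
// with zero gradient.

struct ChSample {
  std::vector<double> val, gx, gy, gz;
};

static void sample_channels(const std::vector<const arma::cube*>& ch,
                            const arma::vec& spacing, const arma::vec& origin,
                            double x, double y, double z, ChSample& s,
                            bool want_grad) {
  const arma::cube& c0 = *ch[0];
  const int nx = c0.n_rows, ny = c0.n_cols, nz = c0.n_slices;
  const int nc = ch.size();
  double u = (x - origin(0)) / spacing(0);
  double v = (y - origin(1)) / spacing(1);
  double w = (z - origin(2)) / spacing(2);
  if (u < 0 || v < 0 || w < 0 || u > nx - 1 || v > ny - 1 || w > nz - 1) {
    for (int c = 0; c < nc; ++c) {
      s.val[c] = (c == 0) ? 1.0 : 0.0;
      s.gx[c] = s.gy[c] = s.gz[c] = 0.0;
    }
    return;
  }
  int i = (int)std::floor(u), j = (int)std::floor(v), k = (int)std::floor(w);
  if (i == nx - 1) i--;
  if (j == ny - 1) j--;
  if (k == nz - 1) k--;
  double fu = u - i, fv = v - j, fw = w - k;
  for (int c = 0; c < nc; ++c) {
    const arma::cube& V = *ch[c];
    double v000 = V(i, j, k), v100 = V(i + 1, j, k);
    double v010 = V(i, j + 1, k), v110 = V(i + 1, j + 1, k);
    double v001 = V(i, j, k + 1), v101 = V(i + 1, j, k + 1);
    double v011 = V(i, j + 1, k + 1), v111 = V(i + 1, j + 1, k + 1);
    double c00 = v000 * (1 - fu) + v100 * fu;
    double c10 = v010 * (1 - fu) + v110 * fu;
    double c01 = v001 * (1 - fu) + v101 * fu;
    double c11 = v011 * (1 - fu) + v111 * fu;
    double c0m = c00 * (1 - fv) + c10 * fv;
    double c1m = c01 * (1 - fv) + c11 * fv;
    s.val[c] = c0m * (1 - fw) + c1m * fw;
    if (!want_grad) continue;
    double du00 = v100 - v000, du10 = v110 - v010;
    double du01 = v101 - v001, du11 = v111 - v011;
    double du = ((du00 * (1 - fv) + du10 * fv) * (1 - fw) +
                 (du01 * (1 - fv) + du11 * fv) * fw);
    double dv0 = c10 - c00, dv1 = c11 - c01;
    double dv = dv0 * (1 - fw) + dv1 * fw;
    double dw = c1m - c0m;
    s.gx[c] = du / spacing(0);
    s.gy[c] = dv / spacing(1);
    s.gz[c] = dw / spacing(2);
  }
}

static std::vector<const arma::cube*> as_cube_ptrs(const List& lst,
                                                   std::vector<arma::cube>& hold) {
  hold.clear();
  hold.reserve(lst.size());
  for (int i = 0; i < lst.size(); ++i) {
    NumericVector v = lst[i];
    IntegerVector d = v.attr("dim");
    // zero-copy alias of the R array
    hold.emplace_back(REAL(v), d[0], d[1], d[2], false, true);
  }
  std::vector<const arma::cube*> p;
  for (auto& c : hold) p.push_back(&c);
  return p;
}

// Mean squared channel difference and gradient w.r.t. affine (A, t):
// moving sampled at A x + t over fixed voxels (strided subsample).
// [[Rcpp::export]]
List cpp_affine_obj_grad(const List& fixedCh, const arma::vec& fsp,
                         const arma::vec& forg, const List& movCh,
                         const arma::vec& msp, const arma::vec& morg,
                         const arma::mat& A, const arma::vec& t, int stride,
                         bool want_grad) {
  std::vector<arma::cube> fhold, mhold;
  auto fch = as_cube_ptrs(fixedCh, fhold);
  auto mch = as_cube_ptrs(movCh, mhold);
  const arma::cube& f0 = *fch[0];
  const int nx = f0.n_rows, ny = f0.n_cols, nz = f0.n_slices;
  const int nc = fch.size();
  ChSample s;
  s.val.resize(nc); s.gx.resize(nc); s.gy.resize(nc); s.gz.resize(nc);
  double obj = 0;
  long nsamp = 0;
  arma::mat gA(3, 3, arma::fill::zeros);
  arma::vec gt(3, arma::fill::zeros);
  for (int k = 0; k < nz; k += stride)
    for (int j = 0; j < ny; j += stride)
      for (int i = 0; i < nx; i += stride) {
        double x = forg(0) + i * fsp(0);
        double y = forg(1) + j * fsp(1);
        double z = forg(2) + k * fsp(2);
        double tx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t(0);
        double ty = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t(1);
        double tz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t(2);
        sample_channels(mch, msp, morg, tx, ty, tz, s, want_grad);
        double g0 = 0, g1 = 0, g2 = 0;
        for (int c = 0; c < nc; ++c) {
          double r = s.val[c] - (*fch[c])(i, j, k);
          obj += r * r;
          if (want_grad) {
            g0 += 2 * r * s.gx[c];
            g1 += 2 * r * s.gy[c];
            g2 += 2 * r * s.gz[c];
          }
        }
        if (want_grad) {
          gA(0, 0) += g0 * x; gA(0, 1) += g0 * y; gA(0, 2) += g0 * z;
          gA(1, 0) += g1 * x; gA(1, 1) += g1 * y; gA(1, 2) += g1 * z;
          gA(2, 0) += g2 * x; gA(2, 1) += g2 * y; gA(2, 2) += g2 * z;
          gt(0) += g0; gt(1) += g1; gt(2) += g2;
        }
        nsamp++;
      }
  double norm = (double)nsamp * nc;
  return List::create(_["obj"] = obj / norm, _["gA"] = gA / norm,
                      _["gt"] = gt / norm);
}

static inline void bspline_w(double u, double* w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  w[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Cubic B-spline displacement field evaluated at physical points.
// disp: (ncx, ncy, ncz, 3) control displacements, control point (i,j,k) at
// lat_origin + (i,j,k)*lat_spacing; indices clamped at the lattice border.
// [[Rcpp::export]]
arma::mat cpp_bspline_disp(const arma::mat& pts, const NumericVector& disp,
                           const arma::vec& lat_origin,
                           const arma::vec& lat_spacing) {
  IntegerVector dm = disp.attr("dim");
  const int ncx = dm[0], ncy = dm[1], ncz = dm[2];
  const double* D = REAL(disp);
  const long planes = (long)ncx * ncy * ncz;
  const int n = pts.n_rows;
  arma::mat out(n, 3, arma::fill::zeros);
  double wx[4], wy[4], wz[4];
  for (int p = 0; p < n; ++p) {
    double u = (pts(p, 0) - lat_origin(0)) / lat_spacing(0);
    double v = (pts(p, 1) - lat_origin(1)) / lat_spacing(1);
    double w = (pts(p, 2) - lat_origin(2)) / lat_spacing(2);
    int bi = (int)std::floor(u), bj = (int)std::floor(v), bk = (int)std::floor(w);
    bspline_w(u - bi, wx);
    bspline_w(v - bj, wy);
    bspline_w(w - bk, wz);
    double dx = 0, dy = 0, dz = 0;
    for (int c = 0; c < 4; ++c) {
      int kk = (int)clampd(bk - 1 + c, 0, ncz - 1);
      for (int b = 0; b < 4; ++b) {
        int jj = (int)clampd(bj - 1 + b, 0, ncy - 1);
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < 4; ++a) {
          int ii = (int)clampd(bi - 1 + a, 0, ncx - 1);
          double wt = wx[a] * wyz;
          long base = ii + (long)ncx * (jj + (long)ncy * kk);
          dx += wt * D[base];
          dy += wt * D[base + planes];
          dz += wt * D[base + 2 * planes];
        }
      }
    }
    out(p, 0) = dx; out(p, 1) = dy; out(p, 2) = dz;
  }
  return out;
}

// Objective and control-point gradient for the FFD stage: moving sampled at
// A x + t + D(x) over strided fixed voxels.
// [[Rcpp::export]]
List cpp_ffd_obj_grad(const List& fixedCh, const arma::vec& fsp,
                      const arma::vec& forg, const List& movCh,
                      const arma::vec& msp, const arma::vec& morg,
                      const arma::mat& A, const arma::vec& t,
                      const NumericVector& disp, const arma::vec& lat_origin,
                      const arma::vec& lat_spacing, int stride,
                      bool want_grad) {
  std::vector<arma::cube> fhold, mhold;
  auto fch = as_cube_ptrs(fixedCh, fhold);
  auto mch = as_cube_ptrs(movCh, mhold);
  IntegerVector dm = disp.attr("dim");
  const int ncx = dm[0], ncy = dm[1], ncz = dm[2];
  const double* D = REAL(disp);
  const long planes = (long)ncx * ncy * ncz;
  NumericVector grad(disp.size());
  grad.attr("dim") = dm;
  double* G = REAL(grad);
  const arma::cube& f0 = *fch[0];
  const int nx = f0.n_rows, ny = f0.n_cols, nz = f0.n_slices;
  const int nc = fch.size();
  ChSample s;
  s.val.resize(nc); s.gx.resize(nc); s.gy.resize(nc); s.gz.resize(nc);
  double obj = 0;
  long nsamp = 0;
  double wx[4], wy[4], wz[4];
  for (int k = 0; k < nz; k += stride)
    for (int j = 0; j < ny; j += stride)
      for (int i = 0; i < nx; i += stride) {
        double x = forg(0) + i * fsp(0);
        double y = forg(1) + j * fsp(1);
        double z = forg(2) + k * fsp(2);
        double u = (x - lat_origin(0)) / lat_spacing(0);
        double v = (y - lat_origin(1)) / lat_spacing(1);
        double w = (z - lat_origin(2)) / lat_spacing(2);
        int bi = (int)std::floor(u), bj = (int)std::floor(v),
            bk = (int)std::floor(w);
        bspline_w(u - bi, wx);
        bspline_w(v - bj, wy);
        bspline_w(w - bk, wz);
        double dx = 0, dy = 0, dz = 0;
        for (int c = 0; c < 4; ++c) {
          int kk = (int)clampd(bk - 1 + c, 0, ncz - 1);
          for (int b = 0; b < 4; ++b) {
            int jj = (int)clampd(bj - 1 + b, 0, ncy - 1);
            double wyz = wy[b] * wz[c];
            for (int a = 0; a < 4; ++a) {
              int ii = (int)clampd(bi - 1 + a, 0, ncx - 1);
              double wt = wx[a] * wyz;
              long base = ii + (long)ncx * (jj + (long)ncy * kk);
              dx += wt * D[base];
              dy += wt * D[base + planes];
              dz += wt * D[base + 2 * planes];
            }
          }
        }
        double tx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t(0) + dx;
        double ty = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t(1) + dy;
        double tz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t(2) + dz;
        sample_channels(mch, msp, morg, tx, ty, tz, s, want_grad);
        double g0 = 0, g1 = 0, g2 = 0;
        for (int c = 0; c < nc; ++c) {
          double r = s.val[c] - (*fch[c])(i, j, k);
          obj += r * r;
          if (want_grad) {
            g0 += 2 * r * s.gx[c];
            g1 += 2 * r * s.gy[c];
            g2 += 2 * r * s.gz[c];
          }
        }
        if (want_grad && (g0 != 0 || g1 != 0 || g2 != 0)) {
          for (int c = 0; c < 4; ++c) {
            int kk = (int)clampd(bk - 1 + c, 0, ncz - 1);
            for (int b = 0; b < 4; ++b) {
              int jj = (int)clampd(bj - 1 + b, 0, ncy - 1);
              double wyz = wy[b] * wz[c];
              for (int a = 0; a < 4; ++a) {
                int ii = (int)clampd(bi - 1 + a, 0, ncx - 1);
                double wt = wx[a] * wyz;
                long base = ii + (long)ncx * (jj + (long)ncy * kk);
                G[base] += g0 * wt;
                G[base + planes] += g1 * wt;
                G[base + 2 * planes] += g2 * wt;
              }
            }
          }
        }
        nsamp++;
      }
  double norm = (double)nsamp * nc;
  if (want_grad)
    for (long q = 0; q < (long)grad.size(); ++q) G[q] /= norm;
  return List::create(_["obj"] = obj / norm, _["grad"] = grad);
}
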