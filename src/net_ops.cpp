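// BLAS-backed layer primitives for the 2-D segmentation network.
// Activations are (N*H*W) x C matrices (pixel column-major within a slice,
// samples stacked). Index tables are built once in R and passed in:
//  - conv: idx (P x 9) of 1-based source pixels per output pixel/kernel
//    position, 0 = zero padding
//  - convT 2x2 stride 2: maps (HW x 4) of 1-based target pixels
//  - upsample: src (P) of 1-based source pixels per target pixel
// NumericMatrix arguments are accessed as zero-copy views; Armadillo
// matrices alias the same memory for GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat view(const NumericMatrix& x) {
  return arma::mat(const_cast<double*>(REAL(x)), x.nrow(), x.ncol(), false,
                   true);
}

static NumericMatrix build_col(const NumericMatrix& X, const IntegerMatrix& idx,
                               int N, int HW, int H, int W, int stride) {
  const int P = idx.nrow(), C = X.ncol();
  NumericMatrix col((R_xlen_t)N * P, 9 * C);
  const double* Xp = REAL(X);
  double* Cp = REAL(col);
  for (int k = 0; k < 9; ++k) {
    const int ki = (k % 3) - 1, kj = (k / 3) - 1;
    const int* ip = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double* xc = Xp + (size_t)c * N * HW;
      double* oc = Cp + ((size_t)k * C + c) * N * P;
      for (int n = 0; n < N; ++n) {
        const double* xn = xc + (size_t)n * HW;
        double* on = oc + (size_t)n * P;
        if (stride == 1) {
          // contiguous shifted copy per column (borders stay zero)
          const int i0 = ki < 0 ? -ki : 0, i1 = ki > 0 ? H - ki : H;
          const int j0 = kj < 0 ? -kj : 0, j1 = kj > 0 ? W - kj : W;
          for (int j = j0; j < j1; ++j)
            std::copy(xn + (i0 + ki) + (size_t)H * (j + kj),
                      xn + (i1 + ki) + (size_t)H * (j + kj),
                      on + i0 + (size_t)H * j);
        } else {
          for (int p = 0; p < P; ++p) {
            int i = ip[p];
            on[p] = i > 0 ? xn[i - 1] : 0.0;
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
List cpp_conv3_fwd(const NumericMatrix& X, const IntegerMatrix& idx, int N,
                   int HW, const NumericMatrix& Wm, bool keep_col, int H,
                   int W, int stride) {
  NumericMatrix col = build_col(X, idx, N, HW, H, W, stride);
  const int P = idx.nrow();
  NumericMatrix Y((R_xlen_t)N * P, Wm.ncol());
  arma::mat Yv = view(Y);
  Yv = view(col) * view(Wm);
  if (keep_col) return List::create(_["y"] = Y, _["col"] = col);
  return List::create(_["y"] = Y);
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const NumericMatrix& col, const NumericMatrix& dY,
                   const IntegerMatrix& idx, int N, int HW,
                   const NumericMatrix& Wm, int Cin, int H, int W,
                   int stride) {
  const int P = idx.nrow();
  NumericMatrix dW(Wm.nrow(), Wm.ncol());
  arma::mat dWv = view(dW);
  dWv = view(col).t() * view(dY);
  NumericMatrix dcol((R_xlen_t)N * P, 9 * Cin);
  arma::mat dcolv = view(dcol);
  dcolv = view(dY) * view(Wm).t();
  NumericMatrix dX((R_xlen_t)N * HW, Cin);
  double* Xp = REAL(dX);
  const double* Dp = REAL(dcol);
  // per kernel position the output->source map is injective, so plain
  // scatter-add per k has no write conflicts
  for (int k = 0; k < 9; ++k) {
    const int ki = (k % 3) - 1, kj = (k / 3) - 1;
    const int* ip = &idx(0, k);
    for (int c = 0; c < Cin; ++c) {
      double* xc = Xp + (size_t)c * N * HW;
      const double* dc = Dp + ((size_t)k * Cin + c) * N * P;
      for (int n = 0; n < N; ++n) {
        double* xn = xc + (size_t)n * HW;
        const double* dn = dc + (size_t)n * P;
        if (stride == 1) {
          const int i0 = ki < 0 ? -ki : 0, i1 = ki > 0 ? H - ki : H;
          const int j0 = kj < 0 ? -kj : 0, j1 = kj > 0 ? W - kj : W;
          for (int j = j0; j < j1; ++j) {
            double* xcol = xn + (i0 + ki) + (size_t)H * (j + kj);
            const double* dcolp = dn + i0 + (size_t)H * j;
            const int len = i1 - i0;
            for (int i = 0; i < len; ++i) xcol[i] += dcolp[i];
          }
        } else {
          for (int p = 0; p < P; ++p) {
            int i = ip[p];
            if (i > 0) xn[i - 1] += dn[p];
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// [[Rcpp::export]]
NumericMatrix cpp_convt_fwd(const NumericMatrix& X, const IntegerMatrix& maps,
                            int N, const NumericMatrix& Wm, int Cout) {
  const int HW = maps.nrow();
  NumericMatrix Ycol((R_xlen_t)N * HW, 4 * Cout);
  arma::mat Ycolv = view(Ycol);
  Ycolv = view(X) * view(Wm);
  NumericMatrix Y(4 * (R_xlen_t)N * HW, Cout);
  double* Yp = REAL(Y);
  const double* Sp = REAL(Ycol);
  for (int q = 0; q < 4; ++q) {
    const int* mp = &maps(0, q);
    for (int c = 0; c < Cout; ++c) {
      double* yc = Yp + (size_t)c * 4 * N * HW;
      const double* sc = Sp + ((size_t)q * Cout + c) * N * HW;
      for (int n = 0; n < N; ++n) {
        double* yn = yc + (size_t)n * 4 * HW;
        const double* sn = sc + (size_t)n * HW;
        for (int p = 0; p < HW; ++p) yn[mp[p] - 1] = sn[p];
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_convt_bwd(const NumericMatrix& X, const NumericMatrix& dY,
                   const IntegerMatrix& maps, int N, const NumericMatrix& Wm,
                   int Cout) {
  const int HW = maps.nrow();
  NumericMatrix dYcol((R_xlen_t)N * HW, 4 * Cout);
  double* Dp = REAL(dYcol);
  const double* Yp = REAL(dY);
  for (int q = 0; q < 4; ++q) {
    const int* mp = &maps(0, q);
    for (int c = 0; c < Cout; ++c) {
      double* dc = Dp + ((size_t)q * Cout + c) * N * HW;
      const double* yc = Yp + (size_t)c * 4 * N * HW;
      for (int n = 0; n < N; ++n) {
        double* dn = dc + (size_t)n * HW;
        const double* yn = yc + (size_t)n * 4 * HW;
        for (int p = 0; p < HW; ++p) dn[p] = yn[mp[p] - 1];
      }
    }
  }
  NumericMatrix dX(X.nrow(), X.ncol());
  arma::mat dXv = view(dX);
  dXv = view(dYcol) * view(Wm).t();
  NumericMatrix dW(Wm.nrow(), Wm.ncol());
  arma::mat dWv = view(dW);
  dWv = view(X).t() * view(dYcol);
  return List::create(_["dX"] = dX, _["dW"] = dW);
}

// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(const NumericMatrix& X, const IntegerVector& src,
                              int N, int HW) {
  const int P = src.size(), C = X.ncol();
  NumericMatrix Y((R_xlen_t)N * P, C);
  const double* Xp = REAL(X);
  double* Yp = REAL(Y);
  const int* sp = INTEGER(src);
  for (int c = 0; c < C; ++c) {
    const double* xc = Xp + (size_t)c * N * HW;
    double* yc = Yp + (size_t)c * N * P;
    for (int n = 0; n < N; ++n) {
      const double* xn = xc + (size_t)n * HW;
      double* yn = yc + (size_t)n * P;
      for (int p = 0; p < P; ++p) yn[p] = xn[sp[p] - 1];
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_scatter_add_rows(const NumericMatrix& dY,
                                   const IntegerVector& src, int N, int HW) {
  const int P = src.size(), C = dY.ncol();
  NumericMatrix dX((R_xlen_t)N * HW, C);
  double* Xp = REAL(dX);
  const double* Yp = REAL(dY);
  const int* sp = INTEGER(src);
  for (int c = 0; c < C; ++c) {
    double* xc = Xp + (size_t)c * N * HW;
    const double* yc = Yp + (size_t)c * N * P;
    for (int n = 0; n < N; ++n) {
      double* xn = xc + (size_t)n * HW;
      const double* yn = yc + (size_t)n * P;
      for (int p = 0; p < P; ++p) xn[sp[p] - 1] += yn[p];
    }
  }
  return dX;
}

// In-place Adam update; theta, m and v are modified directly (they are
// owned exclusively by the model environment).
// [[Rcpp::export]]
void cpp_adam(NumericVector theta, NumericVector m, NumericVector v,
              const NumericVector& g, double lr, double b1, double b2,
              double eps, int t) {
  const R_xlen_t n = theta.size();
  const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  double* th = REAL(theta);
  double* mp = REAL(m);
  double* vp = REAL(v);
  const double* gp = REAL(g);
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    th[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// Fused batch-norm + ReLU forward.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(const NumericMatrix& x, const NumericVector& gamma,
                     const NumericVector& beta, bool training,
                     const NumericVector& rmean, const NumericVector& rvar,
                     double eps) {
  const int n = x.nrow(), C = x.ncol();
  NumericVector m(C), v(C), ivar(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    if (training) {
      const double* xc = xp + (size_t)c * n;
      double s = 0, s2 = 0;
      for (int i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m[c] = s / n;
      v[c] = s2 / n - m[c] * m[c];
    } else {
      m[c] = rmean[c];
      v[c] = rvar[c];
    }
    ivar[c] = 1.0 / std::sqrt(v[c] + eps);
  }
  NumericMatrix xhat(n, C), y(n, C);
  double* hp = REAL(xhat);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * n;
    double* hc = hp + (size_t)c * n;
    double* yc = yp + (size_t)c * n;
    double mc = m[c], ic = ivar[c], gc = gamma[c], bc = beta[c];
    for (int i = 0; i < n; ++i) {
      double h = (xc[i] - mc) * ic;
      hc[i] = h;
      double o = h * gc + bc;
      yc[i] = o > 0 ? o : 0.0;
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivar"] = ivar,
                      _["mean"] = m, _["var"] = v);
}

// Fused ReLU + batch-norm backward: dy masked by relu output > 0.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(const NumericMatrix& dy_in, const NumericMatrix& relu_y,
                     const NumericMatrix& xhat, const NumericVector& ivar,
                     const NumericVector& gamma) {
  const int n = dy_in.nrow(), C = dy_in.ncol();
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dx(n, C);
  const double* dyp = REAL(dy_in);
  const double* ryp = REAL(relu_y);
  const double* hp = REAL(xhat);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dyp + (size_t)c * n;
    const double* ry = ryp + (size_t)c * n;
    const double* hc = hp + (size_t)c * n;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      double d = ry[i] > 0 ? dyc[i] : 0.0;
      s1 += d;
      s2 += d * hc[i];
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    double gc = gamma[c], ic = ivar[c];
    double a1 = gc * s1 / n, a2 = gc * s2 / n;
    double* dxc = dxp + (size_t)c * n;
    for (int i = 0; i < n; ++i) {
      double d = ry[i] > 0 ? dyc[i] : 0.0;
      dxc[i] = (gc * d - a1 - hc[i] * a2) * ic;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Per-pixel softmax cross-entropy: returns loss and dlogits (in place of a
// probability matrix copy, dlogits = (p - onehot)/n).
// [[Rcpp::export]]
List cpp_softmax_ce(const NumericMatrix& logits, const IntegerVector& labels,
                    bool want_probs) {
  const int n = logits.nrow(), C = logits.ncol();
  NumericMatrix dz(n, C);
  NumericMatrix probs = want_probs ? NumericMatrix(n, C) : NumericMatrix(0, 0);
  const double* lp = REAL(logits);
  double* dp = REAL(dz);
  double loss = 0;
  std::vector<double> row(C);
  for (int i = 0; i < n; ++i) {
    double mx = -1e300;
    for (int c = 0; c < C; ++c) {
      row[c] = lp[(size_t)c * n + i];
      if (row[c] > mx) mx = row[c];
    }
    double s = 0;
    for (int c = 0; c < C; ++c) { row[c] = std::exp(row[c] - mx); s += row[c]; }
    int y = labels[i];
    for (int c = 0; c < C; ++c) {
      double p = row[c] / s;
      dp[(size_t)c * n + i] = (p - (c == y ? 1.0 : 0.0)) / n;
      if (want_probs) probs(i, c) = p;
    }
    loss -= std::log(std::max(row[y] / s, 1e-12));
  }
  List out = List::create(_["loss"] = loss / n, _["dlogits"] = dz);
  if (want_probs) out["probs"] = probs;
  return out;
}
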