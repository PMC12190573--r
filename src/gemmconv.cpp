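// Slab-wise implicit-GEMM 3D convolution. Instead of materializing the full
// (B*N) x (C*k^3) patch matrix, patches are built for one run of w-slices at
// a time into a small reusable buffer and multiplied with BLAS dgemm. Same
// layout conventions as vol2col (see conv3d.cpp).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// Single-precision GEMM (not declared in R_ext/BLAS.h but provided by every
// BLAS). The convolution runs its inner products in float: weights and
// activations stay double everywhere else, and the ~1e-7 relative rounding is
// far below the training noise floor.
extern "C" void F77_NAME(sgemm)(const char*, const char*, const int*,
                                const int*, const int*, const float*,
                                const float*, const int*, const float*,
                                const int*, const float*, float*, const int*
                                FCLEN FCLEN);

static void d2f(const double* x, float* y, R_xlen_t n) {
  for (R_xlen_t i = 0; i < n; ++i) y[i] = (float)x[i];
}

// Fill the patch buffer P (nsl x C*k^3, column-major, lda = nsl) for sample b
// and output slices [w0, w0+ws). P must be zeroed by the caller.
template <typename T>
static void fill_patches(const T* xp, T* P, int D, int H, int W,
                         int C, int k, R_xlen_t nr, R_xlen_t base,
                         int w0, int ws) {
  const int p = (k - 1) / 2;
  const R_xlen_t nsl = (R_xlen_t)D * H * ws;
  for (int dx = -p; dx <= p; ++dx)
    for (int dy = -p; dy <= p; ++dy)
      for (int dz = -p; dz <= p; ++dz) {
        const int o = (dz + p) + k * (dy + p) + k * k * (dx + p);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
        const int len = d1 - d0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const T* xcol = xp + (R_xlen_t)c * nr;
          T* pcol = P + (R_xlen_t)(o * C + c) * nsl;
          for (int w = w0; w < w0 + ws; ++w) {
            const int sw = w + dx;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy;
              if (sh < 0 || sh >= H) continue;
              const R_xlen_t dst = d0 + (R_xlen_t)D * (h + (R_xlen_t)H * (w - w0));
              const R_xlen_t src = base + d0 + dz +
                (R_xlen_t)D * (sh + (R_xlen_t)H * sw);
              std::memcpy(pcol + dst, xcol + src, sizeof(T) * len);
            }
          }
        }
      }
}

// Adjoint: scatter-add the patch-gradient buffer back onto dX.
template <typename T>
static void scatter_patches(double* dxp, const T* P, int D, int H, int W,
                            int C, int k, R_xlen_t nr, R_xlen_t base,
                            int w0, int ws) {
  const int p = (k - 1) / 2;
  const R_xlen_t nsl = (R_xlen_t)D * H * ws;
  for (int dx = -p; dx <= p; ++dx)
    for (int dy = -p; dy <= p; ++dy)
      for (int dz = -p; dz <= p; ++dz) {
        const int o = (dz + p) + k * (dy + p) + k * k * (dx + p);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
        const int len = d1 - d0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          double* xcol = dxp + (R_xlen_t)c * nr;
          const T* pcol = P + (R_xlen_t)(o * C + c) * nsl;
          for (int w = w0; w < w0 + ws; ++w) {
            const int sw = w + dx;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + dy;
              if (sh < 0 || sh >= H) continue;
              const T* pv = pcol + d0 +
                (R_xlen_t)D * (h + (R_xlen_t)H * (w - w0));
              double* xv = xcol + base + d0 + dz +
                (R_xlen_t)D * (sh + (R_xlen_t)H * sw);
              for (int i = 0; i < len; ++i) xv[i] += pv[i];
            }
          }
        }
      }
}

static int slab_slices(int D, int H, int W) {
  // aim for roughly 16k rows per slab
  int ws = std::max(1, 16384 / std::max(1, D * H));
  return std::min(ws, W);
}

// [[Rcpp::export]]
NumericMatrix conv3d_fwd(const NumericMatrix& X, const NumericMatrix& W_,
                         const IntegerVector& dims, int k, int B,
                         bool use_double = false) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  const int C = X.ncol();
  const int CK = C * k * k * k;
  const int Cout = W_.ncol();
  if (W_.nrow() != CK) stop("conv3d_fwd: weight shape mismatch");
  if (X.nrow() != (R_xlen_t)N * B) stop("conv3d_fwd: nrow(X) mismatch");
  NumericMatrix Y((R_xlen_t)N * B, Cout);
  const R_xlen_t nr = (R_xlen_t)N * B;
  const int ws_max = slab_slices(D, H, W);
  if (use_double) {
    std::vector<double> P((R_xlen_t)D * H * ws_max * CK);
    const double done = 1.0, dzero = 0.0;
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base = (R_xlen_t)b * N;
      for (int w0 = 0; w0 < W; w0 += ws_max) {
        const int ws = std::min(ws_max, W - w0);
        const int nsl = D * H * ws;
        std::fill(P.begin(), P.begin() + (R_xlen_t)nsl * CK, 0.0);
        fill_patches(X.begin(), P.data(), D, H, W, C, k, nr, base, w0, ws);
        const int m = nsl, n = Cout, kk = CK;
        const int ldy = (int)nr;
        F77_CALL(dgemm)("N", "N", &m, &n, &kk, &done, P.data(), &m,
                        W_.begin(), &kk, &dzero,
                        Y.begin() + base + (R_xlen_t)D * H * w0, &ldy
                        FCONE FCONE);
      }
    }
    return Y;
  }
  std::vector<float> P((R_xlen_t)D * H * ws_max * CK);
  std::vector<float> Xf(nr * C), Wf((R_xlen_t)CK * Cout);
  std::vector<float> Yf((R_xlen_t)D * H * ws_max * Cout);
  d2f(X.begin(), Xf.data(), nr * C);
  d2f(W_.begin(), Wf.data(), (R_xlen_t)CK * Cout);
  const float one = 1.0f, zero = 0.0f;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t base = (R_xlen_t)b * N;
    for (int w0 = 0; w0 < W; w0 += ws_max) {
      const int ws = std::min(ws_max, W - w0);
      const int nsl = D * H * ws;
      std::fill(P.begin(), P.begin() + (R_xlen_t)nsl * CK, 0.0f);
      fill_patches(Xf.data(), P.data(), D, H, W, C, k, nr, base, w0, ws);
      const int m = nsl, n = Cout, kk = CK;
      F77_CALL(sgemm)("N", "N", &m, &n, &kk, &one, P.data(), &m,
                      Wf.data(), &kk, &zero, Yf.data(), &m
                      FCONE FCONE);
      double* yout = Y.begin() + base + (R_xlen_t)D * H * w0;
      for (int j = 0; j < Cout; ++j)
        for (int i = 0; i < nsl; ++i)
          yout[(R_xlen_t)j * nr + i] = (double)Yf[(R_xlen_t)j * nsl + i];
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv3d_bwd(const NumericMatrix& dY, const NumericMatrix& X,
                const NumericMatrix& W_, const IntegerVector& dims,
                int k, int B, bool need_dx = true, bool use_double = false) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  const int C = X.ncol();
  const int CK = C * k * k * k;
  const int Cout = W_.ncol();
  if (W_.nrow() != CK) stop("conv3d_bwd: weight shape mismatch");
  NumericMatrix dX(need_dx ? (R_xlen_t)N * B : 0, C);
  NumericMatrix dW(CK, Cout);
  if (use_double) {
    const R_xlen_t nr = (R_xlen_t)N * B;
    const int ws_max = slab_slices(D, H, W);
    std::vector<double> P((R_xlen_t)D * H * ws_max * CK);
    std::vector<double> dP((R_xlen_t)D * H * ws_max * CK);
    const double done = 1.0, dzero = 0.0;
    for (int b = 0; b < B; ++b) {
      const R_xlen_t base = (R_xlen_t)b * N;
      for (int w0 = 0; w0 < W; w0 += ws_max) {
        const int ws = std::min(ws_max, W - w0);
        const int nsl = D * H * ws;
        std::fill(P.begin(), P.begin() + (R_xlen_t)nsl * CK, 0.0);
        fill_patches(X.begin(), P.data(), D, H, W, C, k, nr, base, w0, ws);
        const double* dy_slab = dY.begin() + base + (R_xlen_t)D * H * w0;
        const int ldy = (int)nr;
        {
          const int m = CK, n = Cout, kk = nsl;
          F77_CALL(dgemm)("T", "N", &m, &n, &kk, &done, P.data(), &kk,
                          dy_slab, &ldy, &done, dW.begin(), &m FCONE FCONE);
        }
        if (need_dx) {
          const int m = nsl, n = CK, kk = Cout;
          F77_CALL(dgemm)("N", "T", &m, &n, &kk, &done, dy_slab, &ldy,
                          W_.begin(), &n, &dzero, dP.data(), &m FCONE FCONE);
          scatter_patches(dX.begin(), dP.data(), D, H, W, C, k, nr, base,
                          w0, ws);
        }
      }
    }
    return List::create(_["dx"] = dX, _["dW"] = dW);
  }
  std::vector<float> dWf((R_xlen_t)CK * Cout, 0.0f);
  const R_xlen_t nr = (R_xlen_t)N * B;
  const int ws_max = slab_slices(D, H, W);
  std::vector<float> P((R_xlen_t)D * H * ws_max * CK);
  std::vector<float> dP((R_xlen_t)D * H * ws_max * CK);
  std::vector<float> Xf(nr * C), Wf((R_xlen_t)CK * Cout);
  std::vector<float> dYf(nr * Cout);
  d2f(X.begin(), Xf.data(), nr * C);
  d2f(W_.begin(), Wf.data(), (R_xlen_t)CK * Cout);
  d2f(dY.begin(), dYf.data(), nr * Cout);
  const float one = 1.0f, zero = 0.0f;
  for (int b = 0; b < B; ++b) {
    const R_xlen_t base = (R_xlen_t)b * N;
    for (int w0 = 0; w0 < W; w0 += ws_max) {
      const int ws = std::min(ws_max, W - w0);
      const int nsl = D * H * ws;
      std::fill(P.begin(), P.begin() + (R_xlen_t)nsl * CK, 0.0f);
      fill_patches(Xf.data(), P.data(), D, H, W, C, k, nr, base, w0, ws);
      const float* dy_slab = dYf.data() + base + (R_xlen_t)D * H * w0;
      const int ldy = (int)nr;
      // dW += P^T %*% dY_slab
      {
        const int m = CK, n = Cout, kk = nsl;
        F77_CALL(sgemm)("T", "N", &m, &n, &kk, &one, P.data(), &kk,
                        dy_slab, &ldy, &one, dWf.data(), &m FCONE FCONE);
      }
      if (need_dx) {
        // dP = dY_slab %*% W^T, then scatter-add into dX
        const int m = nsl, n = CK, kk = Cout;
        F77_CALL(sgemm)("N", "T", &m, &n, &kk, &one, dy_slab, &ldy,
                        Wf.data(), &n, &zero, dP.data(), &m FCONE FCONE);
        scatter_patches(dX.begin(), dP.data(), D, H, W, C, k, nr, base, w0, ws);
      }
    }
  }
  for (R_xlen_t i = 0; i < (R_xlen_t)CK * Cout; ++i) dW[i] = (double)dWf[i];
  return List::create(_["dx"] = dX, _["dW"] = dW);
}

// ---- fused column-wise helpers (batch norm, ReLU) --------------------------

// y[i,j] = x[i,j] * scale[j] + shift[j]
// [[Rcpp::export]]
NumericMatrix col_affine(const NumericMatrix& X, const NumericVector& scale,
                         const NumericVector& shift) {
  const R_xlen_t n = X.nrow();
  const int C = X.ncol();
  NumericMatrix Y(n, C);
  for (int j = 0; j < C; ++j) {
    const double s = scale[j], t = shift[j];
    const double* xc = X.begin() + (R_xlen_t)j * n;
    double* yc = Y.begin() + (R_xlen_t)j * n;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = xc[i] * s + t;
  }
  return Y;
}

// column means and population variances in one pass
// [[Rcpp::export]]
List col_moments(const NumericMatrix& X) {
  const R_xlen_t n = X.nrow();
  const int C = X.ncol();
  NumericVector mu(C), v(C);
  for (int j = 0; j < C; ++j) {
    const double* xc = X.begin() + (R_xlen_t)j * n;
    double s = 0, s2 = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    const double m = s / n;
    mu[j] = m;
    v[j] = s2 / n - m * m;
    if (v[j] < 0) v[j] = 0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// dx[i,j] = (dxhat[i,j] - m1[j] - xhat[i,j] * m2[j]) * invstd[j]
// [[Rcpp::export]]
NumericMatrix bn_backward_x(const NumericMatrix& dxhat,
                            const NumericMatrix& xhat,
                            const NumericVector& m1, const NumericVector& m2,
                            const NumericVector& invstd) {
  const R_xlen_t n = dxhat.nrow();
  const int C = dxhat.ncol();
  NumericMatrix dx(n, C);
  for (int j = 0; j < C; ++j) {
    const double a = m1[j], bb = m2[j], s = invstd[j];
    const double* dc = dxhat.begin() + (R_xlen_t)j * n;
    const double* xc = xhat.begin() + (R_xlen_t)j * n;
    double* oc = dx.begin() + (R_xlen_t)j * n;
    for (R_xlen_t i = 0; i < n; ++i) oc[i] = (dc[i] - a - xc[i] * bb) * s;
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix relu_fwd(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  const double* xp = X.begin();
  double* yp = Y.begin();
  const R_xlen_t n = X.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return Y;
}

// [[Rcpp::export]]
NumericMatrix relu_bwd_c(const NumericMatrix& dY, const NumericMatrix& Y) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  const double* dp = dY.begin();
  const double* yp = Y.begin();
  double* op = dX.begin();
  const R_xlen_t n = dY.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? dp[i] : 0;
  return dX;
}

// row-wise softmax (numerically stabilized)
// [[Rcpp::export]]
NumericMatrix softmax_rows(const NumericMatrix& Z) {
  const R_xlen_t n = Z.nrow();
  const int C = Z.ncol();
  NumericMatrix P(n, C);
  std::vector<const double*> zc(C);
  std::vector<double*> pc(C);
  for (int j = 0; j < C; ++j) {
    zc[j] = Z.begin() + (R_xlen_t)j * n;
    pc[j] = P.begin() + (R_xlen_t)j * n;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    double m = zc[0][i];
    for (int j = 1; j < C; ++j) if (zc[j][i] > m) m = zc[j][i];
    double s = 0;
    for (int j = 0; j < C; ++j) { const double e = std::exp(zc[j][i] - m); pc[j][i] = e; s += e; }
    for (int j = 0; j < C; ++j) pc[j][i] /= s;
  }
  return P;
}
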