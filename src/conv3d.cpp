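#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are stored as (B*N) x C matrices, N = D*H*W voxels per sample,
// samples stacked row-wise, voxel linear index v = d + D*h + D*H*w (0-based,
// matching R's column-major array order for dim c(D,H,W)).
//
// vol2col extracts, for every voxel, the k^3 neighbourhood of every channel
// ("same" zero padding, k odd), giving a (B*N) x (C*k^3) patch matrix so that
// a 3D convolution becomes patch_matrix %*% W with W of dim (C*k^3) x C_out.
// Column layout: col = (o * C) + c, with kernel-offset index
// o = (dz+p) + k*(dy+p) + k*k*(dx+p), p = (k-1)/2.

// [[Rcpp::export]]
NumericMatrix vol2col(const NumericMatrix& X, const IntegerVector& dims,
                      int k, int B) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  const int C = X.ncol();
  const int p = (k - 1) / 2;
  if (X.nrow() != (R_xlen_t)N * B)
    stop("vol2col: nrow(X) does not match dims and B");
  NumericMatrix M((R_xlen_t)N * B, (R_xlen_t)C * k * k * k);
  const double* xp = X.begin();
  double* mp = M.begin();
  const R_xlen_t nr = (R_xlen_t)N * B;
  for (int dx = -p; dx <= p; ++dx) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dz = -p; dz <= p; ++dz) {
        const int o = (dz + p) + k * (dy + p) + k * k * (dx + p);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz); // dest d range
        const int len = d1 - d0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          const double* xcol = xp + ((R_xlen_t)c) * nr;
          double* mcol = mp + ((R_xlen_t)(o * C + c)) * nr;
          for (int b = 0; b < B; ++b) {
            const R_xlen_t base = (R_xlen_t)b * N;
            for (int w = 0; w < W; ++w) {
              const int sw = w + dx;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                const int sh = h + dy;
                if (sh < 0 || sh >= H) continue;
                const R_xlen_t dst = base + d0 + (R_xlen_t)D * (h + (R_xlen_t)H * w);
                const R_xlen_t src = base + d0 + dz + (R_xlen_t)D * (sh + (R_xlen_t)H * sw);
                std::memcpy(mcol + dst, xcol + src, sizeof(double) * len);
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Adjoint of vol2col: scatter-adds a (B*N) x (C*k^3) matrix back onto a
// (B*N) x C volume. Used for the gradient w.r.t. the convolution input.

// [[Rcpp::export]]
NumericMatrix col2vol(const NumericMatrix& M, const IntegerVector& dims,
                      int k, int B) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const int N = D * H * W;
  const int p = (k - 1) / 2;
  const int C = M.ncol() / (k * k * k);
  if ((R_xlen_t)C * k * k * k != M.ncol())
    stop("col2vol: ncol(M) not divisible by k^3");
  if (M.nrow() != (R_xlen_t)N * B)
    stop("col2vol: nrow(M) does not match dims and B");
  NumericMatrix X((R_xlen_t)N * B, C);
  const double* mp = M.begin();
  double* xp = X.begin();
  const R_xlen_t nr = (R_xlen_t)N * B;
  for (int dx = -p; dx <= p; ++dx) {
    for (int dy = -p; dy <= p; ++dy) {
      for (int dz = -p; dz <= p; ++dz) {
        const int o = (dz + p) + k * (dy + p) + k * k * (dx + p);
        const int d0 = std::max(0, -dz), d1 = std::min(D, D - dz);
        const int len = d1 - d0;
        if (len <= 0) continue;
        for (int c = 0; c < C; ++c) {
          double* xcol = xp + ((R_xlen_t)c) * nr;
          const double* mcol = mp + ((R_xlen_t)(o * C + c)) * nr;
          for (int b = 0; b < B; ++b) {
            const R_xlen_t base = (R_xlen_t)b * N;
            for (int w = 0; w < W; ++w) {
              const int sw = w + dx;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                const int sh = h + dy;
                if (sh < 0 || sh >= H) continue;
                const R_xlen_t dst = base + d0 + (R_xlen_t)D * (h + (R_xlen_t)H * w);
                const R_xlen_t src = base + d0 + dz + (R_xlen_t)D * (sh + (R_xlen_t)H * sw);
                const double* mv = mcol + dst;
                double* xv = xcol + src;
                for (int i = 0; i < len; ++i) xv[i] += mv[i];
              }
            }
          }
        }
      }
    }
  }
  return X;
}

// 2x2x2 max pooling with stride 2. Returns the pooled map and the (1-based)
// source-row index of each maximum, per channel, for the backward pass.
// Input dims must be even.

// [[Rcpp::export]]
List maxpool3d_fwd(const NumericMatrix& X, const IntegerVector& dims, int B) {
  const int D = dims[0], H = dims[1], W = dims[2];
  if (D % 2 || H % 2 || W % 2) stop("maxpool3d: dims must be even");
  const int N = D * H * W;
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const int No = Do * Ho * Wo;
  const int C = X.ncol();
  if (X.nrow() != (R_xlen_t)N * B) stop("maxpool3d: nrow(X) mismatch");
  NumericMatrix Y((R_xlen_t)No * B, C);
  IntegerMatrix I((R_xlen_t)No * B, C);
  const double* xp = X.begin();
  const R_xlen_t nr = (R_xlen_t)N * B;
  for (int c = 0; c < C; ++c) {
    const double* xcol = xp + (R_xlen_t)c * nr;
    for (int b = 0; b < B; ++b) {
      const R_xlen_t ibase = (R_xlen_t)b * N;
      const R_xlen_t obase = (R_xlen_t)b * No;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          for (int d = 0; d < Do; ++d) {
            double best = R_NegInf;
            R_xlen_t argmax = 0;
            for (int ow = 0; ow < 2; ++ow)
              for (int oh = 0; oh < 2; ++oh)
                for (int od = 0; od < 2; ++od) {
                  const R_xlen_t src = ibase + (2 * d + od) +
                    (R_xlen_t)D * ((2 * h + oh) + (R_xlen_t)H * (2 * w + ow));
                  const double v = xcol[src];
                  if (v > best) { best = v; argmax = src; }
                }
            const R_xlen_t dst = obase + d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w);
            Y(dst, c) = best;
            I(dst, c) = (int)(argmax + 1);
          }
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = I);
}

// [[Rcpp::export]]
NumericMatrix maxpool3d_bwd(const NumericMatrix& dY, const IntegerMatrix& I,
                            int nrow_in) {
  const int C = dY.ncol();
  NumericMatrix dX(nrow_in, C);
  for (int c = 0; c < C; ++c)
    for (R_xlen_t i = 0; i < dY.nrow(); ++i)
      dX(I(i, c) - 1, c) += dY(i, c);
  return dX;
}
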