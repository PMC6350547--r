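// Hot inner loops of the network: im2col/col2im patch extraction for
// the convolutions and fused per-column affine transforms for batch
// norm. Tensors are (H, W, N, C) column-major; cols matrices are
// (oh*ow*N) x (kh*kw*C) with kernel position varying slower than
// channel within the column blocks, matching the R-side weight layout.
#include <Rcpp.h>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dilation) {
  return (n + 2 * pad - ((k - 1) * dilation + 1)) / stride + 1;
}

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int kh, int kw,
                         int stride, int pad, int dilation) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = out_size(H, kh, stride, pad, dilation);
  const int ow = out_size(W, kw, stride, pad, dilation);
  const R_xlen_t M = (R_xlen_t)oh * ow * N;
  NumericMatrix cols(M, (R_xlen_t)kh * kw * C);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = kj * kh + ki;
        double* col = cp + M * ((R_xlen_t)k * C + c);
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int jo = 0; jo < ow; ++jo) {
            const int jj = kj * dilation + jo * stride - pad;
            double* dst = col + (R_xlen_t)oh * (jo + (R_xlen_t)ow * n);
            if (jj < 0 || jj >= W) {
              for (int io = 0; io < oh; ++io) dst[io] = 0.0;
              continue;
            }
            const double* xcol = xc + (R_xlen_t)H * jj;
            for (int io = 0; io < oh; ++io) {
              const int ii = ki * dilation + io * stride - pad;
              dst[io] = (ii < 0 || ii >= H) ? 0.0 : xcol[ii];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix dcols, IntegerVector dims, int kh,
                         int kw, int stride, int pad, int dilation) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int oh = out_size(H, kh, stride, pad, dilation);
  const int ow = out_size(W, kw, stride, pad, dilation);
  const R_xlen_t M = (R_xlen_t)oh * ow * N;
  NumericVector dx((R_xlen_t)H * W * N * C);
  const double* cp = dcols.begin();
  double* xp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = kj * kh + ki;
        const double* col = cp + M * ((R_xlen_t)k * C + c);
        for (int n = 0; n < N; ++n) {
          double* xc = xp + (R_xlen_t)H * W * (n + (R_xlen_t)N * c);
          for (int jo = 0; jo < ow; ++jo) {
            const int jj = kj * dilation + jo * stride - pad;
            if (jj < 0 || jj >= W) continue;
            const double* src = col + (R_xlen_t)oh * (jo + (R_xlen_t)ow * n);
            double* xcol = xc + (R_xlen_t)H * jj;
            for (int io = 0; io < oh; ++io) {
              const int ii = ki * dilation + io * stride - pad;
              if (ii >= 0 && ii < H) xcol[ii] += src[io];
            }
          }
        }
      }
    }
  }
  return dx;
}

// y[, c] = x[, c] * a[c] + b[c], one pass, no intermediate copies
// [[Rcpp::export(name = ".colaffine_cpp")]]
NumericVector colaffine_cpp(NumericVector x, int ncol, NumericVector a,
                            NumericVector b) {
  const R_xlen_t m = x.size() / ncol;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int c = 0; c < ncol; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xc = xp + m * (R_xlen_t)c;
    double* yc = yp + m * (R_xlen_t)c;
    for (R_xlen_t i = 0; i < m; ++i) yc[i] = xc[i] * ac + bc;
  }
  return y;
}
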