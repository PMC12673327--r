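// Patch gather/scatter kernels for stride-1 dilated convolution.
// Feature maps are column-major arrays with dims (H, W, N, C); the patch
// matrix has H*W*N rows and C*k*k columns (input channel fastest, then
// kernel offset, row offset fastest within the k x k window).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_nhwc(NumericVector x, int H, int W, int N, int C,
                          int k, int dil, int p) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HWN = HW * N;
  NumericMatrix out(HWN, (R_xlen_t)C * k * k);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int ky = 0; ky < k; ++ky) {
    const int dw = ky * dil - p;
    for (int kx = 0; kx < k; ++kx) {
      const int dh = kx * dil - p;
      const int o = kx + k * ky;
      for (int c = 0; c < C; ++c) {
        double* col = op + ((R_xlen_t)c + (R_xlen_t)C * o) * HWN;
        const double* src = xp + (R_xlen_t)c * HWN;
        for (int n = 0; n < N; ++n) {
          const double* srcn = src + (R_xlen_t)n * HW;
          double* dst = col + (R_xlen_t)n * HW;
          for (int w = 0; w < W; ++w) {
            const int w2 = w + dw;
            double* dcol = dst + (R_xlen_t)w * H;
            if (w2 < 0 || w2 >= W) {
              for (int h = 0; h < H; ++h) dcol[h] = 0.0;
              continue;
            }
            const double* scol = srcn + (R_xlen_t)w2 * H;
            for (int h = 0; h < H; ++h) {
              const int h2 = h + dh;
              dcol[h] = (h2 >= 0 && h2 < H) ? scol[h2] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_nhwc(NumericMatrix dP, int H, int W, int N, int C,
                          int k, int dil, int p) {
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HWN = HW * N;
  NumericVector dx(HWN * C);  // zero-initialized
  double* xp = dx.begin();
  const double* op = dP.begin();
  for (int ky = 0; ky < k; ++ky) {
    const int dw = ky * dil - p;
    for (int kx = 0; kx < k; ++kx) {
      const int dh = kx * dil - p;
      const int o = kx + k * ky;
      for (int c = 0; c < C; ++c) {
        const double* col = op + ((R_xlen_t)c + (R_xlen_t)C * o) * HWN;
        double* dst = xp + (R_xlen_t)c * HWN;
        for (int n = 0; n < N; ++n) {
          const double* coln = col + (R_xlen_t)n * HW;
          double* dstn = dst + (R_xlen_t)n * HW;
          for (int w = 0; w < W; ++w) {
            const int w2 = w + dw;
            if (w2 < 0 || w2 >= W) continue;
            const double* scol = coln + (R_xlen_t)w * H;
            double* dcol = dstn + (R_xlen_t)w2 * H;
            for (int h = 0; h < H; ++h) {
              const int h2 = h + dh;
              if (h2 >= 0 && h2 < H) dcol[h2] += scol[h];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// [[Rcpp::export]]
List maxpool2_cpp(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t n_out = (R_xlen_t)Ho * Wo * N * C;
  NumericVector out(n_out);
  IntegerVector which(n_out);
  const double* xp = x.begin();
  double* op = out.begin();
  int* wp = which.begin();
  R_xlen_t oi = 0;
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const double* plane = xp + nc * H * W;
    for (int w = 0; w < Wo; ++w) {
      const double* col0 = plane + (R_xlen_t)(2 * w) * H;
      const double* col1 = plane + (R_xlen_t)(2 * w + 1) * H;
      for (int h = 0; h < Ho; ++h) {
        // window scan order (1,1),(2,1),(1,2),(2,2), first-match ties
        double v0 = col0[2 * h], v1 = col0[2 * h + 1];
        double v2 = col1[2 * h], v3 = col1[2 * h + 1];
        double m = v0; int k = 0;
        if (v1 > m) { m = v1; k = 1; }
        if (v2 > m) { m = v2; k = 2; }
        if (v3 > m) { m = v3; k = 3; }
        op[oi] = m; wp[oi] = k; ++oi;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["out"] = out, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dout, IntegerVector which,
                               int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((R_xlen_t)H * W * N * C);
  const double* dp = dout.begin();
  const int* wp = which.begin();
  double* xp = dx.begin();
  R_xlen_t oi = 0;
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    double* plane = xp + nc * H * W;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int k = wp[oi];
        const int hh = 2 * h + (k & 1);
        const int ww = 2 * w + (k >> 1);
        plane[(R_xlen_t)ww * H + hh] += dp[oi];
        ++oi;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}
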