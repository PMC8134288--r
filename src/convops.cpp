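#include <Rcpp.h>
using namespace Rcpp;

// Batched im2col on arrays stored in R column-major order with dims
// (H, W, C, N): H = rows (axial/depth), W = cols, C = channels, N = batch.
// Output matrix has kh*kw*C rows (kh fastest, then kw, then C — matching the
// flattening of a kernel array with dims (kh, kw, C, Cout)) and Ho*Wo*N
// columns (ho fastest, then wo, then n). Zero padding.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int K = kh * kw * C;
  const R_xlen_t P = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(K, P);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t p = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double* col = op + p * K;
        for (int c = 0; c < C; ++c) {
          const double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = wo * sw - pw + j;
            const bool win = (w >= 0 && w < W);
            for (int i = 0; i < kh; ++i) {
              const int h = ho * sh - ph + i;
              const int r = i + kh * (j + kw * c);
              col[r] = (win && h >= 0 && h < H) ? xc[h + (R_xlen_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add columns back into an (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw, int ph, int pw) {
  const int Ho = (H + 2 * ph - kh) / sh + 1;
  const int Wo = (W + 2 * pw - kw) / sw + 1;
  const int K = kh * kw * C;
  if (cols.nrow() != K || cols.ncol() != (R_xlen_t)Ho * Wo * N)
    stop("col2im_cpp: column matrix shape does not match geometry");
  NumericVector x((R_xlen_t)H * W * C * N);
  const double* cp = cols.begin();
  double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t p = ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double* col = cp + p * K;
        for (int c = 0; c < C; ++c) {
          double* xc = xp + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
          for (int j = 0; j < kw; ++j) {
            const int w = wo * sw - pw + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int h = ho * sh - ph + i;
              if (h < 0 || h >= H) continue;
              xc[h + (R_xlen_t)H * w] += col[i + kh * (j + kw * c)];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
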