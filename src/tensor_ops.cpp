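#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim c(H, W, C, N), column-major.
// im2col row order: r = i + Ho*j + Ho*Wo*n (0-based), so the (Ho*Wo*N) x Cout
// product reshapes to array(., c(Ho, Wo, N, Cout)) followed by aperm.
// Column order: ki + k*kj + k*k*c, matching the weight matrix layout.

// [[Rcpp::export]]
NumericMatrix im2col_hw(const NumericVector& x, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const R_xlen_t R = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(R, k * k * C);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xp = &x[((size_t)n * C + c) * plane];
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int colidx = ki + k * kj + k * k * c;
          double* op = &out(0, colidx);
          for (int j = 0; j < Wo; ++j) {
            const int w = j * stride - pad + kj;
            const bool win = (w >= 0 && w < W);
            double* orow = op + (size_t)Ho * j + (size_t)Ho * Wo * n;
            for (int i = 0; i < Ho; ++i) {
              const int h = i * stride - pad + ki;
              orow[i] = (win && h >= 0 && h < H) ? xp[h + (size_t)H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_hw: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector col2im_hw(const NumericMatrix& cols, int H, int W, int C, int N,
                        int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)H * W * C * N);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xp = &x[((size_t)n * C + c) * plane];
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int colidx = ki + k * kj + k * k * c;
          const double* gp = &cols(0, colidx);
          for (int j = 0; j < Wo; ++j) {
            const int w = j * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            const double* grow = gp + (size_t)Ho * j + (size_t)Ho * Wo * n;
            for (int i = 0; i < Ho; ++i) {
              const int h = i * stride - pad + ki;
              if (h >= 0 && h < H) xp[h + (size_t)H * w] += grow[i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}

// 2x2 stride-2 max pooling; idx holds the 0-based linear argmax into x.
// [[Rcpp::export]]
List maxpool2_fwd(const NumericVector& x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const size_t plane = (size_t)H * W;
  for (long long p = 0; p < (long long)C * N; ++p) {
    const double* xp = &x[(size_t)p * plane];
    double* op = &out[(size_t)p * Ho * Wo];
    int* ip = &idx[(size_t)p * Ho * Wo];
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int h = 2 * i, w = 2 * j;
        int best = h + H * w;
        double bv = xp[best];
        const int cand[3] = {h + 1 + H * w, h + H * (w + 1), h + 1 + H * (w + 1)};
        for (int t = 0; t < 3; ++t)
          if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
        op[i + (size_t)Ho * j] = bv;
        ip[i + (size_t)Ho * j] = (int)((size_t)p * plane) + best;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(const NumericVector& grad, const IntegerVector& idx,
                           int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  const R_xlen_t M = grad.size();
  for (R_xlen_t t = 0; t < M; ++t) dx[idx[t]] += grad[t];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
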