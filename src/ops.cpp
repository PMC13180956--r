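#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Arrays are column-major with dim (H, W, C, N): row index fastest.
// im2col row layout matches flattening a kernel array dim (kh, kw, Cin) in
// column-major order; column m = h_out + Hout*(w_out + Wout*n).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  const int M = Hout * Wout * N;
  NumericMatrix cols(K, M);
  const double *px = x.begin();
  double *pc = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double *img = px + (R_xlen_t)n * planeHW * C;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t m = (R_xlen_t)ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
        double *dst = pc + m * K;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          const double *ch = img + (R_xlen_t)c * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = w0 + kj;
            const bool wok = wi >= 0 && wi < W;
            for (int ki = 0; ki < kh; ++ki, ++r) {
              const int hi = h0 + ki;
              dst[r] = (wok && hi >= 0 && hi < H)
                ? ch[(R_xlen_t)wi * H + hi] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad) {
  const int Hout = (H + 2 * pad - kh) / stride + 1;
  const int Wout = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  NumericVector out((R_xlen_t)H * W * C * N);
  double *po = out.begin();
  const double *pc = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    double *img = po + (R_xlen_t)n * planeHW * C;
    for (int wo = 0; wo < Wout; ++wo) {
      for (int ho = 0; ho < Hout; ++ho) {
        const R_xlen_t m = (R_xlen_t)ho + (R_xlen_t)Hout * (wo + (R_xlen_t)Wout * n);
        const double *src = pc + m * K;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          double *ch = img + (R_xlen_t)c * planeHW;
          for (int kj = 0; kj < kw; ++kj) {
            const int wi = w0 + kj;
            const bool wok = wi >= 0 && wi < W;
            for (int ki = 0; ki < kh; ++ki, ++r) {
              const int hi = h0 + ki;
              if (wok && hi >= 0 && hi < H)
                ch[(R_xlen_t)wi * H + hi] += src[r];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// 2x2 stride-2 max pooling; idx records the 0-based linear offset of the
// winning element so the backward pass routes gradient to a single cell.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx(out.size());
  const double *px = x.begin();
  double *po = out.begin();
  int *pi = idx.begin();
  R_xlen_t o = 0;
  for (R_xlen_t cn = 0; cn < (R_xlen_t)C * N; ++cn) {
    const double *plane = px + cn * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho, ++o) {
        const R_xlen_t base = (R_xlen_t)(2 * wo) * H + 2 * ho;
        R_xlen_t best = base;
        double v = plane[base];
        const R_xlen_t cand[3] = {base + 1, base + H, base + H + 1};
        for (int t = 0; t < 3; ++t)
          if (plane[cand[t]] > v) { v = plane[cand[t]]; best = cand[t]; }
        po[o] = v;
        pi[o] = (int)(cn * H * W + best);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector grad, IntegerVector idx,
                              int H, int W, int C, int N) {
  NumericVector dx((R_xlen_t)H * W * C * N);
  double *pd = dx.begin();
  const double *pg = grad.begin();
  const int *pi = idx.begin();
  for (R_xlen_t i = 0; i < grad.size(); ++i) pd[pi[i]] += pg[i];
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

static inline int reflect_idx(int i, int n) {
  // symmetric reflection (edge duplicated): -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Square median filter, per channel, reflect padding.
// [[Rcpp::export]]
NumericVector cpp_median_filter(NumericVector x, int H, int W, int C,
                                int window) {
  const int r = window / 2;
  NumericVector out((R_xlen_t)H * W * C);
  std::vector<double> buf(window * window);
  const double *px = x.begin();
  double *po = out.begin();
  const int half = (window * window) / 2; // window odd -> odd count, true median
  for (int c = 0; c < C; ++c) {
    const double *ch = px + (R_xlen_t)c * H * W;
    double *oc = po + (R_xlen_t)c * H * W;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        int t = 0;
        for (int dw = -r; dw <= r; ++dw) {
          const int wi = reflect_idx(w + dw, W);
          for (int dh = -r; dh <= r; ++dh)
            buf[t++] = ch[(R_xlen_t)wi * H + reflect_idx(h + dh, H)];
        }
        std::nth_element(buf.begin(), buf.begin() + half, buf.end());
        oc[(R_xlen_t)w * H + h] = buf[half];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// Reshape a Cout x (Hout*Wout*N) gemm result into an (Hout, Wout, Cout, N)
// feature map (and back), replacing aperm round-trips in the conv layers.
// [[Rcpp::export]]
NumericVector cpp_mat2feat(NumericMatrix m, int Ho, int Wo, int C, int N) {
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  double *po = out.begin();
  const double *pm = m.begin();
  const R_xlen_t hw = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double *dst = po + ((R_xlen_t)n * C + c) * hw;
      const double *src = pm + c;               // column-major: row c, stride C
      const R_xlen_t base = (R_xlen_t)n * hw;
      for (R_xlen_t s = 0; s < hw; ++s)
        dst[s] = src[(base + s) * C];
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_feat2mat(NumericVector x, int Ho, int Wo, int C, int N) {
  NumericMatrix m(C, (R_xlen_t)Ho * Wo * N);
  double *pm = m.begin();
  const double *px = x.begin();
  const R_xlen_t hw = (R_xlen_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *src = px + ((R_xlen_t)n * C + c) * hw;
      double *dst = pm + c;
      const R_xlen_t base = (R_xlen_t)n * hw;
      for (R_xlen_t s = 0; s < hw; ++s)
        dst[(base + s) * C] = src[s];
    }
  return m;
}
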