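// Hot inner primitives of the convolutional classifier: im2col gather,
// col2im scatter-add, and 2x2/stride-2 max-pool forward/backward.
// Tensors are column-major (H, W, N, C) arrays; im2col rows are ordered
// (oh, ow, n) and columns (kh, kw, cin) offset-major, matching flat_kernel()
// on the R side. GEMMs stay in R (BLAS).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int Cin) {
  const int OH = H - 2, OW = W - 2;
  const R_xlen_t rows = (R_xlen_t)OH * OW * N;
  NumericMatrix out(rows, 9 * Cin);
  const double* px = REAL(x);
  for (int cin = 0; cin < Cin; ++cin) {
    const double* base = px + (R_xlen_t)cin * H * W * N;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int k = kw * 3 + kh;
        double* pc = REAL(out) + (R_xlen_t)(k * Cin + cin) * rows;
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          const double* pn = base + (R_xlen_t)n * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            const double* p = pn + (R_xlen_t)(ow + kw) * H + kh;
            for (int oh = 0; oh < OH; ++oh) pc[r++] = p[oh];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dXcol, int H, int W, int N, int Cin) {
  const int OH = H - 2, OW = W - 2;
  const R_xlen_t rows = (R_xlen_t)OH * OW * N;
  NumericVector dx((R_xlen_t)H * W * N * Cin);  // zero-initialized
  double* pdx = REAL(dx);
  const double* pcol = REAL(dXcol);
  for (int cin = 0; cin < Cin; ++cin) {
    double* base = pdx + (R_xlen_t)cin * H * W * N;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const int k = kw * 3 + kh;
        const double* pc = pcol + (R_xlen_t)(k * Cin + cin) * rows;
        R_xlen_t r = 0;
        for (int n = 0; n < N; ++n) {
          double* pn = base + (R_xlen_t)n * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            double* p = pn + (R_xlen_t)(ow + kw) * H + kh;
            for (int oh = 0; oh < OH; ++oh) p[oh] += pc[r++];
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, Cin);
  return dx;
}

// Max-pool 2x2 stride 2 (odd trailing row/col dropped). Returns pooled
// values and the linear argmax index into the input.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int N, int C) {
  const int H2 = H / 2, W2 = W / 2;
  const R_xlen_t npool = (R_xlen_t)H2 * W2 * N * C;
  NumericVector out(npool);
  NumericVector arg(npool);  // 1-based linear index, stored as double
  const double* px = REAL(x);
  double* po = REAL(out);
  double* pa = REAL(arg);
  R_xlen_t r = 0;
  for (R_xlen_t nc = 0; nc < (R_xlen_t)N * C; ++nc) {
    const double* pn = px + nc * H * W;
    for (int w2 = 0; w2 < W2; ++w2) {
      for (int h2 = 0; h2 < H2; ++h2) {
        const R_xlen_t i00 = (R_xlen_t)(2 * w2) * H + 2 * h2;
        R_xlen_t best = i00;
        double v = pn[i00];
        const R_xlen_t cand[3] = {i00 + 1, i00 + H, i00 + H + 1};
        for (int t = 0; t < 3; ++t)
          if (pn[cand[t]] > v) { v = pn[cand[t]]; best = cand[t]; }
        po[r] = v;
        pa[r] = (double)(nc * H * W + best + 1);
        ++r;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H2, W2, N, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dM, NumericVector argmax,
                              int H, int W, int N, int C) {
  NumericVector dx((R_xlen_t)H * W * N * C);
  double* pdx = REAL(dx);
  const double* pd = REAL(dM);
  const double* pa = REAL(argmax);
  const R_xlen_t n = dM.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[(R_xlen_t)pa[i] - 1] += pd[i];
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}

// 4x4 stride-1 average pool, separable sliding sums.
// [[Rcpp::export]]
NumericVector cpp_avgpool4(NumericVector x, int H, int W, int N, int C) {
  const int P = H - 3, Q = W - 3;
  const R_xlen_t planes = (R_xlen_t)N * C;
  NumericVector out((R_xlen_t)P * Q * planes);
  std::vector<double> tmp((size_t)H * Q);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (R_xlen_t pl = 0; pl < planes; ++pl) {
    const double* pin = px + pl * H * W;
    for (int h = 0; h < H; ++h) {
      double s = pin[h] + pin[h + H] + pin[h + 2 * H] + pin[h + 3 * H];
      tmp[h] = s;
      for (int q = 1; q < Q; ++q) {
        s += pin[h + (R_xlen_t)(q + 3) * H] - pin[h + (R_xlen_t)(q - 1) * H];
        tmp[h + (size_t)q * H] = s;
      }
    }
    double* pout = po + pl * P * Q;
    for (int q = 0; q < Q; ++q) {
      const double* t = &tmp[(size_t)q * H];
      double s = t[0] + t[1] + t[2] + t[3];
      pout[(R_xlen_t)q * P] = s / 16.0;
      for (int p = 1; p < P; ++p) {
        s += t[p + 3] - t[p - 1];
        pout[(R_xlen_t)q * P + p] = s / 16.0;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(P, Q, N, C);
  return out;
}
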