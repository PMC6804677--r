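// Factored spatio-temporal convolution kernels for the video classifier.
// Tensors are column-major numeric arrays [c, t, h, w, n]; kernels are
// [cOut, cIn, kt, kh, kw]. The convolutions are evaluated through an
// im2col gather followed by one BLAS matrix product (and the transposed
// products plus a col2im scatter for the backward pass).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outDim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// gather the padded receptive fields into a (cIn*kt*kh*kw) x (to*ho*wo*n)
// matrix; rows are ordered c fastest, then dt, dy, dx (matching the R-side
// reshape of the kernel array), columns t fastest, then y, x, batch.
static arma::mat im2col(const double* X, int c, int t, int h, int w, int n,
                        int kt, int kh, int kw,
                        int st, int sh, int sw,
                        int pt, int ph, int pw,
                        int to, int ho, int wo) {
  arma::mat col(c * kt * kh * kw, (size_t)to * ho * wo * n, arma::fill::zeros);
  const size_t strideT = c, strideH = (size_t)c * t,
               strideW = (size_t)c * t * h, strideN = (size_t)c * t * h * w;
  size_t j = 0;
  for (int nn = 0; nn < n; ++nn)
    for (int x = 0; x < wo; ++x)
      for (int y = 0; y < ho; ++y)
        for (int tt = 0; tt < to; ++tt, ++j) {
          double* dst = col.colptr(j);
          for (int dx = 0; dx < kw; ++dx) {
            int xi = x * sw - pw + dx;
            for (int dy = 0; dy < kh; ++dy) {
              int yi = y * sh - ph + dy;
              for (int dt = 0; dt < kt; ++dt) {
                int ti = tt * st - pt + dt;
                double* d = dst + (size_t)c * (dt + (size_t)kt * (dy + (size_t)kh * dx));
                if (ti >= 0 && ti < t && yi >= 0 && yi < h && xi >= 0 && xi < w) {
                  const double* s = X + strideN * nn + strideW * xi +
                                    strideH * yi + strideT * ti;
                  for (int ci = 0; ci < c; ++ci) d[ci] = s[ci];
                }
              }
            }
          }
        }
  // column order produced above is (t, y, x, n); callers expect t fastest,
  // then y (ho), x (wo), n -- which is exactly this order.
  return col;
}

// [[Rcpp::export(name = ".conv5dForward")]]
NumericVector conv5dForward(NumericVector X, NumericVector W,
                            Nullable<NumericVector> bias,
                            IntegerVector stride, IntegerVector pad) {
  IntegerVector dx = X.attr("dim"), dw = W.attr("dim");
  int c = dx[0], t = dx[1], h = dx[2], w = dx[3], n = dx[4];
  int cOut = dw[0], kt = dw[2], kh = dw[3], kw = dw[4];
  if (dw[1] != c) stop("channel mismatch in convolution");
  int to = outDim(t, kt, stride[0], pad[0]);
  int ho = outDim(h, kh, stride[1], pad[1]);
  int wo = outDim(w, kw, stride[2], pad[2]);
  if (to < 1 || ho < 1 || wo < 1) stop("convolution output extent is non-positive");
  arma::mat col = im2col(X.begin(), c, t, h, w, n, kt, kh, kw,
                         stride[0], stride[1], stride[2],
                         pad[0], pad[1], pad[2], to, ho, wo);
  arma::mat Wm(W.begin(), cOut, (size_t)c * kt * kh * kw, false, true);
  arma::mat Y = Wm * col;
  if (bias.isNotNull()) {
    NumericVector b(bias);
    arma::vec bv(b.begin(), cOut, false, true);
    Y.each_col() += bv;
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(cOut, to, ho, wo, n);
  return out;
}

// [[Rcpp::export(name = ".conv5dBackward")]]
List conv5dBackward(NumericVector X, NumericVector W, NumericVector dY,
                    IntegerVector stride, IntegerVector pad, bool hasBias) {
  IntegerVector dx = X.attr("dim"), dw = W.attr("dim"), dyd = dY.attr("dim");
  int c = dx[0], t = dx[1], h = dx[2], w = dx[3], n = dx[4];
  int cOut = dw[0], kt = dw[2], kh = dw[3], kw = dw[4];
  int to = dyd[1], ho = dyd[2], wo = dyd[3];
  size_t M = (size_t)to * ho * wo * n;
  arma::mat col = im2col(X.begin(), c, t, h, w, n, kt, kh, kw,
                         stride[0], stride[1], stride[2],
                         pad[0], pad[1], pad[2], to, ho, wo);
  arma::mat dYm(dY.begin(), cOut, M, false, true);
  arma::mat Wm(W.begin(), cOut, (size_t)c * kt * kh * kw, false, true);
  arma::mat dWm = dYm * col.t();
  arma::mat dcol = Wm.t() * dYm;
  // col2im scatter-add
  NumericVector dXv((size_t)c * t * h * w * n);
  dXv.attr("dim") = dx;
  double* dX = dXv.begin();
  const size_t strideT = c, strideH = (size_t)c * t,
               strideW = (size_t)c * t * h, strideN = (size_t)c * t * h * w;
  size_t j = 0;
  for (int nn = 0; nn < n; ++nn)
    for (int x = 0; x < wo; ++x)
      for (int y = 0; y < ho; ++y)
        for (int tt = 0; tt < to; ++tt, ++j) {
          const double* src = dcol.colptr(j);
          for (int dxk = 0; dxk < kw; ++dxk) {
            int xi = x * stride[2] - pad[2] + dxk;
            if (xi < 0 || xi >= w) continue;
            for (int dyk = 0; dyk < kh; ++dyk) {
              int yi = y * stride[1] - pad[1] + dyk;
              if (yi < 0 || yi >= h) continue;
              for (int dtk = 0; dtk < kt; ++dtk) {
                int ti = tt * stride[0] - pad[0] + dtk;
                if (ti < 0 || ti >= t) continue;
                const double* s = src + (size_t)c *
                  (dtk + (size_t)kt * (dyk + (size_t)kh * dxk));
                double* d = dX + strideN * nn + strideW * xi +
                            strideH * yi + strideT * ti;
                for (int ci = 0; ci < c; ++ci) d[ci] += s[ci];
              }
            }
          }
        }
  NumericVector dWv(dWm.begin(), dWm.end());
  dWv.attr("dim") = dw;
  List out = List::create(Named("dX") = dXv, Named("dW") = dWv);
  if (hasBias) {
    arma::vec db = arma::sum(dYm, 1);
    out["db"] = NumericVector(db.begin(), db.end());
  }
  return out;
}
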