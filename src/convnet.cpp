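// Convolution and max-pooling kernels for the ConvNet training loop.
// Layout conventions (column-major, matching R arrays):
//   images  X : (H, W, C, N)
//   filters W : (k, k, C, F), odd k, same padding, stride 1
//   pooling   : window 2, stride 2 (dims must be even; checked in R)
// The whole batch is lowered to a single im2col matrix so each layer call
// costs one GEMM, which keeps BLAS efficient for small filter counts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Lower a batch to A: (k*k*C) x (H*W*N)
static arma::mat im2col_batch(const double* X, int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  arma::mat A(k * k * C, (size_t)H * W * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const double* x = X + (size_t)H * W * C * n;
    double* acol0 = A.colptr((size_t)H * W * n);
    const size_t lda = A.n_rows;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* acol = acol0 + lda * (h + (size_t)H * w);
        int row = 0;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + (size_t)H * W * c;
          for (int dw = 0; dw < k; ++dw) {
            const int ww = w + dw - pad;
            const bool wok = (ww >= 0 && ww < W);
            for (int dh = 0; dh < k; ++dh, ++row) {
              const int hh = h + dh - pad;
              if (wok && hh >= 0 && hh < H)
                acol[row] = xc[hh + H * ww];
            }
          }
        }
      }
    }
  }
  return A;
}

static void col2im_batch_acc(const arma::mat& dA, double* dX,
                             int H, int W, int C, int N, int k) {
  const int pad = (k - 1) / 2;
  for (int n = 0; n < N; ++n) {
    double* dx = dX + (size_t)H * W * C * n;
    const size_t lda = dA.n_rows;
    const double* acol0 = dA.colptr((size_t)H * W * n);
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double* acol = acol0 + lda * (h + (size_t)H * w);
        int row = 0;
        for (int c = 0; c < C; ++c) {
          double* dxc = dx + (size_t)H * W * c;
          for (int dw = 0; dw < k; ++dw) {
            const int ww = w + dw - pad;
            const bool wok = (ww >= 0 && ww < W);
            for (int dh = 0; dh < k; ++dh, ++row) {
              const int hh = h + dh - pad;
              if (wok && hh >= 0 && hh < H)
                dxc[hh + H * ww] += acol[row];
            }
          }
        }
      }
    }
  }
}

// filters as F x (k*k*C), rows match im2col row order
static arma::mat filter_matrix(const NumericVector& Wt, int k, int C, int F) {
  arma::mat Wm(F, k * k * C);
  for (int f = 0; f < F; ++f) {
    int r = 0;
    for (int c = 0; c < C; ++c)
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh, ++r)
          Wm(f, r) = Wt[dh + k * (dw + k * (c + C * f))];
  }
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector X, NumericVector Wt, NumericVector b) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  arma::mat Wm = filter_matrix(Wt, k, C, F);
  arma::mat A = im2col_batch(&X[0], H, W, C, N, k);
  arma::mat Ym = Wm * A;                         // F x (H*W*N)
  NumericVector Y((size_t)H * W * F * N);
  const size_t plane = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      double* y = &Y[0] + plane * (f + (size_t)F * n);
      const double bf = b[f];
      for (size_t p = 0; p < plane; ++p)
        y[p] = Ym(f, plane * n + p) + bf;
    }
  Y.attr("dim") = IntegerVector::create(H, W, F, N);
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector X, NumericVector Wt, NumericVector dY) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  arma::mat Wm = filter_matrix(Wt, k, C, F);
  arma::mat A = im2col_batch(&X[0], H, W, C, N, k);
  const size_t plane = (size_t)H * W;
  arma::mat dYm(F, plane * N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* dy = &dY[0] + plane * (f + (size_t)F * n);
      for (size_t p = 0; p < plane; ++p)
        dYm(f, plane * n + p) = dy[p];
    }
  arma::mat dWm = dYm * A.t();                   // F x (k*k*C)
  arma::vec db = arma::sum(dYm, 1);
  arma::mat dA = Wm.t() * dYm;                   // (k*k*C) x (H*W*N)
  NumericVector dX((size_t)H * W * C * N);
  col2im_batch_acc(dA, &dX[0], H, W, C, N, k);
  NumericVector dWt((size_t)k * k * C * F);
  for (int f = 0; f < F; ++f) {
    int r = 0;
    for (int c = 0; c < C; ++c)
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh, ++r)
          dWt[dh + k * (dw + k * (c + C * f))] = dWm(f, r);
  }
  dWt.attr("dim") = IntegerVector::create(k, k, C, F);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dX"] = dX, _["dW"] = dWt,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);    // 0-based index into X
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const size_t offo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bidx = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const size_t idx = off + (2 * ho + dh) + (size_t)H * (2 * wo + dw);
              if (X[idx] > best) { best = X[idx]; bidx = idx; }
            }
          Y[offo + ho + (size_t)Ho * wo] = best;
          arg[offo + ho + (size_t)Ho * wo] = (int)bidx;
        }
    }
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["Y"] = Y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dY, IntegerVector argmax,
                                   IntegerVector xdim) {
  NumericVector dX((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dY.size(); ++i)
    dX[argmax[i]] += dY[i];
  dX.attr("dim") = xdim;
  return dX;
}
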