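// Convolution and pooling kernels for the segmentation network.
// Layout convention: image batches are R arrays of dim (H, W, C, N),
// column-major. Convolution weights are matrices of dim (k*k*Cin, Cout)
// with column index c*k*k + kj*k + ki (channel, window column, window row).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* X, int H, int W, int C,
                       int k, int stride, int pad, arma::mat& M) {
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  M.zeros(H2 * W2, k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        double* Mc = M.colptr(col);
        for (int j2 = 0; j2 < W2; ++j2) {
          const int j = j2 * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          const double* Xcj = Xc + (size_t)j * H;
          double* Mcj = Mc + (size_t)j2 * H2;
          for (int i2 = 0; i2 < H2; ++i2) {
            const int i = i2 * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            Mcj[i2] = Xcj[i];
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& M, int H, int W, int C,
                       int k, int stride, int pad, double* dX) {
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  for (int c = 0; c < C; ++c) {
    double* dXc = dX + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = c * k * k + kj * k + ki;
        const double* Mc = M.colptr(col);
        for (int j2 = 0; j2 < W2; ++j2) {
          const int j = j2 * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* dXcj = dXc + (size_t)j * H;
          const double* Mcj = Mc + (size_t)j2 * H2;
          for (int i2 = 0; i2 < H2; ++i2) {
            const int i = i2 * stride - pad + ki;
            if (i < 0 || i >= H) continue;
            dXcj[i] += Mcj[i2];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector X, NumericMatrix Wm, NumericVector b,
                           int k, int stride, int pad, bool use_bias) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector Y(Rcpp::no_init((size_t)H2 * W2 * Cout * N));
  Y.attr("dim") = IntegerVector::create(H2, W2, Cout, N);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col_one(X.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, M);
    arma::mat Yn(Y.begin() + (size_t)n * H2 * W2 * Cout,
                 (size_t)H2 * W2, Cout, false, true);
    Yn = M * Wa;
    if (use_bias)
      for (int c = 0; c < Cout; ++c) Yn.col(c) += b[c];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector X, NumericMatrix Wm, NumericVector dY,
                  int k, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.ncol();
  arma::mat Wa(Wm.begin(), Wm.nrow(), Cout, false);
  NumericVector dX((size_t)H * W * C * N);  // zero-initialised
  dX.attr("dim") = d;
  arma::mat dW(Wm.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    im2col_one(X.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, M);
    arma::mat dYn(dY.begin() + (size_t)n * H2 * W2 * Cout,
                  (size_t)H2 * W2, Cout, false);
    dW += M.t() * dYn;
    db += arma::sum(dYn, 0).t();
    arma::mat dM = dYn * Wa.t();
    col2im_one(dM, H, W, C, k, stride, pad,
               dX.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dX"] = dX, _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// Batch norm over (H, W, N) per channel. Forward returns the normalised
// activations xh (cached for backward) alongside the output.
// [[Rcpp::export]]
List cpp_bn2d_fwd(NumericVector X, NumericVector g, NumericVector b,
                  NumericVector mu, NumericVector istd) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector Y(Rcpp::no_init(X.size())), XH(Rcpp::no_init(X.size()));
  Y.attr("dim") = d; XH.attr("dim") = d;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = istd[c], gc = g[c], bc = b[c];
      const double* xp = X.begin() + ((size_t)n * C + c) * plane;
      double* yp = Y.begin() + ((size_t)n * C + c) * plane;
      double* hp = XH.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) {
        const double xh = (xp[t] - m) * is;
        hp[t] = xh;
        yp[t] = gc * xh + bc;
      }
    }
  return List::create(_["Y"] = Y, _["xh"] = XH);
}

// [[Rcpp::export]]
List cpp_channel_stats(NumericVector X) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xp = X.begin() + ((size_t)n * C + c) * plane;
      for (size_t t = 0; t < plane; ++t) { s += xp[t]; s2 += xp[t] * xp[t]; }
    }
    const double M = (double)plane * N;
    mu[c] = s / M;
    var[c] = s2 / M - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn2d_bwd(NumericVector dY, NumericVector XH, NumericVector g,
                  NumericVector istd) {
  IntegerVector d = dY.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double M = (double)plane * N;
  NumericVector dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * plane;
      const double* dp = dY.begin() + off;
      const double* hp = XH.begin() + off;
      for (size_t t = 0; t < plane; ++t) { sg += dp[t] * hp[t]; sb += dp[t]; }
    }
    dg[c] = sg; db[c] = sb;
  }
  NumericVector dX(Rcpp::no_init(dY.size()));
  dX.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double t1 = g[c] * db[c] / M, t2 = g[c] * dg[c] / M,
                 is = istd[c], gc = g[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * plane;
      const double* dp = dY.begin() + off;
      const double* hp = XH.begin() + off;
      double* xp = dX.begin() + off;
      for (size_t t = 0; t < plane; ++t)
        xp[t] = is * (gc * dp[t] - t1 - hp[t] * t2);
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector X, int k, int stride, int pad) {
  IntegerVector d = X.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int H2 = (H + 2 * pad - k) / stride + 1;
  const int W2 = (W + 2 * pad - k) / stride + 1;
  NumericVector Y(Rcpp::no_init((size_t)H2 * W2 * C * N));
  IntegerVector idx(Rcpp::no_init((size_t)H2 * W2 * C * N));
  Y.attr("dim") = IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + ((size_t)n * C + c) * H * W;
      for (int j2 = 0; j2 < W2; ++j2)
        for (int i2 = 0; i2 < H2; ++i2) {
          double best = -1e300; int bi = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int j = j2 * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int i = i2 * stride - pad + ki;
              if (i < 0 || i >= H) continue;
              const double v = Xc[(size_t)j * H + i];
              if (v > best) { best = v; bi = j * H + i; }
            }
          }
          // column-major output order is (i2, j2, c, n); recompute offset
          const size_t oo = (((size_t)n * C + c) * W2 + j2) * H2 + i2;
          Y[oo] = best; idx[oo] = bi;
          (void)o;
        }
    }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dY, IntegerVector idx,
                              IntegerVector in_dim) {
  IntegerVector d = dY.attr("dim");
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = in_dim[0], W = in_dim[1];
  NumericVector dX((size_t)H * W * C * N);
  dX.attr("dim") = in_dim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dXc = dX.begin() + ((size_t)n * C + c) * H * W;
      const size_t base = ((size_t)n * C + c) * H2 * W2;
      for (size_t t = 0; t < (size_t)H2 * W2; ++t) {
        const int bi = idx[base + t];
        if (bi >= 0) dXc[bi] += dY[base + t];
      }
    }
  return dX;
}
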