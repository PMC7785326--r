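// Convolution and pooling kernels for the segmentation network.
// Tensor layout (R column-major): activations (H, W, C, N); convolution
// weights (KH, KW, Cin, Cout). Convolutions are implemented as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uvec get_dims(const NumericVector& x, int need) {
  IntegerVector d = x.attr("dim");
  if (d.size() != need) stop("tensor has wrong number of dimensions");
  arma::uvec out(need);
  for (int i = 0; i < need; ++i) out[i] = d[i];
  return out;
}

// Build the im2col matrix for one sample: rows index (kh, kw, ci), columns
// index output positions (ho + Ho*wo).
static void im2col(const double* x, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, arma::mat& A) {
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int row = kh + KH * (kw + KW * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          double* Acol = A.memptr() + (size_t)row +
            (size_t)A.n_rows * (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) Acol[(size_t)A.n_rows * ho] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            Acol[(size_t)A.n_rows * ho] =
              (hi < 0 || hi >= H) ? 0.0 : xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix back into an image (adjoint of im2col).
static void col2im(const arma::mat& A, int H, int W, int C,
                   int KH, int KW, int stride, int pad,
                   int Ho, int Wo, double* x) {
  for (int ci = 0; ci < C; ++ci) {
    double* xc = x + (size_t)ci * H * W;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int row = kh + KH * (kw + KW * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* Acol = A.memptr() + (size_t)row +
            (size_t)A.n_rows * (size_t)Ho * wo;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H) xcol[hi] += Acol[(size_t)A.n_rows * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector wgt,
                                 NumericVector bias, int stride, int pad) {
  arma::uvec xd = get_dims(x, 4), wd = get_dims(wgt, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = (H + 2 * pad - KH) / stride + 1;
  int Wo = (W + 2 * pad - KW) / stride + 1;
  int R = KH * KW * C;

  // weight matrix: Cout x R, row co holds the filter for output channel co
  arma::mat Wm(Cout, R);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      Wm(co, r) = wgt[(size_t)r + (size_t)R * co];

  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::mat A(R, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
           Ho, Wo, A);
    arma::mat Y = Wm * A;                     // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      double b = bias[co];
      const double* Yr = Y.memptr() + co;     // stride Cout across columns
      double* yc = yp + (size_t)co * Ho * Wo;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yc[p] = Yr[(size_t)Cout * p] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward_cpp(NumericVector x, NumericVector wgt,
                         NumericVector dy, int stride, int pad) {
  arma::uvec xd = get_dims(x, 4), wd = get_dims(wgt, 4), yd = get_dims(dy, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  int R = KH * KW * C;

  arma::mat Wm(Cout, R);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      Wm(co, r) = wgt[(size_t)r + (size_t)R * co];

  arma::mat dWm(Cout, R, arma::fill::zeros);
  NumericVector db(Cout);
  NumericVector dx((size_t)H * W * C * N);
  arma::mat A(R, (size_t)Ho * Wo);
  arma::mat dY(Cout, (size_t)Ho * Wo);

  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double* dyc = dyp + (size_t)co * Ho * Wo;
      double s = 0.0;
      double* dYr = dY.memptr() + co;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        dYr[(size_t)Cout * p] = dyc[p];
        s += dyc[p];
      }
      db[co] += s;
    }
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride, pad,
           Ho, Wo, A);
    dWm += dY * A.t();
    arma::mat dA = Wm.t() * dY;               // R x (Ho*Wo)
    col2im(dA, H, W, C, KH, KW, stride, pad, Ho, Wo,
           dx.begin() + (size_t)n * H * W * C);
  }

  NumericVector dw((size_t)R * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < R; ++r)
      dw[(size_t)r + (size_t)R * co] = dWm(co, r);
  dw.attr("dim") = IntegerVector::create(KH, KW, C, Cout);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export(name = ".maxpool_forward")]]
List maxpool_forward_cpp(NumericVector x, int k, int stride, int pad) {
  arma::uvec xd = get_dims(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector arg((size_t)Ho * Wo * C * N);   // flat index into x, 0-based
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)C * n) * H * W;
      size_t base = (size_t)(c + (size_t)C * n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; long bidx = -1;
          for (int kw = 0; kw < k; ++kw) {
            int wi = wo * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              int hi = ho * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bidx = hi + (size_t)H * wi; }
            }
          }
          size_t oidx = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[oidx] = (bidx < 0) ? 0.0 : best;
          arg[oidx] = (bidx < 0) ? -1 : (int)(base + bidx);
          ++q;
        }
      }
    }
  }
  (void)q;
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// [[Rcpp::export(name = ".maxpool_backward")]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector argmax,
                                   IntegerVector x_dim) {
  size_t total = 1;
  for (int i = 0; i < x_dim.size(); ++i) total *= (size_t)x_dim[i];
  NumericVector dx(total);
  for (R_xlen_t i = 0; i < dy.size(); ++i) {
    int a = argmax[i];
    if (a >= 0) dx[a] += dy[i];
  }
  dx.attr("dim") = x_dim;
  return dx;
}

// Batch normalisation over (H, W, N) per channel, layout (H, W, C, N).

// [[Rcpp::export(name = ".bn_forward")]]
List bn_forward_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                    double eps, bool training,
                    NumericVector run_mean, NumericVector run_var) {
  arma::uvec xd = get_dims(x, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  size_t m = HW * N;
  NumericVector y(x.size());
  NumericVector mu(C), inv(C), var(C);
  NumericVector xhat;
  if (training) {
    xhat = NumericVector(x.size());
    for (int c = 0; c < C; ++c) {
      double s = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t p = 0; p < HW; ++p) s += xc[p];
      }
      double mc = s / m;
      double v = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        for (size_t p = 0; p < HW; ++p) {
          double d = xc[p] - mc;
          v += d * d;
        }
      }
      v /= m;
      double ic = 1.0 / std::sqrt(v + eps);
      mu[c] = mc; var[c] = v; inv[c] = ic;
      double g = gamma[c], b = beta[c];
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        double* yc = y.begin() + ((size_t)n * C + c) * HW;
        double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
        for (size_t p = 0; p < HW; ++p) {
          double h = (xc[p] - mc) * ic;
          hc[p] = h;
          yc[p] = g * h + b;
        }
      }
    }
  } else {
    for (int c = 0; c < C; ++c) {
      double ic = 1.0 / std::sqrt(run_var[c] + eps);
      double mc = run_mean[c], g = gamma[c], b = beta[c];
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * HW;
        double* yc = y.begin() + ((size_t)n * C + c) * HW;
        for (size_t p = 0; p < HW; ++p)
          yc[p] = g * (xc[p] - mc) * ic + b;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  if (training) xhat.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("mu") = mu, Named("var") = var,
                      Named("inv") = inv);
}

// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat,
                     NumericVector inv, NumericVector gamma) {
  arma::uvec xd = get_dims(dy, 4);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t HW = (size_t)H * W;
  size_t m = HW * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + ((size_t)n * C + c) * HW;
      const double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HW; ++p) {
        sb += dc[p];
        sg += dc[p] * hc[p];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    double g = gamma[c], ic = inv[c];
    double mb = sb / m, mg = sg / m;
    for (int n = 0; n < N; ++n) {
      const double* dc = dy.begin() + ((size_t)n * C + c) * HW;
      const double* hc = xhat.begin() + ((size_t)n * C + c) * HW;
      double* xc = dx.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HW; ++p)
        xc[p] = g * ic * (dc[p] - mb - hc[p] * mg);
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}
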