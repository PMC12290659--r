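// Minimal CNN kernels for the width-reduced residual encoder.
// Activation layout: R arrays of dim (H, W, C, N), column-major.
// Conv weights: (Cout x Cin*KH*KW) matrices, row index over output channel,
// column index ordered as (cin * KH + kh) * KW + kw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int outSize(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Transposed im2col: colT is (L x K) with L = HO*WO output pixels and
// K = C*KH*KW stencil entries; writes run down columns (stride 1).
// ldRow is the leading dimension of the batch-stacked matrix (L*N).
static void im2colT(const double* x, int H, int W, int C,
                    int KH, int KW, int stride, int pad,
                    double* colT, size_t ldRow) {
  const int HO = outSize(H, KH, stride, pad);
  const int WO = outSize(W, KW, stride, pad);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kh = 0; kh < KH; ++kh) {
      for (int kw = 0; kw < KW; ++kw) {
        const int k = (c * KH + kh) * KW + kw;
        double* dst = colT + (size_t)k * ldRow;
        for (int wo = 0; wo < WO; ++wo) {
          const int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < HO; ++ho) dst[ho + (size_t)HO * wo] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * wi;
          for (int ho = 0; ho < HO; ++ho) {
            const int hi = ho * stride + kh - pad;
            dst[ho + (size_t)HO * wo] =
              (hi < 0 || hi >= H) ? 0.0 : src[hi];
          }
        }
      }
    }
  }
}

static void col2imT(const double* colT, int H, int W, int C,
                    int KH, int KW, int stride, int pad,
                    double* x, size_t ldRow) {
  const int HO = outSize(H, KH, stride, pad);
  const int WO = outSize(W, KW, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kh = 0; kh < KH; ++kh) {
      for (int kw = 0; kw < KW; ++kw) {
        const int k = (c * KH + kh) * KW + kw;
        const double* src = colT + (size_t)k * ldRow;
        for (int wo = 0; wo < WO; ++wo) {
          const int wi = wo * stride + kw - pad;
          if (wi < 0 || wi >= W) continue;
          double* dstc = xc + (size_t)H * wi;
          for (int ho = 0; ho < HO; ++ho) {
            const int hi = ho * stride + kh - pad;
            if (hi < 0 || hi >= H) continue;
            dstc[hi] += src[ho + (size_t)HO * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_forward")]]
NumericVector cppConvForward(NumericVector x, NumericMatrix w,
                             NumericVector b, int KH, int KW,
                             int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.nrow();
  const int K = w.ncol();
  const int HO = outSize(H, KH, stride, pad);
  const int WO = outSize(W, KW, stride, pad);
  const int L = HO * WO;
  NumericVector y((R_xlen_t)L * Cout * N);
  y.attr("dim") = IntegerVector::create(HO, WO, Cout, N);
  arma::mat wm(w.begin(), Cout, K, false, true);
  if (KH == 1 && KW == 1 && stride == 1 && pad == 0) {
    // 1x1 conv: per-sample GEMM on aliased memory, no im2col copies
    arma::mat wt = wm.t();             // C x Cout
    for (int n = 0; n < N; ++n) {
      arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * L * C,
                   L, C, false, true);
      arma::mat yn(y.begin() + (size_t)n * L * Cout, L, Cout, false, true);
      yn = xn * wt;
      for (int co = 0; co < Cout; ++co)
        if (b[co] != 0.0) yn.col(co) += b[co];
    }
    return y;
  }
  const size_t ldRow = (size_t)L * N;
  arma::mat colT(ldRow, K, arma::fill::none);
  for (int n = 0; n < N; ++n)
    im2colT(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride,
            pad, colT.memptr() + (size_t)n * L, ldRow);
  arma::mat Y = colT * wm.t();          // (L*N) x Cout, one GEMM
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* src = Y.colptr(co) + (size_t)n * L;
      double* dst = y.begin() + ((size_t)n * Cout + co) * L;
      const double bc = b[co];
      for (int j = 0; j < L; ++j) dst[j] = src[j] + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_backward")]]
List cppConvBackward(NumericVector x, NumericMatrix w, NumericVector dy,
                     int KH, int KW, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.nrow();
  const int K = w.ncol();
  const int HO = outSize(H, KH, stride, pad);
  const int WO = outSize(W, KW, stride, pad);
  const int L = HO * WO;
  arma::mat wm(w.begin(), Cout, K, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  if (KH == 1 && KW == 1 && stride == 1 && pad == 0) {
    arma::mat dWt(K, Cout, arma::fill::zeros);
    arma::vec dB(Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      arma::mat xn(const_cast<double*>(x.begin()) + (size_t)n * L * C,
                   L, C, false, true);
      arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * L * Cout,
                    L, Cout, false, true);
      arma::mat dxn(dx.begin() + (size_t)n * L * C, L, C, false, true);
      dxn = dyn * wm;
      dWt += xn.t() * dyn;
      dB += arma::sum(dyn, 0).t();
    }
    return List::create(_["dx"] = dx,
                        _["dW"] = wrap(arma::mat(dWt.t())),
                        _["db"] = wrap(dB));
  }
  const size_t ldRow = (size_t)L * N;
  arma::mat colT(ldRow, K, arma::fill::none);
  arma::mat dyb(ldRow, Cout, arma::fill::none);
  for (int n = 0; n < N; ++n) {
    im2colT(x.begin() + (size_t)n * H * W * C, H, W, C, KH, KW, stride,
            pad, colT.memptr() + (size_t)n * L, ldRow);
    for (int co = 0; co < Cout; ++co) {
      const double* src = dy.begin() + ((size_t)n * Cout + co) * L;
      double* dst = dyb.colptr(co) + (size_t)n * L;
      for (int j = 0; j < L; ++j) dst[j] = src[j];
    }
  }
  arma::mat dWt = colT.t() * dyb;       // K x Cout
  arma::rowvec dB = arma::sum(dyb, 0);
  arma::mat dcolT = dyb * wm;           // (L*N) x K
  for (int n = 0; n < N; ++n)
    col2imT(dcolT.memptr() + (size_t)n * L, H, W, C, KH, KW, stride, pad,
            dx.begin() + (size_t)n * H * W * C, ldRow);
  return List::create(_["dx"] = dx,
                      _["dW"] = wrap(arma::mat(dWt.t())),
                      _["db"] = wrap(arma::vec(dB.t())));
}

// [[Rcpp::export(name = ".cpp_maxpool_forward")]]
List cppMaxpoolForward(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int HO = outSize(H, k, stride, pad);
  const int WO = outSize(W, k, stride, pad);
  NumericVector y((R_xlen_t)HO * WO * C * N);
  y.attr("dim") = IntegerVector::create(HO, WO, C, N);
  IntegerVector arg(y.size());
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * H * W;
      double* yc = y.begin() + ((size_t)n * C + c) * HO * WO;
      int* ac = arg.begin() + ((size_t)n * C + c) * HO * WO;
      for (int wo = 0; wo < WO; ++wo) {
        for (int ho = 0; ho < HO; ++ho) {
          double best = -1e300; int bestIdx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int wi = wo * stride + kw - pad;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int hi = ho * stride + kh - pad;
              if (hi < 0 || hi >= H) continue;
              const double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bestIdx = hi + H * wi; }
            }
          }
          yc[ho + (size_t)HO * wo] = (bestIdx < 0) ? 0.0 : best;
          ac[ho + (size_t)HO * wo] = bestIdx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cppMaxpoolBackward(NumericVector dy, IntegerVector arg,
                                 IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector d = dy.attr("dim");
  const int HO = d[0], WO = d[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* dyc = dy.begin() + ((size_t)n * C + c) * HO * WO;
      const int* ac = arg.begin() + ((size_t)n * C + c) * HO * WO;
      for (int j = 0; j < HO * WO; ++j)
        if (ac[j] >= 0) dxc[ac[j]] += dyc[j];
    }
  }
  return dx;
}

// [[Rcpp::export(name = ".cpp_bn_forward")]]
List cppBnForward(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps, bool training,
                  NumericVector rmean, NumericVector rvar) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double m, v;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * plane;
        for (size_t j = 0; j < plane; ++j) { s += xc[j]; s2 += xc[j] * xc[j]; }
      }
      const double M = (double)N * plane;
      m = s / M;
      v = s2 / M - m * m;
      if (v < 0) v = 0;
    } else {
      m = rmean[c];
      v = rvar[c];
    }
    mean[c] = m; var[c] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      double* yc = y.begin() + ((size_t)n * C + c) * plane;
      for (size_t j = 0; j < plane; ++j)
        yc[j] = g * (xc[j] - m) * inv + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".cpp_bn_backward")]]
List cppBnBackward(NumericVector x, NumericVector dy, NumericVector gamma,
                   NumericVector mean, NumericVector var, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double M = (double)N * plane;
  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double m = mean[c], inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      const double* dyc = dy.begin() + ((size_t)n * C + c) * plane;
      for (size_t j = 0; j < plane; ++j) {
        sdy += dyc[j];
        sdyx += dyc[j] * (xc[j] - m) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * plane;
      const double* dyc = dy.begin() + ((size_t)n * C + c) * plane;
      double* dxc = dx.begin() + ((size_t)n * C + c) * plane;
      for (size_t j = 0; j < plane; ++j) {
        const double xhat = (xc[j] - m) * inv;
        dxc[j] = g * inv * (dyc[j] - sdy / M - xhat * sdyx / M);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Bilinear resampling of the parameter-map triplet at source coordinates
// (xs, ys) (1-based, zero padding outside). Transmittance is averaged
// directly; retardation/direction through the transmittance-weighted
// complex field r * IT * exp(2i phi).
// [[Rcpp::export(name = ".cpp_affine_resample")]]
List cppAffineResample(NumericMatrix IT, NumericMatrix r, NumericMatrix phi,
                       NumericVector xs, NumericVector ys,
                       NumericMatrix A) {
  const int H = IT.nrow(), W = IT.ncol();
  const R_xlen_t n = xs.size();
  NumericVector oIT(n), oR(n), oPhi(n);
  const double* pIT = IT.begin();
  const double* pR = r.begin();
  const double* pPhiRaw = phi.begin();
  // direction correction (constant Jacobian A) fused into the gather:
  // precompute the doubled-angle complex rotation per source pixel
  const double a11 = A(0, 0), a12 = A(0, 1), a21 = A(1, 0), a22 = A(1, 1);
  const bool ident = (a11 == 1.0 && a12 == 0.0 && a21 == 0.0 && a22 == 1.0);
  std::vector<double> c2(H * (size_t)W), s2(H * (size_t)W);
  for (size_t i = 0; i < (size_t)H * W; ++i) {
    double ph = pPhiRaw[i];
    if (!ident) {
      const double d1 = std::cos(ph), d2 = std::sin(ph);
      ph = std::atan2(a21 * d1 + a22 * d2, a11 * d1 + a12 * d2);
    }
    c2[i] = std::cos(2.0 * ph);
    s2[i] = std::sin(2.0 * ph);
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = xs[i], y = ys[i];
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    const double fx = x - x0, fy = y - y0;
    double aIT = 0.0, aRe = 0.0, aIm = 0.0;
    const double w[4] = {(1 - fx) * (1 - fy), fx * (1 - fy),
                         (1 - fx) * fy, fx * fy};
    const int xi[4] = {x0, x0 + 1, x0, x0 + 1};
    const int yi[4] = {y0, y0, y0 + 1, y0 + 1};
    for (int k = 0; k < 4; ++k) {
      if (w[k] <= 0.0 || xi[k] < 1 || xi[k] > W || yi[k] < 1 || yi[k] > H)
        continue;
      const size_t idx = (size_t)(yi[k] - 1) + (size_t)H * (xi[k] - 1);
      const double it = pIT[idx];
      aIT += w[k] * it;
      const double mag = pR[idx] * it;
      aRe += w[k] * mag * c2[idx];
      aIm += w[k] * mag * s2[idx];
    }
    oIT[i] = aIT;
    if (aIT > 0.0) {
      double rr = std::sqrt(aRe * aRe + aIm * aIm) / aIT;
      if (rr > 1.0) rr = 1.0;
      if (rr > 0.0) {
        // atan2/2 lies in (-pi/2, pi/2]; shift into the canonical [0, pi)
        double ph = 0.5 * std::atan2(aIm, aRe);
        if (ph < 0) ph += M_PI;
        if (ph >= M_PI) ph = 0;
        oPhi[i] = ph;
        oR[i] = rr;
      }
    }
  }
  return List::create(_["IT"] = oIT, _["r"] = oR, _["phi"] = oPhi);
}


// [[Rcpp::export(name = ".cpp_relu_forward")]]
NumericVector cppReluForward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  double* py = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  return y;
}

// [[Rcpp::export(name = ".cpp_relu_backward")]]
NumericVector cppReluBackward(NumericVector y, NumericVector dy) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* py = y.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) pdx[i] = py[i] > 0 ? pdy[i] : 0.0;
  return dx;
}
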