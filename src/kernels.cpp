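// Numeric kernels for the attention convolution network.
// All activation tensors are R arrays with dims (H, W, C, B), column-major.
// Convolutions are cross-correlations (deep-learning convention), stride 1.

#include <RcppArmadillo.h>
#include <cstring>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int b, int H, int W, int C) {
  return h + H * (w + W * (c + C * b));
}

// im2col for one sample: out (Ho*Wo, K*K*Cin); column q = ki + K*kj + K*K*ci
static void im2col(const double* X, int H, int W, int Cin, int b,
                   int K, int pad, int Ho, int Wo, arma::mat& Cm) {
  for (int ci = 0; ci < Cin; ++ci) {
    const double* Xc = X + (size_t)H * W * (ci + (size_t)Cin * b);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int q = ki + K * kj + K * K * ci;
        double* col = Cm.colptr(q);
        // valid output rows: hs = ho + ki - pad in [0, H)
        int ho_lo = std::max(0, pad - ki), ho_hi = std::min(Ho, H + pad - ki);
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo + kj - pad;
          double* dst = col + (size_t)Ho * wo;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + Ho, 0.0);
            continue;
          }
          const double* src = Xc + (size_t)H * ws + (ki - pad);
          for (int ho = 0; ho < ho_lo; ++ho) dst[ho] = 0.0;
          if (ho_hi > ho_lo)
            std::memcpy(dst + ho_lo, src + ho_lo, (ho_hi - ho_lo) * sizeof(double));
          for (int ho = ho_hi; ho < Ho; ++ho) dst[ho] = 0.0;
        }
      }
    }
  }
}

// col2im accumulation: scatter dXcol (Ho*Wo, K*K*Cin) back into dX sample b
static void col2im(const arma::mat& dXcol, double* dX, int H, int W, int Cin,
                   int b, int K, int pad, int Ho, int Wo) {
  for (int ci = 0; ci < Cin; ++ci) {
    double* dXc = dX + (size_t)H * W * (ci + (size_t)Cin * b);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int q = ki + K * kj + K * K * ci;
        const double* col = dXcol.colptr(q);
        int ho_lo = std::max(0, pad - ki), ho_hi = std::min(Ho, H + pad - ki);
        for (int wo = 0; wo < Wo; ++wo) {
          int ws = wo + kj - pad;
          if (ws < 0 || ws >= W) continue;
          double* dst = dXc + (size_t)H * ws + (ki - pad);
          const double* src = col + (size_t)Ho * wo;
          for (int ho = ho_lo; ho < ho_hi; ++ho) dst[ho] += src[ho];
        }
      }
    }
  }
}

// single-map K x K cross-correlation with zero padding, acc(h,w) += conv;
// used by spatial attention (forward) and its transpose/weight gradients
static void conv_single_fw(const double* Z, int H, int W, const double* Wk,
                           int K, int pad, double* out) {
  std::fill(out, out + (size_t)H * W, 0.0);
  for (int kj = 0; kj < K; ++kj) {
    for (int ki = 0; ki < K; ++ki) {
      double wv = Wk[ki + K * kj];
      if (wv == 0.0) continue;
      int h_lo = std::max(0, pad - ki), h_hi = std::min(H, H + pad - ki);
      for (int w = 0; w < W; ++w) {
        int ws = w + kj - pad;
        if (ws < 0 || ws >= W) continue;
        const double* src = Z + (size_t)H * ws + (ki - pad);
        double* dst = out + (size_t)H * w;
        for (int h = h_lo; h < h_hi; ++h) dst[h] += wv * src[h];
      }
    }
  }
}

static IntegerVector dims_of(const NumericVector& X) {
  return IntegerVector(X.attr("dim"));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector X, NumericVector Wt, NumericVector bias, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  int K = dw[0], Cout = dw[3];
  if (dw[2] != Cin) stop("conv2d: input channel mismatch");
  int Ho = H + 2 * pad - K + 1, Wo = W + 2 * pad - K + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: spatial dims too small for kernel");
  NumericVector Y(Ho * Wo * (size_t)Cout * B);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat Wmat(Wt.begin(), K * K * Cin, Cout, false, true);
  arma::rowvec bv(bias.begin(), Cout);
  arma::mat Cm(Ho * Wo, K * K * Cin);
  for (int b = 0; b < B; ++b) {
    im2col(X.begin(), H, W, Cin, b, K, pad, Ho, Wo, Cm);
    arma::mat Ymat(Y.begin() + (size_t)Ho * Wo * Cout * b, Ho * Wo, Cout, false, true);
    Ymat = Cm * Wmat;
    Ymat.each_row() += bv;
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector X, NumericVector Wt, NumericVector dY, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  int H = dx[0], W = dx[1], Cin = dx[2], B = dx[3];
  int K = dw[0], Cout = dw[3];
  int Ho = H + 2 * pad - K + 1, Wo = W + 2 * pad - K + 1;
  arma::mat Wmat(Wt.begin(), K * K * Cin, Cout, false, true);
  NumericVector dX(X.size());
  dX.attr("dim") = dx;
  NumericVector dWt(Wt.size());
  dWt.attr("dim") = dw;
  arma::mat dWmat(dWt.begin(), K * K * Cin, Cout, false, true);
  NumericVector db(Cout);
  arma::mat Cm(Ho * Wo, K * K * Cin);
  arma::rowvec dbv(Cout, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    arma::mat dYmat(dY.begin() + (size_t)Ho * Wo * Cout * b, Ho * Wo, Cout, false, true);
    im2col(X.begin(), H, W, Cin, b, K, pad, Ho, Wo, Cm);
    dWmat += Cm.t() * dYmat;
    dbv += arma::sum(dYmat, 0);
    arma::mat dXcol = dYmat * Wmat.t();
    col2im(dXcol, dX.begin(), H, W, Cin, b, K, pad, Ho, Wo);
  }
  for (int c = 0; c < Cout; ++c) db[c] = dbv[c];
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

// depthwise conv: one K x K filter per channel, Wt dims (K, K, C)
// [[Rcpp::export]]
NumericVector cpp_dwconv2d_fw(NumericVector X, NumericVector Wt, NumericVector bias, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int K = dw[0];
  if (dw[2] != C) stop("dwconv2d: channel mismatch");
  int Ho = H + 2 * pad - K + 1, Wo = W + 2 * pad - K + 1;
  NumericVector Y((size_t)Ho * Wo * C * B);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* Wc = Wt.begin() + (size_t)K * K * c;
      double* Yc = Y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double bc = bias[c];
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bc;
          for (int kj = 0; kj < K; ++kj) {
            int ws = wo + kj - pad;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              int hs = ho + ki - pad;
              if (hs >= 0 && hs < H) acc += Xc[hs + (size_t)H * ws] * Wc[ki + K * kj];
            }
          }
          Yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_dwconv2d_bw(NumericVector X, NumericVector Wt, NumericVector dY, int pad) {
  IntegerVector dx = dims_of(X), dw = dims_of(Wt);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int K = dw[0];
  int Ho = H + 2 * pad - K + 1, Wo = W + 2 * pad - K + 1;
  NumericVector dX(X.size());
  dX.attr("dim") = dx;
  NumericVector dWt(Wt.size());
  dWt.attr("dim") = dw;
  NumericVector db(C);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)H * W * (c + (size_t)C * b);
      const double* Wc = Wt.begin() + (size_t)K * K * c;
      const double* dYc = dY.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* dXc = dX.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* dWc = dWt.begin() + (size_t)K * K * c;
      double accb = 0.0;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dYc[ho + (size_t)Ho * wo];
          accb += g;
          if (g == 0.0) continue;
          for (int kj = 0; kj < K; ++kj) {
            int ws = wo + kj - pad;
            if (ws < 0 || ws >= W) continue;
            for (int ki = 0; ki < K; ++ki) {
              int hs = ho + ki - pad;
              if (hs >= 0 && hs < H) {
                dXc[hs + (size_t)H * ws] += g * Wc[ki + K * kj];
                dWc[ki + K * kj] += g * Xc[hs + (size_t)H * ws];
              }
            }
          }
        }
      }
      db[c] += accb;
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// channel attention: a = sigmoid(W2 relu(W1 (GAP + GMP))); Y = X * a[c]
// W1: (Cr x C), W2: (C x Cr)
// [[Rcpp::export]]
List cpp_cam_fw(NumericVector X, NumericMatrix W1, NumericMatrix W2) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W;
  arma::mat gap(C, B), gmp(C, B);
  IntegerMatrix amax(C, B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      double s = 0.0, m = Xc[0];
      int mi = 0;
      for (int i = 0; i < HW; ++i) {
        s += Xc[i];
        if (Xc[i] > m) { m = Xc[i]; mi = i; }
      }
      gap(c, b) = s / HW;
      gmp(c, b) = m;
      amax(c, b) = mi;
    }
  }
  arma::mat w1(W1.begin(), W1.nrow(), W1.ncol(), false, true);
  arma::mat w2(W2.begin(), W2.nrow(), W2.ncol(), false, true);
  arma::mat p = gap + gmp;
  arma::mat z1 = w1 * p;
  arma::mat hmat = arma::max(z1, arma::zeros<arma::mat>(arma::size(z1)));
  arma::mat z2 = w2 * hmat;
  arma::mat a = 1.0 / (1.0 + arma::exp(-z2));
  NumericVector Y(X.size());
  Y.attr("dim") = dx;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      double* Yc = Y.begin() + (size_t)HW * (c + (size_t)C * b);
      double ac = a(c, b);
      for (int i = 0; i < HW; ++i) Yc[i] = Xc[i] * ac;
    }
  }
  return List::create(_["Y"] = Y, _["p"] = wrap(p), _["h"] = wrap(hmat),
                      _["a"] = wrap(a), _["amax"] = amax);
}

// [[Rcpp::export]]
List cpp_cam_bw(NumericVector X, NumericMatrix W1, NumericMatrix W2,
                List cache, NumericVector dY) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W;
  arma::mat a = as<arma::mat>(cache["a"]);
  arma::mat hmat = as<arma::mat>(cache["h"]);
  arma::mat p = as<arma::mat>(cache["p"]);
  IntegerMatrix amax = cache["amax"];
  arma::mat w1(W1.begin(), W1.nrow(), W1.ncol(), false, true);
  arma::mat w2(W2.begin(), W2.nrow(), W2.ncol(), false, true);
  arma::mat da(C, B, arma::fill::zeros);
  NumericVector dX(X.size());
  dX.attr("dim") = dx;
  // da and the direct scaled path
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      const double* dYc = dY.begin() + (size_t)HW * (c + (size_t)C * b);
      double* dXc = dX.begin() + (size_t)HW * (c + (size_t)C * b);
      double s = 0.0, ac = a(c, b);
      for (int i = 0; i < HW; ++i) {
        s += Xc[i] * dYc[i];
        dXc[i] = ac * dYc[i];
      }
      da(c, b) = s;
    }
  }
  arma::mat dz2 = da % a % (1.0 - a);
  arma::mat dW2 = dz2 * hmat.t();
  arma::mat dh = w2.t() * dz2;
  arma::mat dz1 = dh % arma::conv_to<arma::mat>::from(hmat > 0);
  arma::mat dW1 = dz1 * p.t();
  arma::mat dp = w1.t() * dz1;
  // pooled-path gradients: GAP spreads uniformly, GMP routes to the argmax
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double* dXc = dX.begin() + (size_t)HW * (c + (size_t)C * b);
      double g = dp(c, b);
      double gavg = g / HW;
      for (int i = 0; i < HW; ++i) dXc[i] += gavg;
      dXc[amax(c, b)] += g;
    }
  }
  return List::create(_["dX"] = dX, _["dW1"] = wrap(dW1), _["dW2"] = wrap(dW2));
}

// spatial attention: A = sigmoid(conv_KxK(relu(w1*GAPc + w2*GMPc))); Y = X * A[h,w]
// GAPc/GMPc pool over channels; W3 is a single K x K map, pad = (K-1)/2
// [[Rcpp::export]]
List cpp_sam_fw(NumericVector X, double w1, double w2, NumericMatrix W3) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W, K = W3.nrow(), pad = (K - 1) / 2;
  NumericVector gap((size_t)HW * B), gmp((size_t)HW * B);
  IntegerVector cmax((size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    double* gp = gap.begin() + (size_t)HW * b;
    double* gm = gmp.begin() + (size_t)HW * b;
    int* cm = cmax.begin() + (size_t)HW * b;
    const double* Xb = X.begin() + (size_t)HW * C * b;
    for (int i = 0; i < HW; ++i) {
      double s = 0.0, m = Xb[i];
      int mc = 0;
      for (int c = 0; c < C; ++c) {
        double v = Xb[i + (size_t)HW * c];
        s += v;
        if (v > m) { m = v; mc = c; }
      }
      gp[i] = s / C;
      gm[i] = m;
      cm[i] = mc;
    }
  }
  NumericVector zr((size_t)HW * B), A((size_t)HW * B);
  for (R_xlen_t i = 0; i < zr.size(); ++i) {
    double z = w1 * gap[i] + w2 * gmp[i];
    zr[i] = z > 0 ? z : 0.0;
  }
  // single-channel conv over each (H, W) map
  std::vector<double> tmp((size_t)HW);
  for (int b = 0; b < B; ++b) {
    const double* Z = zr.begin() + (size_t)HW * b;
    double* Ab = A.begin() + (size_t)HW * b;
    conv_single_fw(Z, H, W, W3.begin(), K, pad, tmp.data());
    for (int i = 0; i < HW; ++i) Ab[i] = sigmoid(tmp[i]);
  }
  NumericVector Y(X.size());
  Y.attr("dim") = dx;
  for (int b = 0; b < B; ++b) {
    const double* Ab = A.begin() + (size_t)HW * b;
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      double* Yc = Y.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) Yc[i] = Xc[i] * Ab[i];
    }
  }
  return List::create(_["Y"] = Y, _["gap"] = gap, _["gmp"] = gmp,
                      _["cmax"] = cmax, _["zr"] = zr, _["A"] = A);
}

// [[Rcpp::export]]
List cpp_sam_bw(NumericVector X, double w1, double w2, NumericMatrix W3,
                List cache, NumericVector dY) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W, K = W3.nrow(), pad = (K - 1) / 2;
  NumericVector gap = cache["gap"], gmp = cache["gmp"], zr = cache["zr"], A = cache["A"];
  IntegerVector cmax = cache["cmax"];
  NumericVector dX(X.size());
  dX.attr("dim") = dx;
  NumericVector dA((size_t)HW * B);
  for (int b = 0; b < B; ++b) {
    const double* Ab = A.begin() + (size_t)HW * b;
    double* dAb = dA.begin() + (size_t)HW * b;
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      const double* dYc = dY.begin() + (size_t)HW * (c + (size_t)C * b);
      double* dXc = dX.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) {
        dAb[i] += Xc[i] * dYc[i];
        dXc[i] = Ab[i] * dYc[i];
      }
    }
  }
  // through sigmoid and the KxK map: input gradient is correlation with the
  // 180-degree rotated kernel; weight gradient is a shifted-region dot
  NumericVector dzr((size_t)HW * B);
  NumericMatrix dW3(K, K);
  std::vector<double> W3rot((size_t)K * K), gbuf((size_t)HW);
  for (int kj = 0; kj < K; ++kj)
    for (int ki = 0; ki < K; ++ki)
      W3rot[ki + K * kj] = W3(K - 1 - ki, K - 1 - kj);
  for (int b = 0; b < B; ++b) {
    const double* Ab = A.begin() + (size_t)HW * b;
    const double* dAb = dA.begin() + (size_t)HW * b;
    const double* Z = zr.begin() + (size_t)HW * b;
    double* dZ = dzr.begin() + (size_t)HW * b;
    for (int i = 0; i < HW; ++i) gbuf[i] = dAb[i] * Ab[i] * (1.0 - Ab[i]);
    conv_single_fw(gbuf.data(), H, W, W3rot.data(), K, pad, dZ);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int h_lo = std::max(0, pad - ki), h_hi = std::min(H, H + pad - ki);
        double acc = 0.0;
        for (int w = 0; w < W; ++w) {
          int ws = w + kj - pad;
          if (ws < 0 || ws >= W) continue;
          const double* src = Z + (size_t)H * ws + (ki - pad);
          const double* gcol = gbuf.data() + (size_t)H * w;
          for (int h = h_lo; h < h_hi; ++h) acc += gcol[h] * src[h];
        }
        dW3(ki, kj) += acc;
      }
    }
  }
  double dw1 = 0.0, dw2 = 0.0;
  NumericVector dpool((size_t)HW * B);
  for (R_xlen_t i = 0; i < dzr.size(); ++i) {
    double g = (zr[i] > 0) ? dzr[i] : 0.0;
    dw1 += g * gap[i];
    dw2 += g * gmp[i];
    dpool[i] = g;
  }
  for (int b = 0; b < B; ++b) {
    const double* dp = dpool.begin() + (size_t)HW * b;
    const int* cm = cmax.begin() + (size_t)HW * b;
    double* dXb = dX.begin() + (size_t)HW * C * b;
    for (int i = 0; i < HW; ++i) {
      double gavg = w1 * dp[i] / C;
      double gmax = w2 * dp[i];
      for (int c = 0; c < C; ++c) dXb[i + (size_t)HW * c] += gavg;
      dXb[i + (size_t)HW * cm[i]] += gmax;
    }
  }
  return List::create(_["dX"] = dX, _["dw1"] = dw1, _["dw2"] = dw2, _["dW3"] = dW3);
}

// batch normalization over (H, W, B) per channel, batch statistics
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector X, NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W;
  double M = (double)HW * B;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) s += Xc[i];
    }
    mu[c] = s / M;
    double v = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) { double d = Xc[i] - mu[c]; v += d * d; }
    }
    var[c] = v / M;
  }
  NumericVector Y(X.size());
  Y.attr("dim") = dx;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    for (int b = 0; b < B; ++b) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      double* Yc = Y.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) Yc[i] = gamma[c] * (Xc[i] - mu[c]) * inv + beta[c];
    }
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_bw(NumericVector X, NumericVector gamma, NumericVector mu,
               NumericVector var, double eps, NumericVector dY) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int HW = H * W;
  double M = (double)HW * B;
  NumericVector dX(X.size());
  dX.attr("dim") = dx;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double sum_dy = 0.0, sum_dy_xhat = 0.0;
    for (int b = 0; b < B; ++b) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      const double* dYc = dY.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) {
        double xhat = (Xc[i] - mu[c]) * inv;
        sum_dy += dYc[i];
        sum_dy_xhat += dYc[i] * xhat;
      }
    }
    dbeta[c] = sum_dy;
    dgamma[c] = sum_dy_xhat;
    for (int b = 0; b < B; ++b) {
      const double* Xc = X.begin() + (size_t)HW * (c + (size_t)C * b);
      const double* dYc = dY.begin() + (size_t)HW * (c + (size_t)C * b);
      double* dXc = dX.begin() + (size_t)HW * (c + (size_t)C * b);
      for (int i = 0; i < HW; ++i) {
        double xhat = (Xc[i] - mu[c]) * inv;
        dXc[i] = gamma[c] * inv / M * (M * dYc[i] - sum_dy - xhat * sum_dy_xhat);
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// 2x2 max pooling, stride 2, floor semantics; argmax stored for backward
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector X) {
  IntegerVector dx = dims_of(X);
  int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  int Ho = H / 2, Wo = W / 2;
  if (Ho < 1 || Wo < 1) stop("maxpool: spatial dims smaller than kernel");
  NumericVector Y((size_t)Ho * Wo * C * B);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  IntegerVector amax(Y.size());
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* Xc = X.begin() + (size_t)H * W * (c + (size_t)C * b);
      double* Yc = Y.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      int* Ac = amax.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = 2 * ho, w0 = 2 * wo;
          int best = h0 + H * w0;
          double m = Xc[best];
          int cand[3] = { h0 + 1 + H * w0, h0 + H * (w0 + 1), h0 + 1 + H * (w0 + 1) };
          for (int k = 0; k < 3; ++k)
            if (Xc[cand[k]] > m) { m = Xc[cand[k]]; best = cand[k]; }
          Yc[ho + Ho * wo] = m;
          Ac[ho + Ho * wo] = best;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector xdim, IntegerVector amax, NumericVector dY) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector dX((size_t)H * W * C * B);
  dX.attr("dim") = xdim;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* dYc = dY.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      const int* Ac = amax.begin() + (size_t)Ho * Wo * (c + (size_t)C * b);
      double* dXc = dX.begin() + (size_t)H * W * (c + (size_t)C * b);
      for (int i = 0; i < Ho * Wo; ++i) dXc[Ac[i]] += dYc[i];
    }
  }
  return dX;
}
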