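// Convolution / pooling kernels for the CNN engine.
// Feature maps are R arrays [H, W, C, N] (column-major, H fastest);
// conv weights are [kh, kw, Cin, Cout]; transposed-conv weights [2, 2, Cin, Cout].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cols: (Ho*Wo) x (kh*kw*C); column k = i + kh*(j + kw*c)
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pt, int pl,
                   int Ho, int Wo, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        double* col = cols.colptr((size_t)i + kh * (j + (size_t)kw * c));
        for (int ow = 0; ow < Wo; ++ow) {
          int wi = ow * stride + j - pl;
          double* colw = col + (size_t)Ho * ow;
          if (wi < 0 || wi >= W) {
            std::fill(colw, colw + Ho, 0.0);
          } else {
            const double* xw = xc + (size_t)H * wi;
            for (int oh = 0; oh < Ho; ++oh) {
              int hi = oh * stride + i - pt;
              colw[oh] = (hi < 0 || hi >= H) ? 0.0 : xw[hi];
            }
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int kh, int kw, int stride, int pt, int pl,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const double* col = cols.colptr((size_t)i + kh * (j + (size_t)kw * c));
        for (int ow = 0; ow < Wo; ++ow) {
          int wi = ow * stride + j - pl;
          if (wi < 0 || wi >= W) continue;
          const double* colw = col + (size_t)Ho * ow;
          double* xw = xc + (size_t)H * wi;
          for (int oh = 0; oh < Ho; ++oh) {
            int hi = oh * stride + i - pt;
            if (hi >= 0 && hi < H) xw[hi] += colw[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fw_cpp(NumericVector x, NumericVector Wt, NumericVector b,
                            int stride, int pt, int pb, int pl, int pr) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int Ho = (H + pt + pb - kh) / stride + 1;
  int Wo = (W + pl + pr - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size < 1");
  size_t M = (size_t)Ho * Wo, K = (size_t)kh * kw * C;
  arma::mat Wm(Wt.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  NumericVector y(M * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(M, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pt, pl,
           Ho, Wo, cols);
    arma::mat ym(y.begin() + M * Cout * n, M, Cout, false, true);
    ym = cols * Wm;
    ym.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bw_cpp(NumericVector x, NumericVector Wt, NumericVector dy,
                   int stride, int pt, int pb, int pl, int pr) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  size_t M = (size_t)Ho * Wo, K = (size_t)kh * kw * C;
  arma::mat Wm(Wt.begin(), K, Cout, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dWm(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat cols(M, K), dcols(M, K);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    arma::mat dym(dy.begin() + M * Cout * n, M, Cout, false, true);
    im2col(xn, H, W, C, kh, kw, stride, pt, pl, Ho, Wo, cols);
    dWm += cols.t() * dym;
    db += arma::sum(dym, 0);
    dcols = dym * Wm.t();
    col2im(dcols, H, W, C, kh, kw, stride, pt, pl, Ho, Wo,
           dx.begin() + (size_t)H * W * C * n);
  }
  NumericVector dWout(Wt.size());
  dWout.attr("dim") = wd;
  std::copy(dWm.begin(), dWm.end(), dWout.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 transposed convolution, stride 2: y[2h+i, 2w+j, o] += x[h,w,c] W[i,j,c,o]
// [[Rcpp::export]]
NumericVector convt2x2_fw_cpp(NumericVector x, NumericVector Wt, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convt2x2: channel mismatch");
  int Ho = 2 * H, Wo = 2 * W;
  size_t M = (size_t)H * W;
  // P(c, q) with q = i + 2j + 4o
  arma::mat P(C, 4 * (size_t)Cout);
  const double* wp = Wt.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int q4 = 0; q4 < 4; ++q4)
        P(c, q4 + 4 * (size_t)o) = wp[q4 + 4 * ((size_t)c + (size_t)C * o)];
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Y2(M, 4 * (size_t)Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + M * C * n, M, C, false, true);
    Y2 = X * P;
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          const double* col = Y2.colptr(i + 2 * j + 4 * (size_t)o);
          double bo = b[o];
          for (int w2 = 0; w2 < W; ++w2) {
            double* yw = yn + (size_t)Ho * (2 * w2 + j) + (size_t)Ho * Wo * o;
            const double* cw = col + (size_t)H * w2;
            for (int h2 = 0; h2 < H; ++h2)
              yw[2 * h2 + i] = cw[h2] + bo;
          }
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2x2_bw_cpp(NumericVector x, NumericVector Wt, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  size_t M = (size_t)H * W;
  arma::mat P(C, 4 * (size_t)Cout);
  const double* wp = Wt.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int q4 = 0; q4 < 4; ++q4)
        P(c, q4 + 4 * (size_t)o) = wp[q4 + 4 * ((size_t)c + (size_t)C * o)];
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  arma::mat dP(C, 4 * (size_t)Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dY2(M, 4 * (size_t)Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i) {
          double* col = dY2.colptr(i + 2 * j + 4 * (size_t)o);
          for (int w2 = 0; w2 < W; ++w2) {
            const double* yw = dyn + (size_t)Ho * (2 * w2 + j) + (size_t)Ho * Wo * o;
            double* cw = col + (size_t)H * w2;
            for (int h2 = 0; h2 < H; ++h2)
              cw[h2] = yw[2 * h2 + i];
          }
        }
    }
    arma::mat X(const_cast<double*>(x.begin()) + M * C * n, M, C, false, true);
    dP += X.t() * dY2;
    arma::mat dX(dx.begin() + M * C * n, M, C, false, true);
    dX = dY2 * P.t();
  }
  // db: sum of dy over H,W,N per output channel
  for (int n = 0; n < N; ++n) {
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int o = 0; o < Cout; ++o) {
      const double* p0 = dyn + (size_t)Ho * Wo * o;
      double s = 0.0;
      for (size_t k = 0; k < (size_t)Ho * Wo; ++k) s += p0[k];
      db[o] += s;
    }
  }
  NumericVector dWout(Wt.size());
  dWout.attr("dim") = wd;
  double* dwp = dWout.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < C; ++c)
      for (int q4 = 0; q4 < 4; ++q4)
        dwp[q4 + 4 * ((size_t)c + (size_t)C * o)] = dP(c, q4 + 4 * (size_t)o);
  return List::create(_["dx"] = dx, _["dw"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 max pooling, stride 2; idx stores argmax in {0,1,2,3} = i + 2j
// [[Rcpp::export]]
List maxpool2_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: odd spatial size");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t sx = (size_t)H * W, sy = (size_t)Ho * Wo;
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* xc = xp + sx * cn;
    double* yc = yp + sy * cn;
    int* ic = ip + sy * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        int best = 0;
        double bv = xc[(2 * oh) + (size_t)H * (2 * ow)];
        for (int j = 0; j < 2; ++j)
          for (int i = 0; i < 2; ++i) {
            double v = xc[(2 * oh + i) + (size_t)H * (2 * ow + j)];
            if (v > bv) { bv = v; best = i + 2 * j; }
          }
        yc[oh + (size_t)Ho * ow] = bv;
        ic[oh + (size_t)Ho * ow] = best;
      }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t sx = (size_t)H * W, sy = (size_t)Ho * Wo;
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  for (size_t cn = 0; cn < (size_t)C * N; ++cn) {
    const double* yc = dyp + sy * cn;
    const int* ic = ip + sy * cn;
    double* xc = dxp + sx * cn;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        int a = ic[oh + (size_t)Ho * ow];
        xc[(2 * oh + a % 2) + (size_t)H * (2 * ow + a / 2)] +=
          yc[oh + (size_t)Ho * ow];
      }
  }
  return dx;
}
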