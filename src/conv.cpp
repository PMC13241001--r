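// Convolution kernels for the autodiff engine.
//
// Arrays follow R's column-major layout: an H x W x C feature map is
// indexed i + H*j + H*W*c (0-based), i.e. rows = y, cols = x. All
// convolutions are stride 1 with zero 'same' padding; padding is implicit
// via bounds checks, no padded copy is materialized.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col with column order: channel fastest, then kernel row (di), then
// kernel col (dj) -- matching matrix(aperm(w, c(3,1,2,4)), K*Cin, Cout).
static arma::mat im2col_cm(const double* x, int H, int W, int C,
                           int kh, int kw) {
  const int p = (kh - 1) / 2;
  const int HW = H * W;
  arma::mat out(HW, (std::size_t)kh * kw * C, arma::fill::zeros);
  int col = 0;
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      for (int c = 0; c < C; ++c, ++col) {
        double* o = out.colptr(col);
        const double* xc = x + (std::size_t)HW * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          const double* src = xc + (std::size_t)H * sj + (i0 + di - p);
          double* dst = o + (std::size_t)H * j + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return out;
}

// transpose of im2col: scatter-add columns back onto the image grid
static void col2im_cm(const arma::mat& g, double* gx, int H, int W, int C,
                      int kh, int kw) {
  const int p = (kh - 1) / 2;
  const int HW = H * W;
  int col = 0;
  for (int dj = 0; dj < kw; ++dj) {
    for (int di = 0; di < kh; ++di) {
      for (int c = 0; c < C; ++c, ++col) {
        const double* gcol = g.colptr(col);
        double* xc = gx + (std::size_t)HW * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          double* dst = xc + (std::size_t)H * sj + (i0 + di - p);
          const double* src = gcol + (std::size_t)H * j + i0;
          for (int t = 0; t < i1 - i0; ++t) dst[t] += src[t];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         int H, int W, int Cin, int kh, int kw, int Cout) {
  arma::mat Xc = im2col_cm(x.begin(), H, W, Cin, kh, kw);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)kh * kw * Cin,
               Cout, false, true);
  arma::mat Y = Xc * Wm;
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector g,
                    int H, int W, int Cin, int kh, int kw, int Cout,
                    bool need_gx, bool need_gw) {
  arma::mat Xc = im2col_cm(x.begin(), H, W, Cin, kh, kw);
  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)kh * kw * Cin,
               Cout, false, true);
  arma::mat G(const_cast<double*>(g.begin()), (std::size_t)H * W, Cout,
              false, true);
  List out;
  if (need_gw) {
    arma::mat gW = Xc.t() * G;
    NumericVector gw(gW.begin(), gW.end());
    gw.attr("dim") = IntegerVector::create(kh * kw * Cin, Cout);
    out["gw"] = gw;
  }
  if (need_gx) {
    arma::mat gXc = G * Wm.t();
    NumericVector gx((std::size_t)H * W * Cin);
    col2im_cm(gXc, gx.begin(), H, W, Cin, kh, kw);
    gx.attr("dim") = IntegerVector::create(H, W, Cin);
    out["gx"] = gx;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dwconv(NumericVector x, NumericVector w,
                         int H, int W, int C, int kh, int kw) {
  const int p = (kh - 1) / 2;
  const int HW = H * W;
  NumericVector out((std::size_t)HW * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (std::size_t)HW * c;
    double* oc = out.begin() + (std::size_t)HW * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double wv = w[di + kh * dj + kh * kw * c];
        if (wv == 0.0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, p - di);
          const int i1 = std::min(H, H + p - di);
          const double* src = xc + (std::size_t)H * sj + (i0 + di - p);
          double* dst = oc + (std::size_t)H * j + i0;
          for (int t = 0; t < i1 - i0; ++t) dst[t] += wv * src[t];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, C);
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector g,
                    int H, int W, int C, int kh, int kw,
                    bool need_gx, bool need_gw) {
  const int p = (kh - 1) / 2;
  const int HW = H * W;
  List out;
  if (need_gw) {
    NumericVector gw((std::size_t)kh * kw * C);
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (std::size_t)HW * c;
      const double* gc = g.begin() + (std::size_t)HW * c;
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          double acc = 0.0;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - p;
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, p - di);
            const int i1 = std::min(H, H + p - di);
            const double* src = xc + (std::size_t)H * sj + (i0 + di - p);
            const double* gg = gc + (std::size_t)H * j + i0;
            for (int t = 0; t < i1 - i0; ++t) acc += src[t] * gg[t];
          }
          gw[di + kh * dj + kh * kw * c] = acc;
        }
      }
    }
    gw.attr("dim") = IntegerVector::create(kh, kw, C);
    out["gw"] = gw;
  }
  if (need_gx) {
    NumericVector gx((std::size_t)HW * C);
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (std::size_t)HW * c;
      const double* gc = g.begin() + (std::size_t)HW * c;
      // correlation with the flipped kernel
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const double wv = w[di + kh * dj + kh * kw * c];
          if (wv == 0.0) continue;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - p;   // output col that read input col sj
            if (sj < 0 || sj >= W) continue;
            const int i0 = std::max(0, p - di);
            const int i1 = std::min(H, H + p - di);
            double* dst = xc + (std::size_t)H * sj + (i0 + di - p);
            const double* gg = gc + (std::size_t)H * j + i0;
            for (int t = 0; t < i1 - i0; ++t) dst[t] += wv * gg[t];
          }
        }
      }
    }
    gx.attr("dim") = IntegerVector::create(H, W, C);
    out["gx"] = gx;
  }
  return out;
}
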