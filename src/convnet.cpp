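// Minimal convolutional-network primitives: im2col convolution, max-pooling,
// and their gradients. Array layout follows R column-major conventions:
// images are (H, W, C, N), kernels are (k, k, inC, outC), so an R-side
// `dim<-` reshape of the kernel array to (k*k*inC, outC) matches the row
// ordering of the im2col patch matrix built here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill `cols` (k*k*C x oh*ow) with patches of one image x (H x W x C).
// Out-of-canvas (padded) positions contribute zeros.
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, arma::mat& cols) {
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  cols.zeros();
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const int col = oi + oj * oh;
      double* dst = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        const double* plane = x + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = oj * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int wi = oi * stride - pad + ki;
            const int row = ki + kj * k + c * k * k;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              dst[row] = plane[wi + (size_t)wj * H];
          }
        }
      }
    }
  }
}

// Scatter-add of a patch-gradient matrix back onto the image grid.
static void col2im(const arma::mat& cols, int H, int W, int C,
                   int k, int stride, int pad, double* dx) {
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  for (int oj = 0; oj < ow; ++oj) {
    for (int oi = 0; oi < oh; ++oi) {
      const int col = oi + oj * oh;
      const double* src = cols.colptr(col);
      for (int c = 0; c < C; ++c) {
        double* plane = dx + (size_t)c * H * W;
        for (int kj = 0; kj < k; ++kj) {
          const int wj = oj * stride - pad + kj;
          for (int ki = 0; ki < k; ++ki) {
            const int wi = oi * stride - pad + ki;
            const int row = ki + kj * k + c * k * k;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              plane[wi + (size_t)wj * H] += src[row];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, IntegerVector wdim,
                           NumericVector bias, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], F = wdim[3];
  if (wdim[2] != C) stop("kernel input channels (%d) != image channels (%d)", wdim[2], C);
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  NumericVector y(R_xlen_t(oh) * ow * F * N);
  y.attr("dim") = IntegerVector::create(oh, ow, F, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  arma::vec bv(const_cast<double*>(bias.begin()), F, false, true);
  arma::mat cols((size_t)k * k * C, (size_t)oh * ow);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    arma::mat out = Wm.t() * cols;           // F x (oh*ow)
    out.each_col() += bv;
    // transpose into (oh*ow) x F which matches (oh, ow, F) column-major
    arma::mat dst(y.begin() + (size_t)n * oh * ow * F, (size_t)oh * ow, F, false, true);
    dst = out.t();
  }
  return y;
}

// Returns list(dx, dw, db).
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, IntegerVector xdim,
                  NumericVector w, IntegerVector wdim,
                  NumericVector dy, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int k = wdim[0], F = wdim[3];
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(R_xlen_t(k) * k * C * F);
  dw.attr("dim") = wdim;
  NumericVector db(F);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)k * k * C, F, false, true);
  arma::mat dWm(dw.begin(), (size_t)k * k * C, F, false, true);
  arma::vec dbv(db.begin(), F, false, true);
  arma::mat cols((size_t)k * k * C, (size_t)oh * ow);
  for (int n = 0; n < N; ++n) {
    arma::mat dyn(const_cast<double*>(dy.begin()) + (size_t)n * oh * ow * F,
                  (size_t)oh * ow, F, false, true);
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad, cols);
    dWm += cols * dyn;                        // (kkC x P) * (P x F)
    dbv += arma::sum(dyn, 0).t();
    arma::mat dcols = Wm * dyn.t();           // (kkC x F) * (F x P)
    col2im(dcols, H, W, C, k, stride, pad, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Max pooling; padded cells never win (they are treated as absent, matching
// the usual -inf padding semantics). Returns list(y, argmax) where argmax
// holds 0-based linear indices into the (H, W) plane of the input.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim,
                     int k, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int oh = out_size(H, k, stride, pad);
  const int ow = out_size(W, k, stride, pad);
  NumericVector y(R_xlen_t(oh) * ow * C * N);
  IntegerVector am(R_xlen_t(oh) * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  am.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* plane = x.begin() + ((size_t)n * C + c) * H * W;
      double* yp = y.begin() + ((size_t)n * C + c) * oh * ow;
      int* ap = am.begin() + ((size_t)n * C + c) * oh * ow;
      for (int oj = 0; oj < ow; ++oj) {
        for (int oi = 0; oi < oh; ++oi) {
          double best = R_NegInf; int bidx = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int wj = oj * stride - pad + kj;
            if (wj < 0 || wj >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int wi = oi * stride - pad + ki;
              if (wi < 0 || wi >= H) continue;
              const double v = plane[wi + (size_t)wj * H];
              if (v > best) { best = v; bidx = wi + wj * H; }
            }
          }
          yp[oi + (size_t)oj * oh] = best;
          ap[oi + (size_t)oj * oh] = bidx;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector dy,
                              IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector ydim = argmax.attr("dim");
  const int oh = ydim[0], ow = ydim[1];
  NumericVector dx(R_xlen_t(H) * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* dplane = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* dyp = dy.begin() + ((size_t)n * C + c) * oh * ow;
      const int* ap = argmax.begin() + ((size_t)n * C + c) * oh * ow;
      for (R_xlen_t i = 0; i < (R_xlen_t)oh * ow; ++i)
        if (ap[i] >= 0) dplane[ap[i]] += dyp[i];
    }
  }
  return dx;
}
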