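// im2col convolution kernels for the small CNN. Arrays follow R's
// column-major layout: images are (H, W, C, B), kernels (k, k, C, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the im2col matrix: rows indexed by (ho, wo, b), columns by
// (kernel offset kk = dj*k + di, then channel c) to match the R-side
// weight flattening (c fastest within kk).
static arma::mat im2col(const double* x, int H, int W, int C, int B,
                        int k, int stride, int pad, int Ho, int Wo) {
  arma::mat xcol(static_cast<size_t>(Ho) * Wo * B, static_cast<size_t>(k) * k * C,
                 arma::fill::zeros);
  const long HW = static_cast<long>(H) * W;
  const long HWC = HW * C;
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      int kk = dj * k + di;
      for (int c = 0; c < C; ++c) {
        size_t col = static_cast<size_t>(kk) * C + c;
        for (int b = 0; b < B; ++b) {
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride + dj - pad;
            if (wi < 0 || wi >= W) continue;
            const double* src = x + b * HWC + c * HW + static_cast<long>(wi) * H;
            size_t row0 = static_cast<size_t>(b) * Ho * Wo +
                          static_cast<size_t>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + di - pad;
              if (hi < 0 || hi >= H) continue;
              xcol(row0 + ho, col) = src[hi];
            }
          }
        }
      }
    }
  }
  return xcol;
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector x, IntegerVector xdim,
                  NumericMatrix wmat, NumericVector bias,
                  int k, int stride, int pad) {
  int H = xdim[0], W = xdim[1], C = xdim[2], B = xdim[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int Co = wmat.ncol();
  arma::mat xcol = im2col(x.begin(), H, W, C, B, k, stride, pad, Ho, Wo);
  arma::mat wm(wmat.begin(), wmat.nrow(), Co, false);
  arma::mat y = xcol * wm;  // (Ho*Wo*B, Co)
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Co * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Co, B);
  double* o = out.begin();
  const long HoWo = static_cast<long>(Ho) * Wo;
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double bb = bias[co];
      double* dst = o + (static_cast<long>(b) * Co + co) * HoWo;
      const double* col = y.colptr(co) + static_cast<long>(b) * HoWo;
      for (long i = 0; i < HoWo; ++i) dst[i] = col[i] + bb;
    }
  return List::create(_["out"] = out, _["xcol"] = wrap(xcol));
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(NumericVector dy, IntegerVector ydim,
                  NumericMatrix xcol_in, NumericMatrix wmat,
                  IntegerVector xdim, int k, int stride, int pad) {
  int Ho = ydim[0], Wo = ydim[1], Co = ydim[2], B = ydim[3];
  int H = xdim[0], W = xdim[1], C = xdim[2];
  const long HoWo = static_cast<long>(Ho) * Wo;
  arma::mat dymat(static_cast<size_t>(HoWo) * B, Co);
  const double* d = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int co = 0; co < Co; ++co) {
      const double* src = d + (static_cast<long>(b) * Co + co) * HoWo;
      double* dst = dymat.colptr(co) + static_cast<long>(b) * HoWo;
      for (long i = 0; i < HoWo; ++i) dst[i] = src[i];
    }
  arma::mat xcol(xcol_in.begin(), xcol_in.nrow(), xcol_in.ncol(), false);
  arma::mat wm(wmat.begin(), wmat.nrow(), wmat.ncol(), false);
  arma::rowvec db = arma::sum(dymat, 0);
  arma::mat dwmat = xcol.t() * dymat;        // (k*k*C, Co)
  arma::mat dxcol = dymat * wm.t();          // (Ho*Wo*B, k*k*C)
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  double* dxp = dx.begin();
  const long HW = static_cast<long>(H) * W;
  const long HWC = HW * C;
  for (int dj = 0; dj < k; ++dj)
    for (int di = 0; di < k; ++di) {
      int kk = dj * k + di;
      for (int c = 0; c < C; ++c) {
        size_t col = static_cast<size_t>(kk) * C + c;
        const double* dc = dxcol.colptr(col);
        for (int b = 0; b < B; ++b)
          for (int wo = 0; wo < Wo; ++wo) {
            int wi = wo * stride + dj - pad;
            if (wi < 0 || wi >= W) continue;
            double* dst = dxp + b * HWC + c * HW + static_cast<long>(wi) * H;
            size_t row0 = static_cast<size_t>(b) * HoWo +
                          static_cast<size_t>(wo) * Ho;
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride + di - pad;
              if (hi < 0 || hi >= H) continue;
              dst[hi] += dc[row0 + ho];
            }
          }
      }
    }
  return List::create(_["db"] = wrap(db), _["dwmat"] = wrap(dwmat),
                      _["dx"] = dx);
}
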