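// Minimal 2-D convolution kernels for the patch autoencoders.
//
// Activations are stored channel-fastest, i.e. as R arrays with
// dim = c(channels, height, width, batch).  Convolution weights are a
// (Cin*k*k) x Cout matrix whose row index runs over (channel, dy, dx)
// with channel fastest, matching the im2col layout below.  Images are
// processed in chunks so each chunk needs one GEMM (BLAS-bound) while
// the im2col buffer stays small.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int CHUNK = 32;

static void im2col(const double* x, int Cin, int H, int W,
                   int k, int stride, int pad, int Ho, int Wo,
                   double* colbase) {
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      double* dst = colbase +
          (std::size_t)Cin * k * k * (oi + (std::size_t)Ho * oj);
      for (int dj = 0; dj < k; ++dj) {
        int wj = oj * stride - pad + dj;
        for (int di = 0; di < k; ++di) {
          int wi = oi * stride - pad + di;
          double* d = dst + (std::size_t)Cin * (di + k * dj);
          if (wj < 0 || wj >= W || wi < 0 || wi >= H) {
            std::fill(d, d + Cin, 0.0);
          } else {
            const double* src =
                x + (std::size_t)Cin * (wi + (std::size_t)H * wj);
            std::copy(src, src + Cin, d);
          }
        }
      }
    }
  }
}

static void col2im_add(const double* colbase, double* dx, int Cin, int H,
                       int W, int k, int stride, int pad, int Ho, int Wo) {
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const double* src = colbase +
          (std::size_t)Cin * k * k * (oi + (std::size_t)Ho * oj);
      for (int dj = 0; dj < k; ++dj) {
        int wj = oj * stride - pad + dj;
        if (wj < 0 || wj >= W) continue;
        for (int di = 0; di < k; ++di) {
          int wi = oi * stride - pad + di;
          if (wi < 0 || wi >= H) continue;
          double* dst = dx + (std::size_t)Cin * (wi + (std::size_t)H * wj);
          const double* s = src + (std::size_t)Cin * (di + k * dj);
          for (int c = 0; c < Cin; ++c) dst[c] += s[c];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, NumericMatrix w, NumericVector bias,
                       int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int Cin = d[0], H = d[1], W = d[2], B = d[3];
  const int Cout = w.ncol();
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / Cin));
  if (k * k * Cin != w.nrow())
    stop("weight rows inconsistent with input channels");
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const std::size_t npos = (std::size_t)Ho * Wo;

  arma::mat wmat(w.begin(), w.nrow(), Cout, false, true);
  arma::vec bv(bias.begin(), Cout, false, true);
  NumericVector out((std::size_t)Cout * npos * B);
  arma::mat cols((std::size_t)Cin * k * k, npos * CHUNK);
  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    int nb = std::min(CHUNK, B - b0);
    for (int b = 0; b < nb; ++b)
      im2col(x.begin() + (std::size_t)Cin * H * W * (b0 + b), Cin, H, W, k,
             stride, pad, Ho, Wo, cols.colptr(npos * b));
    arma::mat yview(out.begin() + (std::size_t)Cout * npos * b0, Cout,
                    npos * nb, false, true);
    yview = wmat.t() * cols.head_cols(npos * nb);
    yview.each_col() += bv;
  }
  out.attr("dim") = IntegerVector::create(Cout, Ho, Wo, B);
  return out;
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
              int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int Cin = d[0], H = d[1], W = d[2], B = d[3];
  IntegerVector dd = dy.attr("dim");
  const int Cout = dd[0], Ho = dd[1], Wo = dd[2];
  const int k = (int)std::lround(std::sqrt((double)w.nrow() / Cin));
  const std::size_t npos = (std::size_t)Ho * Wo;

  arma::mat wmat(w.begin(), w.nrow(), Cout, false, true);
  arma::mat dw(w.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  NumericVector dx((std::size_t)Cin * H * W * B);  // zero-initialised
  arma::mat cols((std::size_t)Cin * k * k, npos * CHUNK);

  for (int b0 = 0; b0 < B; b0 += CHUNK) {
    int nb = std::min(CHUNK, B - b0);
    for (int b = 0; b < nb; ++b)
      im2col(x.begin() + (std::size_t)Cin * H * W * (b0 + b), Cin, H, W, k,
             stride, pad, Ho, Wo, cols.colptr(npos * b));
    arma::mat dyb(const_cast<double*>(dy.begin()) +
                      (std::size_t)Cout * npos * b0,
                  Cout, npos * nb, false, true);
    dw += cols.head_cols(npos * nb) * dyb.t();
    db += arma::sum(dyb, 1);
    arma::mat dcols = wmat * dyb;
    for (int b = 0; b < nb; ++b)
      col2im_add(dcols.colptr(npos * b),
                 dx.begin() + (std::size_t)Cin * H * W * (b0 + b), Cin, H,
                 W, k, stride, pad, Ho, Wo);
  }
  dx.attr("dim") = IntegerVector::create(Cin, H, W, B);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dw), _["db"] = wrap(db));
}
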