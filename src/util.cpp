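// Small activation helpers on (C, H, W, B) arrays.  These are trivial
// elementwise/reshaping ops, but doing them in single C++ passes avoids
// the repeated logical-mask and index-vector allocations that dominate
// R-level implementations inside the training loop.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* in = x.begin();
  double* out = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = in[i] > 0 ? in[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// zero dy where ref <= 0 (gradient through a ReLU with pre-activation ref)
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector dy, NumericVector ref) {
  NumericVector out(dy.size());
  const double* d = dy.begin();
  const double* r = ref.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) o[i] = r[i] > 0 ? d[i] : 0;
  out.attr("dim") = dy.attr("dim");
  return out;
}

// concatenate wc (Cc x B) as spatially constant channels under x (C,H,W,B)
// [[Rcpp::export(name = ".ccat_cpp")]]
NumericVector ccat_cpp(NumericVector x, NumericMatrix wc) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], B = d[3];
  const int Cc = wc.nrow();
  NumericVector out((std::size_t)(C + Cc) * H * W * B);
  const double* in = x.begin();
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* wcb = &wc(0, b);
    for (int p = 0; p < H * W; ++p) {
      std::copy(in, in + C, o);
      in += C;
      o += C;
      std::copy(wcb, wcb + Cc, o);
      o += Cc;
    }
  }
  out.attr("dim") = IntegerVector::create(C + Cc, H, W, B);
  return out;
}

// split the gradient of a concatenated activation: dx (first n_main
// channels) and dwc (remaining channels summed over space)
// [[Rcpp::export(name = ".ccat_bwd_cpp")]]
List ccat_bwd_cpp(NumericVector dxc, int n_main) {
  IntegerVector d = dxc.attr("dim");
  const int C = d[0], H = d[1], W = d[2], B = d[3];
  const int Cc = C - n_main;
  NumericVector dx((std::size_t)n_main * H * W * B);
  NumericMatrix dwc(Cc, B);
  const double* in = dxc.begin();
  double* o = dx.begin();
  for (int b = 0; b < B; ++b) {
    double* acc = &dwc(0, b);
    for (int p = 0; p < H * W; ++p) {
      std::copy(in, in + n_main, o);
      o += n_main;
      in += n_main;
      for (int c = 0; c < Cc; ++c) acc[c] += in[c];
      in += Cc;
    }
  }
  dx.attr("dim") = IntegerVector::create(n_main, H, W, B);
  return List::create(_["dx"] = dx, _["dwc"] = dwc);
}

// nearest-neighbour 2x upsampling of (C,H,W,B)
// [[Rcpp::export(name = ".up2_cpp")]]
NumericVector up2_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], B = d[3];
  NumericVector out((std::size_t)C * 4 * H * W * B);
  double* o = out.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + (std::size_t)C * H * W * b;
    for (int j = 0; j < 2 * W; ++j) {
      const double* col = xb + (std::size_t)C * H * (j / 2);
      for (int i = 0; i < 2 * H; ++i) {
        const double* src = col + (std::size_t)C * (i / 2);
        std::copy(src, src + C, o);
        o += C;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, 2 * H, 2 * W, B);
  return out;
}

// adjoint of up2_cpp: sum each 2x2 block
// [[Rcpp::export(name = ".up2_bwd_cpp")]]
NumericVector up2_bwd_cpp(NumericVector dy) {
  IntegerVector d = dy.attr("dim");
  const int C = d[0], H2 = d[1], W2 = d[2], B = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((std::size_t)C * H * W * B);
  const double* in = dy.begin();
  for (int b = 0; b < B; ++b) {
    double* xb = dx.begin() + (std::size_t)C * H * W * b;
    for (int j = 0; j < W2; ++j) {
      double* col = xb + (std::size_t)C * H * (j / 2);
      for (int i = 0; i < H2; ++i) {
        double* dst = col + (std::size_t)C * (i / 2);
        for (int c = 0; c < C; ++c) dst[c] += in[c];
        in += C;
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(C, H, W, B);
  return dx;
}
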