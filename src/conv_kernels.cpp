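// Compiled kernels for the U-Net layers.
//
// 3x3 "same" convolutions are evaluated strip-by-strip: for a block of
// image columns the im2col patch matrix is built in a small buffer,
// multiplied through BLAS (via Armadillo), and written back, so the full
// (H*W) x (9*C) patch matrix is never materialized. The backward pass
// fuses the data-, weight- and bias-gradient computations over the same
// strips. Layout contract: a (H, W, C) column-major array maps to patch
// columns k = a + 3*b + 9*c holding channel c shifted by (a-1, b-1) with
// zero padding, matching the flattening of a (3, 3, Cin, Cout) weight
// array.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
using namespace Rcpp;

// Fill the strip patch matrix for output columns [w0, w1).
static void fill_cols(arma::mat& cols, const double* xp,
                      int H, int W, int C, int w0, int w1) {
  const size_t plane = (size_t)H * W;
  const int S = w1 - w0;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + plane * c;
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        const int dy = a - 1, dx = b - 1;
        double* col = cols.colptr(a + 3 * b + 9 * c);
        for (int w = 0; w < S; ++w) {
          double* dst = col + (size_t)w * H;
          const int sw = w0 + w + dx;
          if (sw < 0 || sw >= W) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sw * H;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          if (h0 > 0) std::fill(dst, dst + h0, 0.0);
          std::copy(src + h0 + dy, src + h1 + dy, dst + h0);
          if (h1 < H) std::fill(dst + h1, dst + H, 0.0);
        }
      }
    }
  }
}

static int strip_width(int H, int C, int W) {
  // keep the strip patch buffer around ~4 MB
  double s = 4.0 * 1024 * 1024 / (9.0 * C * H * 8.0);
  int S = (int)s;
  if (S < 4) S = 4;
  if (S > W) S = W;
  return S;
}

// [[Rcpp::export(name = ".conv3_fwd_cpp")]]
NumericVector conv3_fwd_cpp(NumericVector x, const arma::mat& W,
                            const arma::vec& b, int H, int Wd, int C) {
  const int F = W.n_cols;
  NumericVector out((size_t)H * Wd * F);
  const int S = strip_width(H, C, Wd);
  arma::mat cols(H * S, 9 * C);
  const size_t oplane = (size_t)H * Wd;
  for (int w0 = 0; w0 < Wd; w0 += S) {
    const int w1 = std::min(Wd, w0 + S);
    const int s = w1 - w0;
    arma::mat cview = (s == S) ? arma::mat() : arma::mat(H * s, 9 * C);
    arma::mat& cc = (s == S) ? cols : cview;
    fill_cols(cc, x.begin(), H, Wd, C, w0, w1);
    arma::mat y = cc * W;            // (H*s) x F
    y.each_row() += b.t();
    for (int f = 0; f < F; ++f) {
      const double* src = y.colptr(f);
      double* dst = out.begin() + oplane * f + (size_t)w0 * H;
      std::copy(src, src + (size_t)H * s, dst);
    }
  }
  out.attr("dim") = IntegerVector::create(H, Wd, F);
  return out;
}

// [[Rcpp::export(name = ".conv3_bwd_cpp")]]
List conv3_bwd_cpp(NumericVector x, NumericVector gy, const arma::mat& W,
                   int H, int Wd, int C) {
  const int F = W.n_cols;
  NumericVector gx((size_t)H * Wd * C);
  arma::mat gW(9 * C, F, arma::fill::zeros);
  arma::vec gb(F, arma::fill::zeros);
  const int S = strip_width(H, C, Wd);
  arma::mat cols(H * S, 9 * C);
  const size_t oplane = (size_t)H * Wd;
  const arma::mat Wt = W.t();
  for (int w0 = 0; w0 < Wd; w0 += S) {
    const int w1 = std::min(Wd, w0 + S);
    const int s = w1 - w0;
    arma::mat cview = (s == S) ? arma::mat() : arma::mat(H * s, 9 * C);
    arma::mat& cc = (s == S) ? cols : cview;
    fill_cols(cc, x.begin(), H, Wd, C, w0, w1);
    arma::mat gys(H * s, F);
    for (int f = 0; f < F; ++f) {
      const double* src = gy.begin() + oplane * f + (size_t)w0 * H;
      std::copy(src, src + (size_t)H * s, gys.colptr(f));
    }
    gW += cc.t() * gys;
    gb += arma::sum(gys, 0).t();
    arma::mat gcols = gys * Wt;      // (H*s) x 9C
    // scatter-add back onto gx (adjacent strips overlap via the halo)
    for (int c = 0; c < C; ++c) {
      double* gc = gx.begin() + (size_t)H * Wd * c;
      for (int b3 = 0; b3 < 3; ++b3) {
        for (int a = 0; a < 3; ++a) {
          const int dy = a - 1, dx = b3 - 1;
          const double* col = gcols.colptr(a + 3 * b3 + 9 * c);
          for (int w = 0; w < s; ++w) {
            const int sw = w0 + w + dx;
            if (sw < 0 || sw >= Wd) continue;
            const double* src = col + (size_t)w * H;
            double* dst = gc + (size_t)sw * H;
            const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
            for (int h = h0; h < h1; ++h) dst[h + dy] += src[h];
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, Wd, C);
  return List::create(_["gx"] = gx, _["gW"] = wrap(gW), _["gb"] = wrap(gb));
}

// ReLU backward: zero the gradient where the pre-activation was <= 0.
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector pre, NumericVector g) {
  NumericVector out(g.size());
  const double* pp = pre.begin();
  const double* gp = g.begin();
  double* op = out.begin();
  const R_xlen_t n = g.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = (pp[i] > 0) ? gp[i] : 0.0;
  out.attr("dim") = g.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".relu_cpp")]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = (xp[i] > 0) ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// 2x2 stride-2 max pooling with argmax indices (1..4 = top-left, bottom-
// left, top-right, bottom-right; ties take the first), plus its adjoint.
// [[Rcpp::export(name = ".maxpool2_cpp")]]
List maxpool2_cpp(NumericVector x, int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C);
  IntegerVector idx((size_t)Ho * Wo * C);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    double* oc = op + (size_t)Ho * Wo * c;
    int* ic = ip + (size_t)Ho * Wo * c;
    for (int w = 0; w < Wo; ++w) {
      const double* c0 = xc + (size_t)(2 * w) * H;
      const double* c1 = xc + (size_t)(2 * w + 1) * H;
      for (int h = 0; h < Ho; ++h) {
        const double v1 = c0[2 * h], v2 = c0[2 * h + 1];
        const double v3 = c1[2 * h], v4 = c1[2 * h + 1];
        double best = v1; int which = 1;
        if (v2 > best) { best = v2; which = 2; }
        if (v3 > best) { best = v3; which = 3; }
        if (v4 > best) { best = v4; which = 4; }
        oc[(size_t)w * Ho + h] = best;
        ic[(size_t)w * Ho + h] = which;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd_cpp")]]
NumericVector maxpool2_bwd_cpp(NumericVector g, IntegerVector idx,
                               int H, int W, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector gx((size_t)H * W * C);
  const double* gp = g.begin();
  const int* ip = idx.begin();
  double* xp = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double* gc = gp + (size_t)Ho * Wo * c;
    const int* ic = ip + (size_t)Ho * Wo * c;
    double* xc = xp + (size_t)H * W * c;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int which = ic[(size_t)w * Ho + h];
        const int hh = 2 * h + ((which == 2 || which == 4) ? 1 : 0);
        const int ww = 2 * w + (which >= 3 ? 1 : 0);
        xc[(size_t)ww * H + hh] = gc[(size_t)w * Ho + h];
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, C);
  return gx;
}
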