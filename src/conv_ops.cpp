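// im2col-based 2D convolution forward/backward used by the network engine.
// Feature maps are R arrays ordered (H, W, C); weights are (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(kh * kw * C, Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            M(ki + kh * (kj + kw * c), col) = x(hi, wi, c);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x_, NumericVector w_, NumericVector b_,
                         int stride, int pad) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat Wm(w_.begin(), kh * kw * Cin, Cout, false);
  arma::mat M = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat out = M.t() * Wm;  // (Ho*Wo) x Cout
  for (int c = 0; c < Cout; ++c) out.col(c) += b_[c];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x_, NumericVector w_, NumericVector gout_,
                    int stride, int pad) {
  IntegerVector xd = x_.attr("dim");
  IntegerVector wd = w_.attr("dim");
  IntegerVector gd = gout_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat Wm(w_.begin(), kh * kw * Cin, Cout, false);
  arma::mat G(gout_.begin(), Ho * Wo, Cout, false);

  arma::mat M = im2col(x, kh, kw, stride, pad, Ho, Wo);
  arma::mat dW = M * G;                       // (kh*kw*Cin) x Cout
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dM = Wm * G.t();                  // (kh*kw*Cin) x (Ho*Wo)

  arma::cube dx(H, W, C, arma::fill::zeros);  // col2im scatter-add
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = ho + Ho * wo;
      for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            dx(hi, wi, c) += dM(ki + kh * (kj + kw * c), col);
          }
        }
      }
    }
  }
  NumericVector dxr(dx.begin(), dx.end());
  dxr.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector dwr(dW.begin(), dW.end());
  dwr.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["dx"] = dxr, _["dw"] = dwr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
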