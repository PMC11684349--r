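// Hot-path kernels for the 1D-CNN: stride-1 "same" convolution (forward,
// weight gradient, data gradient) and stride-2 max pooling.
//
// Activations use the (B*L, C) column-major layout with row index
// b + B*(t-1), so the rows touched by kernel tap j form one contiguous block
// and every tap is a single BLAS product against the (C_in x C_out) weight
// slab W[j + k*(c-1), ]. Everything is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat borrow(NumericMatrix x) {
  return arma::mat(x.begin(), x.nrow(), x.ncol(), false, true);
}

// W rows j, j+k, ..., j+k*(C_in-1): the tap-j weight slab (C_in x C_out)
static arma::mat tap_slab(const arma::mat& W, int j, int k, int C_in) {
  arma::uvec rows(C_in);
  for (int c = 0; c < C_in; ++c) rows[c] = j + (arma::uword)k * c;
  return W.rows(rows);
}

// [[Rcpp::export(name = "cpp_conv_fw")]]
NumericMatrix cpp_conv_fw(NumericMatrix X, int B, int L, NumericMatrix Wm,
                          NumericVector bias, int pl, int pr, int k) {
  const int C_in = X.ncol();
  const int C_out = Wm.ncol();
  arma::mat Xm = borrow(X);
  arma::mat W = borrow(Wm);
  const int Lp = L + pl + pr;
  NumericMatrix xp_out(B * Lp, C_in);
  arma::mat Xp(xp_out.begin(), B * Lp, C_in, false, true);
  Xp.rows(B * pl, B * pl + B * L - 1) = Xm;

  NumericMatrix out(B * L, C_out);
  arma::mat Z(out.begin(), B * L, C_out, false, true);
  for (int o = 0; o < C_out; ++o) Z.col(o).fill(bias[o]);
  for (int j = 0; j < k; ++j) {
    Z += Xp.rows(B * j, B * j + B * L - 1) * tap_slab(W, j, k, C_in);
  }
  out.attr("Xp") = xp_out;
  return out;
}

// [[Rcpp::export(name = "cpp_conv_bw")]]
List cpp_conv_bw(NumericMatrix dZm, NumericMatrix Xpm, NumericMatrix Wm,
                 int B, int L, int pl, int pr, int k) {
  const int C_out = dZm.ncol();
  const int C_in = Xpm.ncol();
  arma::mat dZ = borrow(dZm);
  arma::mat Xp = borrow(Xpm);
  arma::mat W = borrow(Wm);

  arma::mat dW(k * C_in, C_out, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const arma::mat blk = Xp.rows(B * j, B * j + B * L - 1);
    arma::mat g = blk.t() * dZ;  // gemm with TransA, C_in x C_out
    for (int c = 0; c < C_in; ++c) dW.row(j + (arma::uword)k * c) = g.row(c);
  }
  arma::rowvec db = arma::sum(dZ, 0);

  // full convolution with the tap-reversed kernel; output padded pr|pl
  arma::mat Dp(B * (L + k - 1), C_out, arma::fill::zeros);
  Dp.rows(B * pr, B * pr + B * L - 1) = dZ;
  arma::mat dX(B * L, C_in, arma::fill::zeros);
  for (int jp = 0; jp < k; ++jp) {
    dX += Dp.rows(B * jp, B * jp + B * L - 1) * tap_slab(W, k - 1 - jp, k, C_in).t();
  }
  return List::create(_["dW"] = dW, _["db"] = NumericVector(db.begin(), db.end()),
                      _["dX"] = dX);
}

// [[Rcpp::export(name = "cpp_maxpool_fw")]]
List cpp_maxpool_fw(NumericMatrix X, int B, int L) {
  const int C = X.ncol();
  const int Lo = L / 2;
  NumericMatrix out(B * Lo, C);
  LogicalMatrix first(B * Lo, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &X(0, c);
    double* oc = &out(0, c);
    int* fc = &first(0, c);
    for (int t = 0; t < Lo; ++t) {
      for (int b = 0; b < B; ++b) {
        const double a = xc[b + (std::size_t)B * (2 * t)];
        const double v = xc[b + (std::size_t)B * (2 * t + 1)];
        const bool tf = a >= v;  // ties -> first element
        oc[b + (std::size_t)B * t] = tf ? a : v;
        fc[b + (std::size_t)B * t] = tf;
      }
    }
  }
  return List::create(_["out"] = out, _["take_first"] = first);
}

// [[Rcpp::export(name = "cpp_maxpool_bw")]]
NumericMatrix cpp_maxpool_bw(NumericMatrix dOut, LogicalMatrix first,
                             int B, int L_in) {
  const int C = dOut.ncol();
  const int Lo = dOut.nrow() / B;
  NumericMatrix dX(B * L_in, C);  // zero-initialised
  for (int c = 0; c < C; ++c) {
    const double* gc = &dOut(0, c);
    const int* fc = &first(0, c);
    double* dc = &dX(0, c);
    for (int t = 0; t < Lo; ++t) {
      for (int b = 0; b < B; ++b) {
        const std::size_t src = b + (std::size_t)B * t;
        const std::size_t dst = b + (std::size_t)B * (fc[src] ? 2 * t : 2 * t + 1);
        dc[dst] = gc[src];
      }
    }
  }
  return dX;
}
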