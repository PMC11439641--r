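// Inner loops of the shallow CNN layers: im2col gather, GEMM, ReLU and
// max-pool forward/backward. The R side precomputes (and memoises) the
// integer row selectors; these kernels only gather, multiply and scatter.
// Large matrices are wrapped in-place (no copies across the R boundary).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat wrap_view(const NumericMatrix& x) {
  return arma::mat(const_cast<double*>(x.begin()), x.nrow(), x.ncol(),
                   false, true);
}

// Forward one conv layer. X: (npos_in*B) x Cin in position-major layout;
// padrows scatters X into the zero-padded canvas of HpWpB rows; rowsel[k]
// gathers patch element k for every output position.
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(const NumericMatrix& X, const IntegerVector& padrows,
                  const List& rowsel, int HpWpB, const NumericMatrix& W,
                  const NumericVector& b) {
  const int Cin = X.ncol();
  const int nk = rowsel.size();
  const int nout = as<IntegerVector>(rowsel[0]).size();
  const int Cout = W.ncol();
  arma::mat Xv = wrap_view(X), Wv = wrap_view(W);
  arma::mat Xp(HpWpB, Cin, arma::fill::zeros);
  const int* pr = INTEGER(padrows);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = Xv.colptr(c);
    double* xpc = Xp.colptr(c);
    for (int i = 0; i < X.nrow(); ++i) xpc[pr[i] - 1] = xc[i];
  }
  NumericMatrix Mr(nout, nk * Cin);
  arma::mat M = wrap_view(Mr);
  for (int k = 0; k < nk; ++k) {
    const int* sel = INTEGER(rowsel[k]);
    for (int c = 0; c < Cin; ++c) {
      const double* xpc = Xp.colptr(c);
      double* mc = M.colptr((arma::uword)k * Cin + c);
      for (int i = 0; i < nout; ++i) mc[i] = xpc[sel[i] - 1];
    }
  }
  NumericMatrix Ar(nout, Cout);
  arma::mat A = wrap_view(Ar);
  A = M * Wv;
  for (int c = 0; c < Cout; ++c) {
    double* ac = A.colptr(c);
    const double bc = b[c];
    for (int i = 0; i < nout; ++i) {
      double v = ac[i] + bc;
      ac[i] = v > 0.0 ? v : 0.0;   // ReLU in place; A>0 marks active units
    }
  }
  return List::create(_["M"] = Mr, _["A"] = Ar);
}

// Backward one conv layer: dA -> (dW, db, dX).
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const NumericMatrix& dA, const NumericMatrix& A,
                  const NumericMatrix& M, const NumericMatrix& W,
                  const IntegerVector& padrows, const List& rowsel,
                  int HpWpB, bool want_dX) {
  const int nout = dA.nrow();
  const int Cout = dA.ncol();
  arma::mat dAv = wrap_view(dA), Av = wrap_view(A), Mv = wrap_view(M),
            Wv = wrap_view(W);
  arma::mat dZ(nout, Cout);
  for (int c = 0; c < Cout; ++c) {
    const double* da = dAv.colptr(c);
    const double* ac = Av.colptr(c);
    double* dz = dZ.colptr(c);
    for (int i = 0; i < nout; ++i) dz[i] = ac[i] > 0.0 ? da[i] : 0.0;
  }
  NumericMatrix dWr(W.nrow(), Cout);
  arma::mat dW = wrap_view(dWr);
  dW = Mv.t() * dZ;
  NumericVector dbr(Cout);
  for (int c = 0; c < Cout; ++c) dbr[c] = arma::accu(dZ.col(c));
  if (!want_dX) {
    return List::create(_["dW"] = dWr, _["db"] = dbr, _["dX"] = R_NilValue);
  }
  const int nk = rowsel.size();
  const int Cin = W.nrow() / nk;
  arma::mat dM = dZ * Wv.t();
  arma::mat dXp(HpWpB, Cin, arma::fill::zeros);
  for (int k = 0; k < nk; ++k) {
    const int* sel = INTEGER(rowsel[k]);
    for (int c = 0; c < Cin; ++c) {
      double* xpc = dXp.colptr(c);
      const double* mc = dM.colptr((arma::uword)k * Cin + c);
      for (int i = 0; i < nout; ++i) xpc[sel[i] - 1] += mc[i];
    }
  }
  const int* pr = INTEGER(padrows);
  NumericMatrix dXr(padrows.size(), Cin);
  arma::mat dX = wrap_view(dXr);
  for (int c = 0; c < Cin; ++c) {
    const double* xpc = dXp.colptr(c);
    double* xc = dX.colptr(c);
    for (int i = 0; i < padrows.size(); ++i) xc[i] = xpc[pr[i] - 1];
  }
  return List::create(_["dW"] = dWr, _["db"] = dbr, _["dX"] = dXr);
}

// Max pooling over the precomputed window selectors. Returns the pooled
// matrix and the winning window index per (position, channel) for
// backprop; ties go to the first window, matching a left-to-right scan.
// [[Rcpp::export(name = ".pool_fwd_cpp")]]
List pool_fwd_cpp(const NumericMatrix& X, const List& sels) {
  const int nk = sels.size();
  const int C = X.ncol();
  const int nout = as<IntegerVector>(sels[0]).size();
  arma::mat Xv = wrap_view(X);
  NumericMatrix Pr(nout, C);
  arma::mat P = wrap_view(Pr);
  IntegerMatrix argk(nout, C);
  for (int k = 0; k < nk; ++k) {
    const int* sel = INTEGER(sels[k]);
    for (int c = 0; c < C; ++c) {
      const double* xc = Xv.colptr(c);
      double* pc = P.colptr(c);
      int* ac = &argk(0, c);
      if (k == 0) {
        for (int i = 0; i < nout; ++i) { pc[i] = xc[sel[i] - 1]; ac[i] = 0; }
      } else {
        for (int i = 0; i < nout; ++i) {
          double v = xc[sel[i] - 1];
          if (v > pc[i]) { pc[i] = v; ac[i] = k; }
        }
      }
    }
  }
  return List::create(_["P"] = Pr, _["argk"] = argk);
}

// [[Rcpp::export(name = ".pool_bwd_cpp")]]
NumericMatrix pool_bwd_cpp(const NumericMatrix& dP,
                           const IntegerMatrix& argk, const List& sels,
                           int n_in_rows) {
  const int C = dP.ncol();
  const int nout = dP.nrow();
  arma::mat dPv = wrap_view(dP);
  NumericMatrix dXr(n_in_rows, C);
  arma::mat dX = wrap_view(dXr);
  for (int k = 0; k < sels.size(); ++k) {
    const int* sel = INTEGER(sels[k]);
    for (int c = 0; c < C; ++c) {
      const double* dpc = dPv.colptr(c);
      const int* ac = &argk(0, c);
      double* xc = dX.colptr(c);
      for (int i = 0; i < nout; ++i) {
        if (ac[i] == k) xc[sel[i] - 1] += dpc[i];
      }
    }
  }
  return dXr;
}
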