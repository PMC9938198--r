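// Small fused elementwise kernels. Each replaces a chain of R vector ops
// that would otherwise allocate one intermediate per step.

#include <Rcpp.h>
using namespace Rcpp;

// y[i, j] = x[i, j] + v[j]
// [[Rcpp::export]]
NumericMatrix addcol_cpp(const NumericMatrix& x, const NumericVector& v) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double vj = v[j];
    const double* xi = &x(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < nr; ++i) yi[i] = xi[i] + vj;
  }
  return y;
}

// y[i, j] = x[i, j] * v[j]
// [[Rcpp::export]]
NumericMatrix mulcol_cpp(const NumericMatrix& x, const NumericVector& v) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double vj = v[j];
    const double* xi = &x(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < nr; ++i) yi[i] = xi[i] * vj;
  }
  return y;
}

// Fused relu block tail: a = relu(z + b[col]) * rowmask (* dropmask),
// also returning the relu activity pattern for the backward pass.
// [[Rcpp::export]]
List relu_post_cpp(const NumericMatrix& z, const NumericVector& b,
                   const NumericVector& rowmask, SEXP dropmask) {
  int nr = z.nrow(), nc = z.ncol();
  NumericMatrix a(nr, nc);
  LogicalMatrix pos(nr, nc);
  bool has_dm = dropmask != R_NilValue;
  NumericMatrix dm;
  if (has_dm) dm = as<NumericMatrix>(dropmask);
  for (int j = 0; j < nc; ++j) {
    double bj = b[j];
    const double* zi = &z(0, j);
    double* ai = &a(0, j);
    int* pi = &pos(0, j);
    const double* di = has_dm ? &dm(0, j) : (const double*)0;
    for (int i = 0; i < nr; ++i) {
      double v = zi[i] + bj;
      bool p = v > 0;
      pi[i] = p;
      double out = p ? v * rowmask[i] : 0.0;
      ai[i] = has_dm ? out * di[i] : out;
    }
  }
  return List::create(_["a"] = a, _["pos"] = pos);
}

// Fused relu block backward: dz = dh (* dropmask) * rowmask * pos
// [[Rcpp::export]]
NumericMatrix relu_back_cpp(const NumericMatrix& dh, SEXP dropmask,
                            const NumericVector& rowmask,
                            const LogicalMatrix& pos) {
  int nr = dh.nrow(), nc = dh.ncol();
  NumericMatrix dz(nr, nc);
  bool has_dm = dropmask != R_NilValue;
  NumericMatrix dm;
  if (has_dm) dm = as<NumericMatrix>(dropmask);
  for (int j = 0; j < nc; ++j) {
    const double* di = &dh(0, j);
    const int* pi = &pos(0, j);
    const double* dmi = has_dm ? &dm(0, j) : (const double*)0;
    double* zi = &dz(0, j);
    for (int i = 0; i < nr; ++i) {
      double v = pi[i] ? di[i] * rowmask[i] : 0.0;
      zi[i] = has_dm ? v * dmi[i] : v;
    }
  }
  return dz;
}

// y = x * rowmask (rows scaled by a 0/1 mask vector)
// [[Rcpp::export]]
NumericMatrix rowmask_cpp(const NumericMatrix& x,
                          const NumericVector& rowmask) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix y(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const double* xi = &x(0, j);
    double* yi = &y(0, j);
    for (int i = 0; i < nr; ++i) yi[i] = xi[i] * rowmask[i];
  }
  return y;
}
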