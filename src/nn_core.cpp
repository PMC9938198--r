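// Convolution and batch-norm kernels for the labeler.
//
// Layout contract (shared with R/nn.R): activations are flat (B*L) x F
// matrices, position-major (row = b + l*B, 0-based), so a positional shift
// by s is a contiguous row-block offset of s*B and each kernel tap is one
// BLAS product on submatrix views — no im2col materialisation.

#include <RcppArmadillo.h>
#include "blas_shim.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward conv block: z = sum_t shift(x, t-P-1) * W_t, then fused
// bias + relu + row mask + (optional, training) inverted dropout drawn from
// R's RNG. Returns activations, relu pattern, and the dropout mask.
// [[Rcpp::export]]
List conv_fwd_cpp(const arma::mat& x, int B, int L, const arma::mat& Wmat,
                  const arma::vec& bias, const arma::vec& rowmask,
                  double drop_rate, bool training) {
  int Cin = x.n_cols;
  int Cout = Wmat.n_cols;
  int K = Wmat.n_rows / Cin;
  int P = (K - 1) / 2;
  int BL = B * L;
  arma::mat z(BL, Cout, arma::fill::zeros);
  for (int t = 0; t < K; ++t) {
    int s = t - P; // source position = target + s
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    int src0 = (t0 + s) * B;
    int nr = (t1 - t0 + 1) * B;
    blas_gemm('N', 'N', nr, Cout, Cin, 1.0,
              x.memptr() + src0, BL,
              Wmat.memptr() + t * Cin, K * Cin,
              1.0, z.memptr() + t0 * B, BL);
  }
  arma::mat a(BL, Cout);
  LogicalMatrix pos(BL, Cout);
  bool use_drop = training && drop_rate > 0;
  arma::mat dm;
  if (use_drop) dm.set_size(BL, Cout);
  double keep = 1.0 - drop_rate;
  for (int j = 0; j < Cout; ++j) {
    const double* zj = z.colptr(j);
    double* aj = a.colptr(j);
    int* pj = &pos(0, j);
    double* dj = use_drop ? dm.colptr(j) : (double*)0;
    double bj = bias[j];
    for (int i = 0; i < BL; ++i) {
      double v = zj[i] + bj;
      bool p = v > 0;
      pj[i] = p;
      double out = p ? v * rowmask[i] : 0.0;
      if (use_drop) {
        double d = (unif_rand() >= drop_rate) ? 1.0 / keep : 0.0;
        dj[i] = d;
        out *= d;
      }
      aj[i] = out;
    }
  }
  List ret = List::create(_["a"] = a, _["pos"] = pos);
  if (use_drop) ret["dm"] = dm; else ret["dm"] = R_NilValue;
  return ret;
}

// Backward conv block: dz = dh (*dm) * rowmask * pos, then dW, db and dx.
// [[Rcpp::export]]
List conv_bwd_cpp(const arma::mat& dh, SEXP dropmask,
                  const arma::vec& rowmask, const LogicalMatrix& pos,
                  const arma::mat& x, const arma::mat& Wmat, int B, int L) {
  int Cin = x.n_cols;
  int Cout = Wmat.n_cols;
  int K = Wmat.n_rows / Cin;
  int P = (K - 1) / 2;
  int BL = B * L;
  bool has_dm = dropmask != R_NilValue;
  arma::mat dmv;
  if (has_dm) dmv = as<arma::mat>(dropmask);
  arma::mat dz(BL, Cout);
  arma::rowvec db(Cout);
  for (int j = 0; j < Cout; ++j) {
    const double* dj = dh.colptr(j);
    const int* pj = &pos(0, j);
    const double* mm = has_dm ? dmv.colptr(j) : (double*)0;
    double* zj = dz.colptr(j);
    double acc = 0;
    for (int i = 0; i < BL; ++i) {
      double v = pj[i] ? dj[i] * rowmask[i] : 0.0;
      if (has_dm) v *= mm[i];
      zj[i] = v;
      acc += v;
    }
    db[j] = acc;
  }
  arma::mat dW(K * Cin, Cout, arma::fill::zeros);
  arma::mat dx(BL, Cin, arma::fill::zeros);
  for (int t = 0; t < K; ++t) {
    int s = t - P;
    int t0 = std::max(0, -s), t1 = std::min(L - 1, L - 1 - s);
    if (t0 > t1) continue;
    int src0 = (t0 + s) * B;
    int nr = (t1 - t0 + 1) * B;
    blas_gemm('T', 'N', Cin, Cout, nr, 1.0,
              x.memptr() + src0, BL,
              dz.memptr() + t0 * B, BL,
              0.0, dW.memptr() + t * Cin, K * Cin);
    blas_gemm('N', 'T', nr, Cin, Cout, 1.0,
              dz.memptr() + t0 * B, BL,
              Wmat.memptr() + t * Cin, K * Cin,
              1.0, dx.memptr() + src0, BL);
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// Batch norm forward over masked rows. Returns y, xhat, inv and updated
// running stats (training mode) in one pass.
// [[Rcpp::export]]
List bn_fwd_cpp(const arma::mat& xf, const arma::vec& rowmask,
                const arma::vec& gamma, const arma::vec& beta,
                const arma::vec& rmean, const arma::vec& rvar,
                bool training, double eps, double momentum) {
  int nr = xf.n_rows, nc = xf.n_cols;
  arma::vec mu(nc), va(nc);
  double nm = arma::accu(rowmask);
  if (training) {
    for (int j = 0; j < nc; ++j) {
      const double* xj = xf.colptr(j);
      double s = 0;
      for (int i = 0; i < nr; ++i) s += xj[i] * rowmask[i];
      double m = s / nm;
      double v = 0;
      for (int i = 0; i < nr; ++i) {
        double d = xj[i] - m;
        v += d * d * rowmask[i];
      }
      mu[j] = m;
      va[j] = v / nm;
    }
  } else {
    mu = rmean;
    va = rvar;
  }
  arma::mat y(nr, nc), xhat(nr, nc);
  arma::vec inv(nc);
  for (int j = 0; j < nc; ++j) {
    double iv = 1.0 / std::sqrt(va[j] + eps);
    inv[j] = iv;
    double g = gamma[j], b = beta[j], m = mu[j];
    const double* xj = xf.colptr(j);
    double* hj = xhat.colptr(j);
    double* yj = y.colptr(j);
    for (int i = 0; i < nr; ++i) {
      double h = (xj[i] - m) * iv;
      hj[i] = h;
      yj[i] = g * h + b;
    }
  }
  arma::vec new_rmean = rmean, new_rvar = rvar;
  if (training) {
    new_rmean = momentum * rmean + (1 - momentum) * mu;
    new_rvar = momentum * rvar + (1 - momentum) * va;
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// Batch norm backward (training mode stats) over masked rows.
// [[Rcpp::export]]
List bn_bwd_cpp(const arma::mat& dy, const arma::mat& xhat,
                const arma::vec& inv, const arma::vec& gamma,
                const arma::vec& rowmask, bool training) {
  int nr = dy.n_rows, nc = dy.n_cols;
  arma::mat dx(nr, nc);
  arma::vec dgamma(nc), dbeta(nc);
  double nm = arma::accu(rowmask);
  for (int j = 0; j < nc; ++j) {
    const double* dj = dy.colptr(j);
    const double* hj = xhat.colptr(j);
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (int i = 0; i < nr; ++i) {
      double d = dj[i] * rowmask[i];
      sg += d * hj[i];
      sb += d;
      s1 += d;
      s2 += d * hj[i];
    }
    dgamma[j] = sg;
    dbeta[j] = sb;
    double g = gamma[j], iv = inv[j];
    double* xj = dx.colptr(j);
    if (training) {
      double a1 = g * s1 / nm, a2 = g * s2 / nm;
      for (int i = 0; i < nr; ++i) {
        double d = dj[i] * rowmask[i];
        xj[i] = (g * d - a1 - hj[i] * a2) * iv * rowmask[i];
      }
    } else {
      for (int i = 0; i < nr; ++i) {
        xj[i] = dj[i] * rowmask[i] * g * iv;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Inverted dropout mask drawn from R's RNG.
// [[Rcpp::export]]
NumericMatrix dropout_mask_cpp(int rows, int cols, double rate) {
  NumericMatrix dm(rows, cols);
  double keep = 1.0 - rate;
  int n = rows * cols;
  double* d = REAL(dm);
  for (int i = 0; i < n; ++i) {
    d[i] = (unif_rand() >= rate) ? 1.0 / keep : 0.0;
  }
  return dm;
}
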