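// Bi-LSTM recurrence for the exterior-loop labeler.
//
// Activations are flat (B*L) x F matrices in position-major blocks (row =
// b + l*B, 0-based), so timestep l occupies the contiguous row range
// [l*B, (l+1)*B). The input projection x * W_x is done for all timesteps in
// one BLAS call; the recurrence itself only multiplies the (small) hidden
// state by W_h per step. The gate transforms use raw pointers to avoid
// per-step temporaries. W stacks [W_x; W_h] with C + U rows.

#include <RcppArmadillo.h>
#include "blas_shim.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// tanh via one exp (measurably faster than std::tanh with this libm),
// guarded against exp overflow
static inline double tanh_e(double x) {
  if (x > 19.0) return 1.0;
  if (x < -19.0) return -1.0;
  double e = std::exp(2.0 * x);
  return (e - 1.0) / (e + 1.0);
}

// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat& x, int B, int L, const arma::mat& W,
                      const arma::vec& b, bool reverse) {
  int C = x.n_cols;
  int U = W.n_cols / 4;
  int U4 = 4 * U;
  int BL = B * L;
  int ldw = C + U;
  arma::mat hs(BL, U), cs(BL, U), tcs(BL, U), gates(BL, U4);
  arma::mat zall(BL, U4); // x * W_x for every position
  blas_gemm('N', 'N', BL, U4, C, 1.0, x.memptr(), BL, W.memptr(), ldw,
            0.0, zall.memptr(), BL);
  arma::mat h(B, U, arma::fill::zeros), c(B, U, arma::fill::zeros);
  arma::mat zh(B, U4);
  for (int step = 0; step < L; ++step) {
    int t = reverse ? (L - 1 - step) : step;
    int r0 = t * B;
    // zh = h * W_h
    blas_gemm('N', 'N', B, U4, U, 1.0, h.memptr(), B, W.memptr() + C, ldw,
              0.0, zh.memptr(), B);
    for (int u = 0; u < U; ++u) {
      const double* zi = zall.colptr(u) + r0;
      const double* zf = zall.colptr(U + u) + r0;
      const double* zg = zall.colptr(2 * U + u) + r0;
      const double* zo = zall.colptr(3 * U + u) + r0;
      const double* hi = zh.colptr(u);
      const double* hf = zh.colptr(U + u);
      const double* hg = zh.colptr(2 * U + u);
      const double* ho = zh.colptr(3 * U + u);
      double bi = b[u], bf = b[U + u], bg = b[2 * U + u], bo = b[3 * U + u];
      double* gi = gates.colptr(u) + r0;
      double* gf = gates.colptr(U + u) + r0;
      double* gg = gates.colptr(2 * U + u) + r0;
      double* go = gates.colptr(3 * U + u) + r0;
      double* cu = c.colptr(u);
      double* hu = h.colptr(u);
      double* hsu = hs.colptr(u) + r0;
      double* csu = cs.colptr(u) + r0;
      double* tcu = tcs.colptr(u) + r0;
      for (int i = 0; i < B; ++i) {
        double vi = 1.0 / (1.0 + std::exp(-(zi[i] + hi[i] + bi)));
        double vf = 1.0 / (1.0 + std::exp(-(zf[i] + hf[i] + bf)));
        double vg = tanh_e(zg[i] + hg[i] + bg);
        double vo = 1.0 / (1.0 + std::exp(-(zo[i] + ho[i] + bo)));
        double cc = vf * cu[i] + vi * vg;
        double th = tanh_e(cc);
        double hh = vo * th;
        gi[i] = vi; gf[i] = vf; gg[i] = vg; go[i] = vo;
        cu[i] = cc; hu[i] = hh;
        csu[i] = cc; hsu[i] = hh; tcu[i] = th;
      }
    }
  }
  return List::create(_["hs"] = hs, _["cs"] = cs, _["tcs"] = tcs,
                      _["gates"] = gates);
}

// [[Rcpp::export]]
List lstm_backward_cpp(const arma::mat& x, int B, int L, const arma::mat& W,
                       const arma::mat& hs, const arma::mat& cs,
                       const arma::mat& tcs, const arma::mat& gates,
                       const arma::mat& dhs, bool reverse) {
  int C = x.n_cols;
  int U = hs.n_cols;
  int U4 = 4 * U;
  int BL = B * L;
  int ldw = C + U;
  arma::mat dzall(BL, U4);
  arma::mat dh_next(B, U, arma::fill::zeros);
  arma::mat dc_next(B, U, arma::fill::zeros);
  for (int step = L - 1; step >= 0; --step) {
    int t = reverse ? (L - 1 - step) : step;
    int tp = reverse ? (t + 1) : (t - 1); // previous step in scan order
    int r0 = t * B;
    bool has_prev = step > 0;
    for (int u = 0; u < U; ++u) {
      const double* gi = gates.colptr(u) + r0;
      const double* gf = gates.colptr(U + u) + r0;
      const double* gg = gates.colptr(2 * U + u) + r0;
      const double* go = gates.colptr(3 * U + u) + r0;
      const double* tcu = tcs.colptr(u) + r0;
      const double* cprev = has_prev ? cs.colptr(u) + tp * B : (double*)0;
      const double* dhsu = dhs.colptr(u) + r0;
      double* dhn = dh_next.colptr(u);
      double* dcn = dc_next.colptr(u);
      double* dzi = dzall.colptr(u) + r0;
      double* dzf = dzall.colptr(U + u) + r0;
      double* dzg = dzall.colptr(2 * U + u) + r0;
      double* dzo = dzall.colptr(3 * U + u) + r0;
      for (int i = 0; i < B; ++i) {
        double tc = tcu[i];
        double dh = dhsu[i] + dhn[i];
        double dgo = dh * tc;
        double dc = dcn[i] + dh * go[i] * (1.0 - tc * tc);
        double cp = has_prev ? cprev[i] : 0.0;
        dzi[i] = dc * gg[i] * gi[i] * (1.0 - gi[i]);
        dzf[i] = dc * cp * gf[i] * (1.0 - gf[i]);
        dzg[i] = dc * gi[i] * (1.0 - gg[i] * gg[i]);
        dzo[i] = dgo * go[i] * (1.0 - go[i]);
        dcn[i] = dc * gf[i];
      }
    }
    // dh_next = dz_t * W_h^T
    blas_gemm('N', 'T', B, U, U4, 1.0, dzall.memptr() + r0, BL,
              W.memptr() + C, ldw, 0.0, dh_next.memptr(), B);
  }
  // accumulate parameter and input gradients from the stored dz
  arma::mat dW(ldw, U4);
  // dW_x = x^T * dzall
  blas_gemm('T', 'N', C, U4, BL, 1.0, x.memptr(), BL, dzall.memptr(), BL,
            0.0, dW.memptr(), ldw);
  // hs shifted one step back in scan order (zeros at the scan start)
  arma::mat hprev(BL, U, arma::fill::zeros);
  for (int step = 1; step < L; ++step) {
    int t = reverse ? (L - 1 - step) : step;
    int tp = reverse ? (t + 1) : (t - 1);
    hprev.rows(t * B, t * B + B - 1) = hs.rows(tp * B, tp * B + B - 1);
  }
  // dW_h = hprev^T * dzall
  blas_gemm('T', 'N', U, U4, BL, 1.0, hprev.memptr(), BL, dzall.memptr(),
            BL, 0.0, dW.memptr() + C, ldw);
  arma::rowvec db = arma::sum(dzall, 0);
  // dx = dzall * W_x^T
  arma::mat dx(BL, C);
  blas_gemm('N', 'T', BL, C, U4, 1.0, dzall.memptr(), BL, W.memptr(), ldw,
            0.0, dx.memptr(), BL);
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
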