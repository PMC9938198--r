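#ifndef RNAFRAG_BLAS_SHIM_H
#define RNAFRAG_BLAS_SHIM_H

#include <R_ext/BLAS.h>

#ifndef FCONE
#define FCONE
#endif

// Column-major dgemm on raw pointers with explicit leading dimensions, so
// submatrix blocks (row ranges of flat activations) multiply without copies.
static inline void blas_gemm(char ta, char tb, int m, int n, int k,
                             double alpha, const double* A, int lda,
                             const double* B, int ldb, double beta,
                             double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, const_cast<double*>(A), &lda,
                  const_cast<double*>(B), &ldb, &beta, C, &ldc FCONE FCONE);
}

#endif
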