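// Fused compute kernels for the convolutional tower of the half-life
// regressor. All sequence tensors are channels x positions, column-major:
// a batch of B sequences of length L is a C x (B*L) matrix whose column
// (b-1)*L + t is position t of sequence b. Convolutions use 'same' zero
// padding handled by bounds checks, so no padded copies are made.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Copy a C x (B*L) batch into per-sequence zero-padded form:
// C x (B*(L+k-1)) with p = (k-1)/2 zero columns before and k-1-p after
// each sequence block.
static void padBatch(const double* x, double* xp, int C, int B, int L,
                     int k) {
  const int p = (k - 1) / 2;
  const int Lp = L + k - 1;
  std::memset(xp, 0, sizeof(double) * (size_t)C * B * Lp);
  for (int bb = 0; bb < B; ++bb)
    std::memcpy(xp + ((size_t)bb * Lp + p) * C,
                x + (size_t)bb * L * C, sizeof(double) * (size_t)C * L);
}

// 'Same'-padding 1D convolution as k accumulated GEMMs on contiguous
// slabs of the padded input; W is (k*Cin) x Cout tap-major, so tap j's
// Cin x Cout slice is addressed in place with leading dimension k*Cin.
// [[Rcpp::export(name = ".cppConvForward")]]
NumericMatrix cppConvForward(const NumericMatrix& X,
                             const NumericMatrix& W,
                             const NumericVector& b,
                             int B, int L, int k) {
  const int Cin = X.nrow(), Cout = W.ncol(), kCin = W.nrow();
  const int Lp = L + k - 1;
  const int N = B * L;
  std::vector<double> xp((size_t)Cin * B * Lp);
  padBatch(X.begin(), xp.data(), Cin, B, L, k);
  const double one = 1.0, zero = 0.0;
  const int p = (k - 1) / 2;
  NumericMatrix Z(Cout, N);
  double* z = Z.begin();
  if (Cin <= 8) {
    // narrow input (the 6-track first layer): gather an im2col matrix so
    // a single GEMM with inner dimension k*Cin does all the work
    std::vector<double> Y((size_t)kCin * N);
    for (int bb = 0; bb < B; ++bb) {
      const double* blk = xp.data() + (size_t)bb * Lp * Cin;
      double* yb = Y.data() + (size_t)bb * L * kCin;
      for (int t = 0; t < L; ++t)
        std::memcpy(yb + (size_t)t * kCin, blk + (size_t)t * Cin,
                    sizeof(double) * kCin);
    }
    F77_CALL(dgemm)("T", "N", &Cout, &N, &kCin, &one, W.begin(), &kCin,
                    Y.data(), &kCin, &zero, z, &Cout FCONE FCONE);
  } else {
    // padded-layout result: column p + t of each block holds output t
    std::vector<double> zp((size_t)Cout * B * Lp, 0.0);
    const int nslab = B * Lp - (k - 1);
    for (int j = 0; j < k; ++j) {
      // zp[:, u + p] += W_j' xp[:, u + j] for u = 0..nslab-1
      F77_CALL(dgemm)("T", "N", &Cout, &nslab, &Cin, &one,
                      W.begin() + (size_t)j * Cin, &kCin,
                      xp.data() + (size_t)j * Cin, &Cin, &one,
                      zp.data() + (size_t)p * Cout, &Cout FCONE FCONE);
    }
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(z + (size_t)bb * L * Cout,
                  zp.data() + ((size_t)bb * Lp + p) * Cout,
                  sizeof(double) * (size_t)Cout * L);
  }
  for (int n = 0; n < N; ++n) {
    double* zc = z + (size_t)n * Cout;
    for (int c = 0; c < Cout; ++c) zc[c] += b[c];
  }
  return Z;
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cppConvBackward(const NumericMatrix& dZ,
                     const NumericMatrix& X,
                     const NumericMatrix& W,
                     int B, int L, int k, bool need_dx) {
  const int Cin = X.nrow(), Cout = W.ncol(), kCin = W.nrow();
  const int p = (k - 1) / 2;
  const int Lp = L + k - 1;
  const int N = B * L;
  std::vector<double> xp((size_t)Cin * B * Lp);
  padBatch(X.begin(), xp.data(), Cin, B, L, k);
  std::vector<double> dzp((size_t)Cout * B * Lp);
  padBatch(dZ.begin(), dzp.data(), Cout, B, L, k);
  std::vector<double> dxp;
  if (need_dx) dxp.assign((size_t)Cin * B * Lp, 0.0);
  NumericMatrix dW(kCin, Cout);
  NumericVector db(Cout);
  const int nslab = B * Lp - (k - 1);
  const double one = 1.0;
  for (int j = 0; j < k; ++j) {
    // dW_j += xp_slab_j dz_slab_p' (slabs aligned as in the forward)
    F77_CALL(dgemm)("N", "T", &Cin, &Cout, &nslab, &one,
                    xp.data() + (size_t)j * Cin, &Cin,
                    dzp.data() + (size_t)p * Cout, &Cout, &one,
                    dW.begin() + (size_t)j * Cin, &kCin FCONE FCONE);
    if (!need_dx) continue;
    // dxp[:, u + j] += W_j dzp[:, u + p] for u = 0..nslab-1
    F77_CALL(dgemm)("N", "N", &Cin, &nslab, &Cout, &one,
                    W.begin() + (size_t)j * Cin, &kCin,
                    dzp.data() + (size_t)p * Cout, &Cout, &one,
                    dxp.data() + (size_t)j * Cin, &Cin FCONE FCONE);
  }
  NumericMatrix dX(need_dx ? Cin : 1, need_dx ? N : 1);
  if (need_dx) {
    double* dx = dX.begin();
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(dx + (size_t)bb * L * Cin,
                  dxp.data() + ((size_t)bb * Lp + p) * Cin,
                  sizeof(double) * (size_t)Cin * L);
  }
  const double* dz = dZ.begin();
  for (int n = 0; n < N; ++n) {
    const double* dzc = dz + (size_t)n * Cout;
    for (int c = 0; c < Cout; ++c) db[c] += dzc[c];
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// Layer normalization (per column, i.e. per position) fused with ReLU.
// Returns the post-ReLU output plus the caches needed for the backward
// pass (normalized values and inverse sd per column).
// [[Rcpp::export(name = ".cppLnReluForward")]]
List cppLnReluForward(const NumericMatrix& X,
                      const NumericVector& gamma,
                      const NumericVector& beta,
                      double eps) {
  const int C = X.nrow(), N = X.ncol();
  NumericMatrix out(C, N), xhat(C, N);
  NumericVector inv(N);
  const double* x = X.begin();
  double* o = out.begin();
  double* xh = xhat.begin();
  for (int n = 0; n < N; ++n) {
    const double* xc = x + (size_t)n * C;
    double mu = 0.0;
    for (int c = 0; c < C; ++c) mu += xc[c];
    mu /= C;
    double v = 0.0;
    for (int c = 0; c < C; ++c) {
      const double d = xc[c] - mu;
      v += d * d;
    }
    v /= C;
    const double iv = 1.0 / std::sqrt(v + eps);
    inv[n] = iv;
    double* oc = o + (size_t)n * C;
    double* xhc = xh + (size_t)n * C;
    for (int c = 0; c < C; ++c) {
      const double h = (xc[c] - mu) * iv;
      xhc[c] = h;
      const double pre = h * gamma[c] + beta[c];
      oc[c] = pre > 0.0 ? pre : 0.0;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["inv"] = inv);
}

// Backward of the fused layer-norm + ReLU. `out` is the forward output
// (used to recover the ReLU mask).
// [[Rcpp::export(name = ".cppLnReluBackward")]]
List cppLnReluBackward(const NumericMatrix& dOut,
                       const NumericMatrix& out,
                       const NumericMatrix& xhat,
                       const NumericVector& inv,
                       const NumericVector& gamma) {
  const int C = dOut.nrow(), N = dOut.ncol();
  NumericMatrix dX(C, N);
  NumericVector dgamma(C), dbeta(C);
  const double* d = dOut.begin();
  const double* o = out.begin();
  const double* xh = xhat.begin();
  double* dx = dX.begin();
  std::vector<double> dxh(C);
  for (int n = 0; n < N; ++n) {
    const double* dc = d + (size_t)n * C;
    const double* oc = o + (size_t)n * C;
    const double* xhc = xh + (size_t)n * C;
    double m1 = 0.0, m2 = 0.0;
    for (int c = 0; c < C; ++c) {
      const double dpre = oc[c] > 0.0 ? dc[c] : 0.0;
      dgamma[c] += dpre * xhc[c];
      dbeta[c] += dpre;
      const double v = dpre * gamma[c];
      dxh[c] = v;
      m1 += v;
      m2 += v * xhc[c];
    }
    m1 /= C;
    m2 /= C;
    double* dxc = dx + (size_t)n * C;
    const double iv = inv[n];
    for (int c = 0; c < C; ++c)
      dxc[c] = (dxh[c] - m1 - xhc[c] * m2) * iv;
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Width-2 max pooling over positions; ties resolve to the earlier
// position. Mask records whether the first element won.
// [[Rcpp::export(name = ".cppPoolForward")]]
List cppPoolForward(const NumericMatrix& X, int B, int L) {
  const int C = X.nrow();
  const int N2 = B * L / 2;
  NumericMatrix out(C, N2);
  LogicalMatrix mask(C, N2);
  const double* x = X.begin();
  double* o = out.begin();
  int* m = mask.begin();
  for (int n = 0; n < N2; ++n) {
    const double* a = x + (size_t)(2 * n) * C;
    const double* b = a + C;
    double* oc = o + (size_t)n * C;
    int* mc = m + (size_t)n * C;
    for (int c = 0; c < C; ++c) {
      const bool first = a[c] >= b[c];
      mc[c] = first;
      oc[c] = first ? a[c] : b[c];
    }
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export(name = ".cppPoolBackward")]]
NumericMatrix cppPoolBackward(const NumericMatrix& dOut,
                              const LogicalMatrix& mask,
                              int B, int L) {
  const int C = dOut.nrow();
  const int N2 = B * L / 2;
  NumericMatrix dX(C, B * L);
  const double* d = dOut.begin();
  const int* m = mask.begin();
  double* dx = dX.begin();
  for (int n = 0; n < N2; ++n) {
    const double* dc = d + (size_t)n * C;
    const int* mc = m + (size_t)n * C;
    double* a = dx + (size_t)(2 * n) * C;
    double* b = a + C;
    for (int c = 0; c < C; ++c) {
      if (mc[c]) a[c] = dc[c]; else b[c] = dc[c];
    }
  }
  return dX;
}

// Inverted dropout using R's RNG (honors set.seed). Returns the dropped
// matrix and the logical keep mask.
// [[Rcpp::export(name = ".cppDropoutForward")]]
List cppDropoutForward(const NumericMatrix& X, double keep) {
  const int C = X.nrow(), N = X.ncol();
  NumericMatrix out(C, N);
  LogicalMatrix mask(C, N);
  const double* x = X.begin();
  double* o = out.begin();
  int* m = mask.begin();
  const double scale = 1.0 / keep;
  const size_t len = (size_t)C * N;
  for (size_t i = 0; i < len; ++i) {
    const bool kept = unif_rand() < keep;
    m[i] = kept;
    o[i] = kept ? x[i] * scale : 0.0;
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export(name = ".cppDropoutBackward")]]
NumericMatrix cppDropoutBackward(const NumericMatrix& dOut,
                                 const LogicalMatrix& mask, double keep) {
  const int C = dOut.nrow(), N = dOut.ncol();
  NumericMatrix dX(C, N);
  const double* d = dOut.begin();
  const int* m = mask.begin();
  double* dx = dX.begin();
  const double scale = 1.0 / keep;
  const size_t len = (size_t)C * N;
  for (size_t i = 0; i < len; ++i) dx[i] = m[i] ? d[i] * scale : 0.0;
  return dX;
}
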