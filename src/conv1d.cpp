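// 1D convolution kernels (stride 1, same padding) for the sample-major
// activation layout: a batch of B signals of length L with C channels is a
// C x (L*B) matrix whose columns are time steps, sample-major. Each sample
// is zero-padded with P columns per side, which makes every kernel tap a
// constant column offset across the whole padded batch: one accumulating
// dgemm per tap, no temporaries, no per-sample loops. Pad columns are zero,
// so taps never bleed across batch members in the extracted region.
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
using namespace Rcpp;

static void pad_batch(const double* X, double* Xp, int C, int L, int B, int P) {
  const int Lp = L + 2 * P;
  std::memset(Xp, 0, sizeof(double) * (size_t)C * Lp * B);
  for (int s = 0; s < B; ++s)
    std::memcpy(Xp + (size_t)C * (s * Lp + P), X + (size_t)C * s * L,
                sizeof(double) * (size_t)C * L);
}

static void unpad_batch(const double* Xp, double* X, int C, int L, int B, int P) {
  const int Lp = L + 2 * P;
  for (int s = 0; s < B; ++s)
    std::memcpy(X + (size_t)C * s * L, Xp + (size_t)C * (s * Lp + P),
                sizeof(double) * (size_t)C * L);
}

// [[Rcpp::export]]
NumericMatrix cpp_conv1d_fwd(const NumericMatrix X, const NumericVector W,
                             const NumericVector b, const int L, const int B) {
  const IntegerVector dims = W.attr("dim");
  const int Cout = dims[0], Cin = dims[1], K = dims[2];
  const int P = (K - 1) / 2, Lp = L + 2 * P, N = Lp * B;
  std::vector<double> Xp((size_t)Cin * N), Yp((size_t)Cout * N, 0.0);
  pad_batch(X.begin(), Xp.data(), Cin, L, B, P);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int d = k - P;                   // output col c reads input col c+d
    const int a = std::max(0, -d), bb = N - 1 - std::max(0, d);
    const int nc = bb - a + 1;
    F77_CALL(dgemm)("N", "N", &Cout, &nc, &Cin, &one,
                    &W[(size_t)Cout * Cin * k], &Cout,
                    Xp.data() + (size_t)Cin * (a + d), &Cin, &one,
                    Yp.data() + (size_t)Cout * a, &Cout FCONE FCONE);
  }
  NumericMatrix Y(Cout, L * B);
  unpad_batch(Yp.data(), Y.begin(), Cout, L, B, P);
  for (int c = 0; c < L * B; ++c)
    for (int i = 0; i < Cout; ++i) Y[(size_t)c * Cout + i] += b[i];
  return Y;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const NumericMatrix X, const NumericVector W,
                    const NumericMatrix dY, const int L, const int B) {
  const IntegerVector dims = W.attr("dim");
  const int Cout = dims[0], Cin = dims[1], K = dims[2];
  const int P = (K - 1) / 2, Lp = L + 2 * P, N = Lp * B;
  std::vector<double> Xp((size_t)Cin * N), dYp((size_t)Cout * N),
      dXp((size_t)Cin * N, 0.0);
  pad_batch(X.begin(), Xp.data(), Cin, L, B, P);
  pad_batch(dY.begin(), dYp.data(), Cout, L, B, P);
  NumericVector dW(Cout * Cin * K);
  dW.attr("dim") = IntegerVector::create(Cout, Cin, K);
  NumericVector db(Cout);
  for (int c = 0; c < L * B; ++c)
    for (int i = 0; i < Cout; ++i) db[i] += dY[(size_t)c * Cout + i];
  const double one = 1.0, zero = 0.0;
  for (int k = 0; k < K; ++k) {
    const int d = k - P;
    const int a = std::max(0, -d), bb = N - 1 - std::max(0, d);
    const int nc = bb - a + 1;
    // dW_k = dYp[, a..b] %*% t(Xp[, a+d..b+d])
    F77_CALL(dgemm)("N", "T", &Cout, &Cin, &nc, &one,
                    dYp.data() + (size_t)Cout * a, &Cout,
                    Xp.data() + (size_t)Cin * (a + d), &Cin, &zero,
                    &dW[(size_t)Cout * Cin * k], &Cout FCONE FCONE);
    // dXp[, a+d..b+d] += t(W_k) %*% dYp[, a..b]
    F77_CALL(dgemm)("T", "N", &Cin, &nc, &Cout, &one,
                    &W[(size_t)Cout * Cin * k], &Cout,
                    dYp.data() + (size_t)Cout * a, &Cout, &one,
                    dXp.data() + (size_t)Cin * (a + d), &Cin FCONE FCONE);
  }
  NumericMatrix dX(Cin, L * B);
  unpad_batch(dXp.data(), dX.begin(), Cin, L, B, P);
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}
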