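#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Fused 1D same-convolution forward/backward: im2col is materialized only
// in cache-sized column panels that feed BLAS dgemm directly, so the full
// (k*C) x (L*N) matrix never exists. Activations are (L, N, C) arrays.

static const int PANEL = 128;

// fill panel columns [j0, j1) of the implicit im2col matrix; column
// j = n*L + l, row r = c*k + t, zero-padded same-convolution
static void fill_panel(const double* x, double* M, int L, int N, int C,
                       int k, int j0, int j1) {
  int pad = (k - 1) / 2;
  size_t nrow = (size_t)k * C;
  for (int j = j0; j < j1; ++j) {
    int n = j / L, l = j % L;
    double* col = M + nrow * (size_t)(j - j0);
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)L * (n + (size_t)N * c);
      for (int t = 0; t < k; ++t) {
        int s = l + t - pad;
        col[c * k + t] = (s >= 0 && s < L) ? xc[s] : 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv1d_fwd(NumericVector x, NumericMatrix W,
                            NumericVector b) {
  IntegerVector d = x.attr("dim");
  int L = d[0], N = d[1], C = d[2];
  int kC = W.nrow(), Cout = W.ncol();
  int k = kC / C;
  if (k * C != kC) stop("weight rows not a multiple of input channels");
  size_t LN = (size_t)L * N;
  int iLN = (int)LN;
  NumericVector y(LN * Cout);
  y.attr("dim") = IntegerVector::create(L, N, Cout);
  std::vector<double> M((size_t)kC * PANEL);
  const double one = 1.0, zero = 0.0;
  for (int j0 = 0; j0 < (int)LN; j0 += PANEL) {
    int j1 = std::min<int>(j0 + PANEL, (int)LN);
    int P = j1 - j0;
    fill_panel(x.begin(), M.data(), L, N, C, k, j0, j1);
    // Y[j0:j1, ] = M' W
    F77_CALL(dgemm)("T", "N", &P, &Cout, &kC, &one, M.data(), &kC,
                    W.begin(), &kC, &zero, y.begin() + j0, &iLN
                    FCONE FCONE);
  }
  // bias
  double* py = y.begin();
  for (int co = 0; co < Cout; ++co) {
    double bc = b[co];
    double* col = py + (size_t)co * LN;
    for (size_t i = 0; i < LN; ++i) col[i] += bc;
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv1d_bwd(NumericVector x, NumericVector dy, NumericMatrix W) {
  IntegerVector d = x.attr("dim");
  int L = d[0], N = d[1], C = d[2];
  int kC = W.nrow(), Cout = W.ncol();
  int k = kC / C, pad = (k - 1) / 2;
  size_t LN = (size_t)L * N;
  int iLN = (int)LN;
  NumericVector dx(LN * C);
  dx.attr("dim") = IntegerVector::create(L, N, C);
  NumericMatrix dW(kC, Cout);
  NumericVector db(Cout);
  std::vector<double> M((size_t)kC * PANEL), dM((size_t)kC * PANEL);
  const double one = 1.0, zero = 0.0;
  for (int j0 = 0; j0 < (int)LN; j0 += PANEL) {
    int j1 = std::min<int>(j0 + PANEL, (int)LN);
    int P = j1 - j0;
    fill_panel(x.begin(), M.data(), L, N, C, k, j0, j1);
    // dW += M dYpanel ; dYpanel = dy[j0:j1, ] with leading dim LN
    F77_CALL(dgemm)("N", "N", &kC, &Cout, &P, &one, M.data(), &kC,
                    dy.begin() + j0, &iLN, &one, dW.begin(), &kC
                    FCONE FCONE);
    // dM = W dYpanel'
    F77_CALL(dgemm)("N", "T", &kC, &P, &Cout, &one, W.begin(), &kC,
                    dy.begin() + j0, &iLN, &zero, dM.data(), &kC
                    FCONE FCONE);
    // scatter-add dM back into dx
    for (int j = j0; j < j1; ++j) {
      int n = j / L, l = j % L;
      const double* col = dM.data() + (size_t)kC * (j - j0);
      for (int c = 0; c < C; ++c) {
        double* xc = dx.begin() + (size_t)L * (n + (size_t)N * c);
        for (int t = 0; t < k; ++t) {
          int s = l + t - pad;
          if (s >= 0 && s < L) xc[s] += col[c * k + t];
        }
      }
    }
  }
  const double* pdy = dy.begin();
  for (int co = 0; co < Cout; ++co) {
    double acc = 0.0;
    const double* col = pdy + (size_t)co * LN;
    for (size_t i = 0; i < LN; ++i) acc += col[i];
    db[co] = acc;
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
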