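#include <Rcpp.h>
using namespace Rcpp;

// Activations are stored as (L, N, C) arrays: band index fastest, then
// sample, then channel, so conv output reshapes straight from the GEMM.

// im2col for 1D same-convolution: returns (k*C) x (L*N) matrix whose
// column (n*L + l) holds the receptive field of band l in sample n,
// rows ordered channel-major then tap (r = c*k + t). Zero padding.
// [[Rcpp::export]]
NumericMatrix nn_im2col1d(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  int L = d[0], N = d[1], C = d[2];
  int pad = (k - 1) / 2;
  NumericMatrix out(k * C, L * N);
  const double* px = x.begin();
  double* po = out.begin();
  size_t nrow = (size_t)k * C;
  // loop order chosen so the source reads are contiguous in l
  for (int n = 0; n < N; ++n) {
    double* blk = po + nrow * (size_t)n * L;
    for (int c = 0; c < C; ++c) {
      const double* xc = px + (size_t)L * (n + (size_t)N * c);
      for (int t = 0; t < k; ++t) {
        int l0 = pad - t > 0 ? pad - t : 0;
        int l1 = L + pad - t < L ? L + pad - t : L;
        double* dst = blk + (size_t)(c * k + t);
        const double* src = xc + (l0 + t - pad);
        for (int l = l0; l < l1; ++l, src++)
          dst[(size_t)l * nrow] = *src;
      }
    }
  }
  return out;
}

// Adjoint of nn_im2col1d: scatter-add a (k*C) x (L*N) gradient back to
// an (L, N, C) input gradient.
// [[Rcpp::export]]
NumericVector nn_col2im1d(NumericMatrix dM, int k, int L, int N, int C) {
  int pad = (k - 1) / 2;
  NumericVector dx(L * N * C);
  dx.attr("dim") = IntegerVector::create(L, N, C);
  double* pdx = dx.begin();
  const double* pm = dM.begin();
  size_t nrow = (size_t)k * C;
  for (int n = 0; n < N; ++n) {
    const double* blk = pm + nrow * (size_t)n * L;
    for (int c = 0; c < C; ++c) {
      double* xc = pdx + (size_t)L * (n + (size_t)N * c);
      for (int t = 0; t < k; ++t) {
        int l0 = pad - t > 0 ? pad - t : 0;
        int l1 = L + pad - t < L ? L + pad - t : L;
        const double* src = blk + (size_t)(c * k + t);
        double* dst = xc + (l0 + t - pad);
        for (int l = l0; l < l1; ++l, dst++)
          *dst += src[(size_t)l * nrow];
      }
    }
  }
  return dx;
}

// Non-overlapping max pooling along the band axis; remainder bands are
// dropped. Returns pooled values and 1-based argmax band indices.
// [[Rcpp::export]]
List nn_maxpool1d(NumericVector x, int p) {
  IntegerVector d = x.attr("dim");
  int L = d[0], N = d[1], C = d[2];
  int Lo = L / p;
  NumericVector y(Lo * N * C);
  IntegerVector idx(Lo * N * C);
  y.attr("dim") = IntegerVector::create(Lo, N, C);
  idx.attr("dim") = IntegerVector::create(Lo, N, C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      const double* xc = px + (size_t)L * (n + (size_t)N * c);
      size_t off = (size_t)Lo * (n + (size_t)N * c);
      for (int lo = 0; lo < Lo; ++lo) {
        int best = lo * p;
        double bv = xc[best];
        for (int t = 1; t < p; ++t) {
          if (xc[lo * p + t] > bv) { bv = xc[lo * p + t]; best = lo * p + t; }
        }
        y[off + lo] = bv;
        idx[off + lo] = best + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool1d_bwd(NumericVector dy, IntegerVector idx, int L) {
  IntegerVector d = dy.attr("dim");
  int Lo = d[0], N = d[1], C = d[2];
  NumericVector dx(L * N * C);
  dx.attr("dim") = IntegerVector::create(L, N, C);
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      size_t offo = (size_t)Lo * (n + (size_t)N * c);
      size_t offi = (size_t)L * (n + (size_t)N * c);
      for (int lo = 0; lo < Lo; ++lo) {
        dx[offi + idx[offo + lo] - 1] += dy[offo + lo];
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) py[i] = px[i] > 0 ? px[i] : 0.0;
  return y;
}

// ReLU backward using the forward output: dy where y > 0, else 0.
// [[Rcpp::export]]
NumericVector nn_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* pd = dy.begin();
  const double* py = y.begin();
  double* px = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) px[i] = py[i] > 0 ? pd[i] : 0.0;
  return dx;
}

// In-place variants: callers guarantee the argument is a freshly allocated
// intermediate with no other live reference.

// [[Rcpp::export]]
NumericVector nn_relu_ip(NumericVector x) {
  double* px = x.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) if (px[i] < 0) px[i] = 0.0;
  return x;
}

// [[Rcpp::export]]
NumericVector nn_relu_bwd_ip(NumericVector dy, NumericVector y) {
  double* pd = dy.begin();
  const double* py = y.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) if (py[i] <= 0) pd[i] = 0.0;
  return dy;
}

// Fused AdamW update, mutating parameters and moment buffers in place.
// [[Rcpp::export]]
void nn_adamw(NumericVector p, NumericVector g, NumericVector m,
              NumericVector v, double lr, double wd, double b1, double b2,
              double eps, double bc1, double bc2) {
  double* pp = p.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  for (R_xlen_t i = 0; i < p.size(); ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    pp[i] -= lr * ((pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps) + wd * pp[i]);
  }
}
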