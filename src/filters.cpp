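#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filtering of a channels x samples matrix,
// with explicit per-channel state so streams can be filtered chunk by chunk
// with exact continuity. b and a are the numerator/denominator coefficients
// (a[0] need not be 1; it is normalized here). zi has n-1 state values per
// channel, where n = max(length(b), length(a)).
// [[Rcpp::export]]
List df2t_filter(NumericVector b, NumericVector a, NumericMatrix x,
                 NumericMatrix zi) {
  int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0);
  double a0 = a[0];
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i] / a0;

  int n_ch = x.nrow(), n_s = x.ncol();
  if (zi.nrow() != n_ch || zi.ncol() != n - 1)
    stop("zi must be channels x (filter order) in size");

  NumericMatrix y(n_ch, n_s);
  NumericMatrix zf(clone(zi));
  for (int c = 0; c < n_ch; ++c) {
    std::vector<double> z(n - 1);
    for (int i = 0; i < n - 1; ++i) z[i] = zf(c, i);
    for (int t = 0; t < n_s; ++t) {
      double xn = x(c, t);
      double yn = bb[0] * xn + z[0];
      for (int i = 0; i < n - 2; ++i)
        z[i] = bb[i + 1] * xn + z[i + 1] - aa[i + 1] * yn;
      z[n - 2] = bb[n - 1] * xn - aa[n - 1] * yn;
      y(c, t) = yn;
    }
    for (int i = 0; i < n - 1; ++i) zf(c, i) = z[i];
  }
  return List::create(_["y"] = y, _["zf"] = zf);
}

// fast elementwise ELU and its derivative (expressed via the output),
// avoiding repeated logical-mask allocations on multi-megabyte conv tensors
// [[Rcpp::export]]
NumericVector elu_cpp(NumericVector x) {
  NumericVector y(clone(x));
  int n = y.size();
  for (int i = 0; i < n; ++i) if (y[i] <= 0) y[i] = std::exp(y[i]) - 1.0;
  return y;
}

// [[Rcpp::export]]
NumericVector elu_grad_cpp(NumericVector y) {
  NumericVector g(y.size());
  int n = y.size();
  for (int i = 0; i < n; ++i) g[i] = y[i] > 0 ? 1.0 : y[i] + 1.0;
  return g;
}

// one-pass row mean and variance (biased) of a features x observations
// matrix; avoids materializing Z*Z
// [[Rcpp::export]]
List row_mean_var_cpp(NumericMatrix Z) {
  int nr = Z.nrow(); R_xlen_t nc = Z.ncol();
  NumericVector mu(nr), v(nr);
  const double* p = Z.begin();
  for (R_xlen_t j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) { double z = *p++; mu[i] += z; v[i] += z * z; }
  for (int i = 0; i < nr; ++i) {
    mu[i] /= nc;
    v[i] = v[i] / nc - mu[i] * mu[i];
    if (v[i] < 0) v[i] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = v);
}

// fused batch-norm + ELU forward over rows: y = elu(xhat * g + b),
// xhat = (Z - mu) * sdinv. Returns the activation and xhat for backward.
// [[Rcpp::export]]
List bn_elu_forward_cpp(NumericMatrix Z, NumericVector mu, NumericVector sdinv,
                        NumericVector g, NumericVector b) {
  int nr = Z.nrow(); R_xlen_t nc = Z.ncol();
  NumericMatrix y(nr, nc), xhat(nr, nc);
  const double* pz = Z.begin();
  double* py = y.begin();
  double* px = xhat.begin();
  for (R_xlen_t j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double xh = (*pz++ - mu[i]) * sdinv[i];
      *px++ = xh;
      double t = xh * g[i] + b[i];
      *py++ = t > 0 ? t : std::exp(t) - 1.0;
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// fused backward through ELU and training-mode batch norm. dA is the
// gradient at the activation output, Y the activation output itself.
// [[Rcpp::export]]
List bn_elu_backward_cpp(NumericMatrix dA, NumericMatrix Y, NumericMatrix xhat,
                         NumericVector sdinv, NumericVector g) {
  int nr = dA.nrow(); R_xlen_t nc = dA.ncol();
  NumericMatrix dZ(nr, nc);
  NumericVector dg(nr), db(nr), s1(nr), s2(nr);
  const double *pa = dA.begin(), *py = Y.begin(), *px = xhat.begin();
  {
    const double *a = pa, *y = py, *x = px;
    for (R_xlen_t j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double dy = *a++ * ((*y > 0) ? 1.0 : (*y + 1.0)); ++y;
        double dxh = dy * g[i];
        dg[i] += dy * *x;
        db[i] += dy;
        s1[i] += dxh;
        s2[i] += dxh * *x++;
      }
  }
  for (int i = 0; i < nr; ++i) { s1[i] /= nc; s2[i] /= nc; }
  {
    const double *a = pa, *y = py, *x = px;
    double* pdz = dZ.begin();
    for (R_xlen_t j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        double dy = *a++ * ((*y > 0) ? 1.0 : (*y + 1.0)); ++y;
        double dxh = dy * g[i];
        *pdz++ = (dxh - s1[i] - *x++ * s2[i]) * sdinv[i];
      }
  }
  return List::create(_["dZ"] = dZ, _["dg"] = dg, _["db"] = db);
}

// im2col for the temporal convolution: X is a (channels x samples x batch)
// array; returns the (kernel_len x channels*positions*batch) unfolded
// matrix with columns ordered (channel, position, batch)
// [[Rcpp::export]]
NumericMatrix unfold_cpp(NumericVector X, int C, int S, int B, int ts) {
  int L1 = S - ts + 1;
  NumericMatrix M(ts, (R_xlen_t)C * L1 * B);
  const double* px = X.begin();
  double* pm = M.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (R_xlen_t)b * C * S;
    for (int t = 0; t < L1; ++t) {
      for (int c = 0; c < C; ++c) {
        const double* xs = xb + c + (R_xlen_t)t * C;
        for (int j = 0; j < ts; ++j) *pm++ = xs[(R_xlen_t)j * C];
      }
    }
  }
  return M;
}
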