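#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Row-major encoding gain of a sorted module submatrix relative to the
// independent-background null code. `x` must already be sorted (rows by
// decreasing row sum, columns by decreasing column sum). Per-cell model:
// the row's single expected aberration lands on gene j with probability
// proportional to gene j's remaining (unobserved) aberration count; once a
// one has been seen in the row, or a gene/sample has no unobserved
// aberrations left, the probability of a one drops to eps.
// [[Rcpp::export(name = ".encoding_gain_cpp")]]
double encoding_gain_cpp(IntegerMatrix x, double p_null, double eps) {
  const int k = x.nrow(), m = x.ncol();
  std::vector<double> a(m, 0.0); // per-gene unobserved counts
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += x(i, j);
    a[j] = s;
  }
  const double ln1 = std::log2(p_null), ln0 = std::log2(1.0 - p_null);
  double d = 0.0;
  for (int i = 0; i < k; ++i) {
    double b = 0.0; // this sample's unobserved count
    for (int j = 0; j < m; ++j) b += x(i, j);
    bool has_one = false;
    // sum of remaining gene counts over this row's unobserved cells
    double tail = 0.0;
    for (int j = 0; j < m; ++j) tail += a[j];
    for (int j = 0; j < m; ++j) {
      double p1;
      if (has_one || a[j] <= 0.0 || b <= 0.0) {
        p1 = eps;
      } else {
        p1 = a[j] / tail;
        if (p1 < eps) p1 = eps;
        if (p1 > 1.0 - eps) p1 = 1.0 - eps;
      }
      if (x(i, j) == 1) d += std::log2(p1) - ln1;
      else              d += std::log2(1.0 - p1) - ln0;
      tail -= a[j];
      if (x(i, j) == 1) { a[j] -= 1.0; b -= 1.0; has_one = true; }
    }
  }
  return d;
}

// Winnow2 online training: multiplicative promotion on false negatives,
// demotion by division on false positives. Samples are visited in input
// order for `epochs` passes; weights start at 1 and stay positive.
// [[Rcpp::export(name = ".winnow_train_cpp")]]
NumericVector winnow_train_cpp(IntegerMatrix feat, IntegerVector y,
                               double alpha, double theta, int epochs) {
  const int k = feat.nrow(), p = feat.ncol();
  NumericVector w(p, 1.0);
  for (int e = 0; e < epochs; ++e) {
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) if (feat(i, j) == 1) s += w[j];
      const bool pred = s >= theta;
      if (y[i] == 1 && !pred) {
        for (int j = 0; j < p; ++j) if (feat(i, j) == 1) w[j] *= alpha;
      } else if (y[i] == 0 && pred) {
        for (int j = 0; j < p; ++j) if (feat(i, j) == 1) w[j] /= alpha;
      }
    }
  }
  return w;
}
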