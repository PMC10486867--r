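#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Column-wise weighted median of M restricted to the given rows
// (1-based indices). The weighted L1 minimizer per coordinate; with equal
// weights and an even count it averages the two central values, matching
// stats::median.
// [[Rcpp::export]]
NumericVector cpp_col_weighted_median(const NumericMatrix& M,
                                      const IntegerVector& rows,
                                      const NumericVector& w) {
  const int n = rows.size();
  const int G = M.ncol();
  NumericVector out(G);
  if (n == 0) return out;
  bool uniform = true;
  for (int i = 1; i < n && uniform; ++i) {
    if (w[i] != w[0]) uniform = false;
  }
  std::vector<double> v(n);
  if (uniform) {
    // plain median via partial selection
    const int mid = n / 2;
    for (int g = 0; g < G; ++g) {
      for (int i = 0; i < n; ++i) v[i] = M(rows[i] - 1, g);
      std::nth_element(v.begin(), v.begin() + mid, v.end());
      double hi = v[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + mid);
        out[g] = (lo + hi) / 2.0;
      } else {
        out[g] = hi;
      }
    }
    return out;
  }
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) wtot += w[i];
  const double half = wtot / 2.0;
  std::vector<int> ord(n);
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < n; ++i) v[i] = M(rows[i] - 1, g);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    double cw = 0.0;
    for (int i = 0; i < n; ++i) {
      cw += w[ord[i]];
      if (cw >= half - 1e-12) {
        if (std::abs(cw - half) <= 1e-12 && i + 1 < n) {
          out[g] = (v[ord[i]] + v[ord[i + 1]]) / 2.0;
        } else {
          out[g] = v[ord[i]];
        }
        break;
      }
    }
  }
  return out;
}

// Pairwise L1 distances between rows of X and rows of C (n x k), looping
// gene-major so the column-major matrices are walked sequentially.
// [[Rcpp::export]]
NumericMatrix cpp_l1_dist(const NumericMatrix& X, const NumericMatrix& C) {
  const int n = X.nrow(), G = X.ncol(), k = C.nrow();
  NumericMatrix D(n, k);
  std::vector<double> acc(n);
  for (int j = 0; j < k; ++j) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int g = 0; g < G; ++g) {
      const double cg = C(j, g);
      const double* xg = &X(0, g);
      for (int i = 0; i < n; ++i) acc[i] += std::fabs(xg[i] - cg);
    }
    for (int i = 0; i < n; ++i) D(i, j) = acc[i];
  }
  return D;
}
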