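#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// distance between templates x[i..i+d-1] and x[j..j+d-1]
static inline double tmpl_dist(const double* x, int i, int j, int d,
                               bool chebyshev) {
  if (chebyshev) {
    double m = 0.0;
    for (int k = 0; k < d; ++k) {
      double v = std::fabs(x[i + k] - x[j + k]);
      if (v > m) m = v;
    }
    return m;
  }
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double v = x[i + k] - x[j + k];
    s += v * v;
  }
  return std::sqrt(s);
}

// mean log correlation integral at embedding dimension m, self-matches
// included: phi(m) = (1/n) sum_i log(C_i), C_i = (#{j: dist<=r}) / n,
// n = L - m + 1 templates
static double phi_m(const double* x, int L, int m, double r,
                    bool chebyshev) {
  int n = L - m + 1;
  std::vector<int> cnt(n, 1);  // self-match
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (tmpl_dist(x, i, j, m, chebyshev) <= r) {
        ++cnt[i];
        ++cnt[j];
      }
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    s += std::log(static_cast<double>(cnt[i]) / n);
  return s / n;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int d, double r, bool chebyshev) {
  int L = x.size();
  return phi_m(REAL(x), L, d, r, chebyshev) -
         phi_m(REAL(x), L, d + 1, r, chebyshev);
}

// Template-match pair counts for sample entropy over the first L - d
// templates, self-matches excluded: [0] matches at dimension d+1 (A),
// [1] matches at dimension d (B).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int d, double r,
                                bool chebyshev) {
  int L = x.size();
  int n = L - d;  // templates of length d+1 (and the first n of length d)
  double A = 0.0, B = 0.0;
  const double* px = REAL(x);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (tmpl_dist(px, i, j, d, chebyshev) <= r) ++B;
      if (tmpl_dist(px, i, j, d + 1, chebyshev) <= r) ++A;
    }
  return NumericVector::create(A, B);
}
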