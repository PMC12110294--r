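#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy template counts with Chebyshev (max-norm) distance and
// self-matches excluded. Templates are taken at stride `lag` (lag 1 is the
// classical SampEn; lag tau serves the moving-average multiscale variant).
// Returns c(B, A): B = matching m-template pairs, A = matching (m+1)-template
// pairs; both over unordered distinct pairs.

// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double tol, int lag) {
  const int n = x.size();
  // number of (m+1)-length templates at stride lag
  const int ntpl = n - m * lag;
  double A = 0.0, B = 0.0;
  if (ntpl < 2) return NumericVector::create(0.0, 0.0);

  for (int i = 0; i < ntpl - 1; ++i) {
    for (int j = i + 1; j < ntpl; ++j) {
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k * lag] - x[j + k * lag]) > tol) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m * lag] - x[j + m * lag]) <= tol) A += 1.0;
    }
  }
  return NumericVector::create(B, A);
}
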