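#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy of a numeric series with embedding dimension m and
// tolerance r (Chebyshev distance, self-matches excluded).
// Counts template pairs over the N - m template vectors; A extends the
// match by one sample. Returns -log(A/B), NA when no matches exist.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;           // templates of length m (extendable to m+1)
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  if (A <= 0.0 || B <= 0.0) return NA_REAL;
  return -std::log(A / B);
}
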