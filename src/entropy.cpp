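#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy by direct template counting.
//
// Templates of length m and m+1 are both drawn from the first n - m
// starting positions so that the conditional probability A/B compares
// counts over the same template set (Richman & Moorman convention).
// Distance is Chebyshev (max absolute coordinate difference), matches are
// counted over unordered pairs i < j (self-matches excluded), and the
// result is -log(A/B) in nats. NA is returned when either count is zero
// (entropy undefined) or the series is too short.
//
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of (m+1)-length templates
  if (nt < 2 || m < 1 || r < 0) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  if (A == 0.0 || B == 0.0) return NA_REAL;
  return -std::log(A / B);
}
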