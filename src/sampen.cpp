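#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Template-match counts for sample entropy under the Chebyshev distance.
// Counts unordered pairs i != j (i, j in 0..N-m-1) whose length-m templates
// lie strictly within tolerance r, and how many still match when extended to
// length m+1. Both counts range over the same template index set (the
// Richman-Moorman convention), so the conditional probability is well
// defined. Pairs are enumerated in order of the templates' first sample so
// that the scan can stop as soon as the first-coordinate gap reaches r
// (first-coordinate distance bounds the Chebyshev distance from below);
// this prunes most comparisons without changing the counts.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;                 // usable templates of length m (and m+1)
  if (nt < 2) stop("series too short for embedding dimension m");
  std::vector<int> ord(nt);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  double a_cnt = 0.0, b_cnt = 0.0;
  for (int ii = 0; ii < nt - 1; ++ii) {
    int i = ord[ii];
    for (int jj = ii + 1; jj < nt; ++jj) {
      int j = ord[jj];
      if (x[j] - x[i] >= r) break;      // sorted: no later j can match
      double d = 0.0;
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d >= r) { ok = false; break; }
      }
      if (ok) {
        a_cnt += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) < r) b_cnt += 1.0;
      }
    }
  }
  return List::create(Named("matches_m") = a_cnt,
                      Named("matches_m1") = b_cnt);
}
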