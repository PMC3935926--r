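#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Minimum-M-statistic scan over all rows of a features x samples matrix.
// For one feature the candidate cutoffs are the midpoints between
// consecutive distinct pooled values plus one cutoff above the maximum;
// at each cutoff the one-sided (case-high) hypergeometric upper tail of
// the 2x2 threshold table is evaluated and the minimum over cutoffs is
// returned. Ties in p go to the largest cutoff.

// [[Rcpp::export]]
List cpp_mscore(NumericMatrix X, LogicalVector is_case) {
  const int p = X.nrow();
  const int n = X.ncol();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += is_case[i];
  const int n2 = n - n1;
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty");

  NumericVector pval(p), cutoff(p);
  IntegerVector cases_above(p), controls_above(p);

  std::vector<std::pair<double, int> > v(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(j, i), static_cast<int>(is_case[i]));
    std::sort(v.begin(), v.end());

    // cutoff above the maximum: empty table, tail probability 1
    double best_p = 1.0;
    double best_cut = v[n - 1].first + 1.0;
    int best_a = 0, best_b = 0;

    // walk boundaries from the largest cutoff downward; strict '<' keeps
    // the largest cutoff on ties
    int a = 0;  // cases strictly above the current boundary
    for (int i = n - 1; i >= 1; --i) {
      a += v[i].second;
      if (v[i].first == v[i - 1].first) continue;
      const int k = n - i;  // total above
      const double pr = ::Rf_phyper(a - 1, n1, n2, k, 0, 0);
      if (pr < best_p) {
        best_p = pr;
        best_cut = 0.5 * (v[i].first + v[i - 1].first);
        best_a = a;
        best_b = k - a;
      }
    }

    pval[j] = best_p;
    cutoff[j] = best_cut;
    cases_above[j] = best_a;
    controls_above[j] = best_b;
  }

  return List::create(_["p_value"] = pval, _["best_cutoff"] = cutoff,
                      _["cases_above"] = cases_above,
                      _["controls_above"] = controls_above);
}
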