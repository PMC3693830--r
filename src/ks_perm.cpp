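#include <Rcpp.h>
using namespace Rcpp;

// One-sided two-sample KS statistic D+ = sup_x [F_ref(x) - F_bg(x)] for a
// pooled, pre-sorted sample. `is_ref` marks reference observations in sorted
// order; `step` marks positions where the sorted value changes (last index of
// each tie group), so the supremum is only read at valid evaluation points.
static double dplus_sorted(const LogicalVector& is_ref,
                           const LogicalVector& step, int m, int n) {
  double cr = 0.0, cb = 0.0, best = 0.0;
  const int N = is_ref.size();
  for (int i = 0; i < N; ++i) {
    if (is_ref[i]) cr += 1.0; else cb += 1.0;
    if (step[i]) {
      double d = cr / m - cb / n;
      if (d > best) best = d;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".ks_dplus_sorted")]]
double ks_dplus_sorted(LogicalVector is_ref, LogicalVector step, int m, int n) {
  return dplus_sorted(is_ref, step, m, n);
}

// Permutation null for D+: B random reassignments of the m reference labels
// across the pooled sorted sample. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export(name = ".ks_dplus_perm")]]
NumericVector ks_dplus_perm(LogicalVector step, int m, int n, int B) {
  const int N = m + n;
  NumericVector out(B);
  std::vector<int> idx(N);
  LogicalVector lab(N);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < N; ++i) { idx[i] = i; lab[i] = FALSE; }
    // partial Fisher-Yates: draw m label positions
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (N - j));
      if (k >= N) k = N - 1;
      std::swap(idx[j], idx[k]);
      lab[idx[j]] = TRUE;
    }
    out[b] = dplus_sorted(lab, step, m, n);
  }
  return out;
}
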