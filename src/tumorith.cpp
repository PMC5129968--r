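#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular-arc two-sample statistic for binary segmentation.
// For every arc of length k (min_bins <= k <= n - min_bins) the statistic
// is |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n-k)); the overall
// noise scale is permutation-invariant and cancels in the permutation
// test, so it is left out here. Wrapped arcs are redundant: a wrapped arc
// is the complement of an unwrapped one and the statistic is symmetric.
static double max_arc_stat(const std::vector<double>& S, int n, int min_bins,
                           int* best_i, int* best_j) {
  double tot = S[n];
  double best = 0.0;
  if (best_i) { *best_i = -1; *best_j = -1; }
  for (int k = min_bins; k <= n - min_bins; ++k) {
    double denom = std::sqrt(1.0 / k + 1.0 / (n - k));
    for (int i = 0; i + k <= n; ++i) {
      double a = S[i + k] - S[i];
      double stat = std::fabs(a / k - (tot - a) / (n - k)) / denom;
      if (stat > best) {
        best = stat;
        if (best_i) { *best_i = i + 1; *best_j = i + k; }
      }
    }
  }
  return best;
}

static std::vector<double> cumsum_of(const NumericVector& x) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  return S;
}

// [[Rcpp::export]]
List cpp_cbs_scan(NumericVector x, int min_bins) {
  int n = x.size();
  if (n < 2 * min_bins) {
    return List::create(_["stat"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  }
  std::vector<double> S = cumsum_of(x);
  int bi, bj;
  double best = max_arc_stat(S, n, min_bins, &bi, &bj);
  return List::create(_["stat"] = best, _["start"] = bi, _["end"] = bj);
}

// Permutation reference distribution of the maximal arc statistic. Uses
// R's RNG so results are governed by set.seed(). Returns the count of
// permutations reaching the observed statistic.
// [[Rcpp::export]]
int cpp_cbs_perm_count(NumericVector x, int min_bins, int n_perm,
                       double observed) {
  int n = x.size();
  std::vector<double> y(x.begin(), x.end());
  int count = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    std::vector<double> S(n + 1, 0.0);
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + y[i];
    double stat = max_arc_stat(S, n, min_bins, nullptr, nullptr);
    if (stat >= observed - 1e-12) ++count;
  }
  return count;
}

static double ks_d_counts(const std::vector<int>& t, const std::vector<int>& u,
                          double n, double m) {
  double ct = 0.0, cu = 0.0, d = 0.0;
  for (size_t k = 0; k < t.size(); ++k) {
    ct += t[k];
    cu += u[k];
    double diff = std::fabs(ct / n - cu / m);
    if (diff > d) d = diff;
  }
  return d;
}

// Permutation p-value for the two-sample KS statistic on integer-valued
// histograms sharing one support vector. Label permutation of the pooled
// reads is drawn as a sequence of hypergeometric splits per support point
// (multivariate hypergeometric), equivalent to shuffling the pooled sample.
// Add-one corrected: p = (1 + #{D* >= D}) / (1 + B).
// [[Rcpp::export]]
double cpp_ks_perm_pvalue(IntegerVector tumor, IntegerVector normal, int B) {
  int K = tumor.size();
  std::vector<int> t(tumor.begin(), tumor.end());
  std::vector<int> u(normal.begin(), normal.end());
  double n = 0.0, m = 0.0;
  std::vector<int> pooled(K);
  for (int k = 0; k < K; ++k) {
    n += t[k];
    m += u[k];
    pooled[k] = t[k] + u[k];
  }
  double d_obs = ks_d_counts(t, u, n, m);
  int count = 0;
  std::vector<int> ts(K), us(K);
  for (int b = 0; b < B; ++b) {
    double remaining_tumor = n;
    double remaining_total = n + m;
    for (int k = 0; k < K; ++k) {
      double white = pooled[k];
      double black = remaining_total - white;
      int x = (remaining_tumor <= 0) ? 0
        : static_cast<int>(R::rhyper(white, black, remaining_tumor));
      ts[k] = x;
      us[k] = pooled[k] - x;
      remaining_tumor -= x;
      remaining_total -= pooled[k];
    }
    if (ks_d_counts(ts, us, n, m) >= d_obs - 1e-12) ++count;
  }
  return (1.0 + count) / (1.0 + B);
}
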