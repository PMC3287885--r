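#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Column-wise affected-individual rank sums with midranks for ties.
// gamma: n x K matrix of per-individual scores, one column per phenotype
// labeling; y: n x K 0/1 matrix of matching labelings. Returns, for each
// column k, sum over {j : y(j,k) == 1} of midrank(gamma(.,k))[j].
// [[Rcpp::export(name = ".case_ranksums")]]
NumericVector case_ranksums(NumericMatrix gamma, NumericMatrix y) {
  const int n = gamma.nrow();
  const int K = gamma.ncol();
  if (y.nrow() != n || y.ncol() != K)
    stop("gamma and y must have identical dimensions");
  NumericVector out(K);
  std::vector<std::pair<double, int> > pairs(n);
  std::vector<double> ranks(n);
  for (int k = 0; k < K; ++k) {
    const double* col = &gamma(0, k);
    for (int j = 0; j < n; ++j) pairs[j] = std::make_pair(col[j], j);
    std::sort(pairs.begin(), pairs.end());
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && pairs[j + 1].first == pairs[i].first) ++j;
      const double mid = 0.5 * (i + j) + 1.0;  // average of ranks i+1..j+1
      for (int t = i; t <= j; ++t) ranks[pairs[t].second] = mid;
      i = j + 1;
    }
    double s = 0.0;
    const double* yk = &y(0, k);
    for (int j2 = 0; j2 < n; ++j2)
      if (yk[j2] > 0.5) s += ranks[j2];
    out[k] = s;
  }
  return out;
}
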