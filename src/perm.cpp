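#include <Rcpp.h>
#include <algorithm>
#include <utility>
#include <vector>
using namespace Rcpp;

// K independent Fisher-Yates permutations of y, one per column, using R's
// RNG stream (reproducible under set.seed).
// [[Rcpp::export(name = ".perm_matrix")]]
IntegerMatrix perm_matrix(IntegerVector y, int K) {
  const int n = y.size();
  IntegerMatrix out(n, K);
  RNGScope scope;
  std::vector<int> v(n);
  for (int k = 0; k < K; ++k) {
    std::copy(y.begin(), y.end(), v.begin());
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(v[i], v[j]);
    }
    std::copy(v.begin(), v.end(), &out(0, k));
  }
  return out;
}
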