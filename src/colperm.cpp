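// Independent random permutation of each column of a matrix (the
// column-permutation null of parallel analysis). Uses R's RNG so results
// are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".col_permute_cpp")]]
NumericMatrix col_permute_cpp(NumericMatrix X) {
  int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  std::vector<int> idx(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    // Fisher-Yates with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(idx[i], idx[k]);
    }
    for (int i = 0; i < n; ++i) out(i, j) = X(idx[i], j);
  }
  return out;
}
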