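#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// distance to the k-th nearest neighbour (excluding self) for every point,
// given a full symmetric distance matrix; nth_element per row
// [[Rcpp::export]]
NumericVector kth_nn_dist_cpp(NumericMatrix dmat, int k) {
  const int n = dmat.nrow();
  NumericVector out(n);
  std::vector<double> row(n - 1);
  for (int i = 0; i < n; ++i) {
    int t = 0;
    for (int j = 0; j < n; ++j) if (j != i) row[t++] = dmat(i, j);
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    out[i] = row[k - 1];
  }
  return out;
}
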