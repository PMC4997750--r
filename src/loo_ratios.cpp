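#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <utility>
using namespace Rcpp;

// Leave-one-out reference-ratio matrix.
//
// D is the nb x nb matrix of squared distances summed over ALL panel
// samples. For held-out sample s, the distance without s is
// D(j, i) - (V(s, i) - V(s, j))^2, so each sample's own noise never
// steers the choice of its reference bins. For every (s, i) the k
// eligible bins with the smallest held-out distance (ties broken by the
// lower bin index, matching order(d, seq_along(d)) on the R side) form
// the reference set, and the returned entry is
// V(s, i) / mean(V(s, ref)).
//
// Eligibility: j != i, eligible[j] (bins on chromosome X are never
// references), and chromId[j] != chromId[i] when excludeSame.
// [[Rcpp::export(name = ".looRatioMatrix")]]
NumericMatrix loo_ratio_matrix(NumericMatrix D, NumericMatrix V,
                               IntegerVector chromId, LogicalVector eligible,
                               int k, bool excludeSame) {
  const int S = V.nrow(), nb = V.ncol();
  NumericMatrix R(S, nb);
  std::vector< std::pair<double, int> > cand;
  cand.reserve(nb);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < nb; ++i) {
      cand.clear();
      const double vi = V(s, i);
      for (int j = 0; j < nb; ++j) {
        if (j == i) continue;
        if (!eligible[j]) continue;
        if (excludeSame && chromId[j] == chromId[i]) continue;
        const double diff = vi - V(s, j);
        cand.push_back(std::make_pair(D(j, i) - diff * diff, j));
      }
      if ((int) cand.size() < k)
        stop("bin %d has only %d eligible reference bins (k = %d)",
             i + 1, (int) cand.size(), k);
      // pair comparison orders ties by the lower bin index
      std::nth_element(cand.begin(), cand.begin() + (k - 1), cand.end());
      double sum = 0.0;
      for (int t = 0; t < k; ++t) sum += V(s, cand[t].second);
      R(s, i) = vi / (sum / k);
    }
  }
  return R;
}
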