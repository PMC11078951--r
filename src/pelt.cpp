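#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// PELT (pruned exact linear time) mean-shift changepoint detection with an
// L2 (sum of squared deviations from the segment mean) cost.
// Returns 1-based indices of the last element of each segment except the
// final one, i.e. a changepoint at k means segments (..., k] and (k, ...].
//
// [[Rcpp::export(name = ".pelt_meanshift")]]
List pelt_meanshift(NumericVector y, double penalty, int min_seg) {
  const int n = y.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + y[i];
    cs2[i + 1] = cs2[i] + y[i] * y[i];
  }
  auto segcost = [&](int s, int t) {
    // cost of segment (s, t], 0-based exclusive/inclusive
    const int m = t - s;
    const double sum = cs[t] - cs[s];
    return (cs2[t] - cs2[s]) - sum * sum / m;
  };

  std::vector<double> F(n + 1, 0.0);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.reserve(256);
  cand.push_back(0);

  for (int t = min_seg; t <= n; ++t) {
    double best = R_PosInf;
    int best_s = 0;
    for (size_t c = 0; c < cand.size(); ++c) {
      const int s = cand[c];
      if (t - s < min_seg) continue;
      const double v = F[s] + segcost(s, t) + penalty;
      if (v < best) {
        best = v;
        best_s = s;
      }
    }
    F[t] = best;
    last[t] = best_s;
    // prune candidates that can never be optimal again
    std::vector<int> keep;
    keep.reserve(cand.size() + 1);
    for (size_t c = 0; c < cand.size(); ++c) {
      const int s = cand[c];
      if (t - s < min_seg || F[s] + segcost(s, t) <= F[t]) keep.push_back(s);
    }
    keep.push_back(t);  // t becomes a candidate start for later ends
    cand.swap(keep);
  }

  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    const int s = last[t];
    if (s > 0) cps.push_back(s);
    t = s;
  }
  std::reverse(cps.begin(), cps.end());
  return List::create(_["changepoints"] = IntegerVector(cps.begin(), cps.end()),
                      _["cost"] = F[n],
                      _["n_cp"] = (int)cps.size());
}
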