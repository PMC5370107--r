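#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Plug-in mutual information (in nats) between two equal-length integer
// series with states in 1..K. The joint distribution is the empirical
// frequency of position-paired states; marginals are the per-series
// empirical frequencies over the same positions.
static double mi_core(const int* x, const int* y, const int L, const int K,
                      std::vector<int>& joint, std::vector<int>& mx,
                      std::vector<int>& my) {
  std::fill(joint.begin(), joint.end(), 0);
  std::fill(mx.begin(), mx.end(), 0);
  std::fill(my.begin(), my.end(), 0);
  for (int t = 0; t < L; ++t) {
    const int a = x[t] - 1, b = y[t] - 1;
    joint[a * K + b]++;
    mx[a]++;
    my[b]++;
  }
  const double dl = static_cast<double>(L);
  double mi = 0.0;
  for (int a = 0; a < K; ++a) {
    if (mx[a] == 0) continue;
    const int* row = &joint[a * K];
    for (int b = 0; b < K; ++b) {
      const int c = row[b];
      if (c > 0)
        mi += (c / dl) *
              std::log((c * dl) / (static_cast<double>(mx[a]) * my[b]));
    }
  }
  // plug-in MI is mathematically >= 0; clamp float rounding only
  if (mi < 0.0 && mi > -1e-12) mi = 0.0;
  return mi;
}

// [[Rcpp::export]]
double cpp_mutual_information(IntegerVector x, IntegerVector y, int K) {
  if (x.size() != y.size())
    stop("series must have equal length");
  const int L = x.size();
  std::vector<int> joint(K * K), mx(K), my(K);
  return mi_core(x.begin(), y.begin(), L, K, joint, mx, my);
}

// Slide the shorter series `s` (length M) along the longer `l` (length N)
// and return the maximum windowed MI (nats) together with the smallest
// 1-based offset attaining it.
// [[Rcpp::export]]
List cpp_max_mutual_information(IntegerVector s, IntegerVector l, int K) {
  const int M = s.size(), N = l.size();
  if (M > N) stop("first series must be the shorter one");
  if (M < 1) stop("series must have length >= 1");
  std::vector<int> joint(K * K), mx(K), my(K);
  double best = -1.0;
  int best_i = 1;
  for (int i = 0; i <= N - M; ++i) {
    const double v = mi_core(s.begin(), l.begin() + i, M, K, joint, mx, my);
    if (v > best) {
      best = v;
      best_i = i + 1;
    }
  }
  return List::create(_["value"] = best, _["offset"] = best_i);
}
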