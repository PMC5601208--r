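#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Penalized-contrast change-point DP: partition y into k = 1..kmax
// segments (each of length >= lmin) minimizing the Gaussian contrast
// sum_s n_s * log(sigma2_s), sigma2_s the within-segment ML variance
// floored at eps. Returns the optimal contrast per k and the segment
// start indices (1-based) of each optimal partition.
// [[Rcpp::export]]
List lavielle_dp(NumericVector y, int kmax, int lmin, double eps) {
  const int n = y.size();
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + y[i];
    s2[i + 1] = s2[i] + y[i] * y[i];
  }
  auto cost = [&](int a, int b) {  // 1-based inclusive [a, b]
    const double len = b - a + 1;
    const double m = (s1[b] - s1[a - 1]) / len;
    double v = (s2[b] - s2[a - 1]) / len - m * m;
    if (v < eps) v = eps;
    return len * std::log(v);
  };
  const double INF = R_PosInf;
  // J[k][j]: best contrast for 1..j split into k segments
  std::vector<std::vector<double> > J(kmax + 1,
                                      std::vector<double>(n + 1, INF));
  std::vector<std::vector<int> > B(kmax + 1, std::vector<int>(n + 1, 0));
  for (int j = lmin; j <= n; ++j) J[1][j] = cost(1, j);
  for (int k = 2; k <= kmax; ++k) {
    for (int j = k * lmin; j <= n; ++j) {
      double best = INF;
      int barg = 0;
      for (int t = (k - 1) * lmin; t <= j - lmin; ++t) {
        if (J[k - 1][t] == INF) continue;
        const double c = J[k - 1][t] + cost(t + 1, j);
        if (c < best) { best = c; barg = t; }
      }
      J[k][j] = best;
      B[k][j] = barg;
    }
  }
  NumericVector contrasts(kmax, NA_REAL);
  List starts(kmax);
  for (int k = 1; k <= kmax; ++k) {
    if (J[k][n] == INF) { starts[k - 1] = R_NilValue; continue; }
    contrasts[k - 1] = J[k][n];
    IntegerVector st(k);
    int j = n;
    for (int kk = k; kk >= 2; --kk) {
      const int t = B[kk][j];
      st[kk - 1] = t + 1;
      j = t;
    }
    st[0] = 1;
    starts[k - 1] = st;
  }
  return List::create(_["contrasts"] = contrasts, _["starts"] = starts);
}
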