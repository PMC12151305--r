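#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Local efficiency per node: global efficiency (mean inverse shortest-path
// distance, lengths 1/weight) of each node's neighborhood-induced subgraph.
// Floyd-Warshall per neighborhood; neighborhoods are small for thresholded
// connectomes so the cubic cost is negligible.
// [[Rcpp::export]]
NumericVector neighborhood_efficiency(NumericMatrix W) {
  const int n = W.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> D;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (W(i, j) > 0) nb.push_back(j);
    const int m = (int) nb.size();
    if (m < 2) { out[i] = 0.0; continue; }
    D.assign((size_t) m * m, INF);
    for (int a = 0; a < m; ++a) {
      D[(size_t) a * m + a] = 0.0;
      for (int b = a + 1; b < m; ++b) {
        double w = W(nb[a], nb[b]);
        if (w > 0) D[(size_t) a * m + b] = D[(size_t) b * m + a] = 1.0 / w;
      }
    }
    for (int k = 0; k < m; ++k)
      for (int a = 0; a < m; ++a) {
        const double dak = D[(size_t) a * m + k];
        if (dak == INF) continue;
        for (int b = 0; b < m; ++b) {
          const double alt = dak + D[(size_t) k * m + b];
          if (alt < D[(size_t) a * m + b]) D[(size_t) a * m + b] = alt;
        }
      }
    double s = 0.0;
    long cnt = 0;
    for (int a = 0; a < m; ++a)
      for (int b = a + 1; b < m; ++b) {
        if (D[(size_t) a * m + b] < INF) s += 1.0 / D[(size_t) a * m + b];
        ++cnt;
      }
    out[i] = s / (double) cnt;
  }
  return out;
}
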