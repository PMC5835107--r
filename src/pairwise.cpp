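#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Streaming accumulation of per-bin (sum of squared fitness differences,
// pair count) over all unordered point pairs.  Pairs are enumerated in
// ascending (i, j), i < j order with plain sequential double addition so
// the per-bin sums are bitwise identical to a nested-loop accumulation in
// R.  Bins are [edge_b, edge_{b+1}) with the final bin closed on both
// ends; pairs beyond the last edge are discarded.  A 200x200 grid gives
// ~8e8 pairs, which is why this lives in C++.

// [[Rcpp::export(name = ".binned_pairs_cpp")]]
List binned_pairs_cpp(NumericMatrix pts, NumericVector fit,
                      NumericVector edges) {
  const int n = pts.nrow();
  const int dim = pts.ncol();
  const int nb = edges.size() - 1;
  if (n != fit.size()) stop("points and fitnesses differ in length");
  if (nb < 1) stop("need at least two bin edges");

  std::vector<double> sum(nb, 0.0);
  std::vector<double> cnt(nb, 0.0);
  const double lo0 = edges[0];
  const double hiN = edges[nb];

  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ss = 0.0;
      for (int d = 0; d < dim; ++d) {
        double diff = pts(i, d) - pts(j, d);
        ss += diff * diff;
      }
      double dist = std::sqrt(ss);
      if (dist < lo0 || dist > hiN) continue;
      int b;
      if (dist == hiN) {
        b = nb - 1; // final bin closed on the right
      } else {
        b = 0;
        while (b < nb - 1 && dist >= edges[b + 1]) ++b;
        if (dist < edges[b] || dist >= edges[b + 1]) continue;
      }
      double fd = fit[i] - fit[j];
      sum[b] += fd * fd;
      cnt[b] += 1.0;
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sum"] = NumericVector(sum.begin(), sum.end()),
                      _["count"] = NumericVector(cnt.begin(), cnt.end()));
}
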