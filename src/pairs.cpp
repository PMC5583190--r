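#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double min_image2(double d, double L) {
  d -= L * std::floor(d / L + 0.5);
  if (d >= L / 2.0) d -= L;
  if (d < -L / 2.0) d += L;
  return d;
}

// Per-bin sums of delta-phi inner products over ordered pairs (i != j) of
// alive agents, using periodic minimum-image distances. Bins are
// [breaks[b], breaks[b+1]); pairs beyond the last break are dropped (the
// last break should be >= L/sqrt(2), the largest possible distance).
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix pos, LogicalVector alive,
                   NumericMatrix dphi, double L, NumericVector breaks) {
  int n = pos.nrow();
  int nb = breaks.size() - 1;
  NumericVector sum(nb);
  NumericVector cnt(nb);
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!alive[j]) continue;
      double dx = min_image2(pos(j, 0) - pos(i, 0), L);
      double dy = min_image2(pos(j, 1) - pos(i, 1), L);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < breaks[0] || d >= breaks[nb]) continue;
      int lo = 0, hi = nb;  // find bin: breaks[lo] <= d < breaks[lo+1]
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (d >= breaks[mid]) lo = mid; else hi = mid;
      }
      double p = dphi(i, 0) * dphi(j, 0) + dphi(i, 1) * dphi(j, 1);
      sum[lo] += 2.0 * p;  // ordered-pair convention
      cnt[lo] += 2.0;
    }
  }
  return List::create(_["sum"] = sum, _["count"] = cnt);
}

// Raw unordered pair distances and inner products, for the exact
// (un-binned) cumulative correlation.
// [[Rcpp::export]]
List cpp_pair_list(NumericMatrix pos, LogicalVector alive,
                   NumericMatrix dphi, double L) {
  int n = pos.nrow();
  long long n_alive = 0;
  for (int i = 0; i < n; ++i) if (alive[i]) ++n_alive;
  long long np = n_alive * (n_alive - 1) / 2;
  NumericVector dist(np), prod(np);
  long long t = 0;
  for (int i = 0; i < n; ++i) {
    if (!alive[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!alive[j]) continue;
      double dx = min_image2(pos(j, 0) - pos(i, 0), L);
      double dy = min_image2(pos(j, 1) - pos(i, 1), L);
      dist[t] = std::sqrt(dx * dx + dy * dy);
      prod[t] = dphi(i, 0) * dphi(j, 0) + dphi(i, 1) * dphi(j, 1);
      ++t;
    }
  }
  return List::create(_["dist"] = dist, _["prod"] = prod);
}
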