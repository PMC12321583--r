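#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tally same-color neighbor pairs into concentric xy-annuli, for the
// observed label assignment and for label-position shuffles.
//
// colors: 0 = unlabeled, 1..K = Confetti colors, attached to positions.
// Each shuffle reassigns the multiset of labels to a uniform random set of
// positions (equivalent to permuting the color vector over positions),
// drawn with R's RNG via a partial Fisher-Yates so a caller-side
// set.seed() makes results reproducible.
//
// Returns an (n_shuffles + 1) x n_bins matrix of total ordered same-color
// pair counts (origin, neighbor) = twice the unordered pair count; row 1
// is the observed assignment, rows 2.. are the shuffles. Bins are
// half-open (lo, hi] on xy-distance.
// [[Rcpp::export]]
IntegerMatrix ring_shuffle_pair_counts(NumericVector x, NumericVector y,
                                       IntegerVector colors,
                                       NumericVector edges,
                                       int n_shuffles) {
  const int n = x.size();
  if (colors.size() != n) stop("x and colors must have equal length");
  if (n_shuffles < 0) stop("n_shuffles must be >= 0");
  const int nb = edges.size() - 1;
  int K = 0;
  for (int i = 0; i < n; ++i) {
    if (colors[i] < 0) stop("colors must be >= 0");
    if (colors[i] > K) K = colors[i];
  }
  std::vector<double> e2(nb + 1);
  for (int b = 0; b <= nb; ++b) e2[b] = edges[b] * edges[b];
  const double rmax2 = e2[nb];

  std::vector<int> lab_col;             // labeled colors, fixed order
  for (int i = 0; i < n; ++i) if (colors[i] > 0) lab_col.push_back(colors[i]);
  const int L = lab_col.size();

  IntegerMatrix out(n_shuffles + 1, nb);
  std::vector<std::vector<int> > members(K + 1);
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[i] = i;
  std::vector<int> swapped(L);

  for (int s = 0; s <= n_shuffles; ++s) {
    for (int c = 1; c <= K; ++c) members[c].clear();
    if (s == 0) {
      for (int i = 0; i < n; ++i)
        if (colors[i] > 0) members[colors[i]].push_back(i);
    } else {
      // assign the label multiset to L uniformly drawn distinct positions
      for (int t = 0; t < L; ++t) {
        const int j = t + (int)R_unif_index(n - t);
        std::swap(pos[t], pos[j]);
        swapped[t] = j;
        members[lab_col[t]].push_back(pos[t]);
      }
      for (int t = L - 1; t >= 0; --t) std::swap(pos[t], pos[swapped[t]]);
    }
    for (int c = 1; c <= K; ++c) {
      const std::vector<int>& m = members[c];
      const int Lc = m.size();
      for (int a = 0; a < Lc; ++a) {
        const double xa = x[m[a]], ya = y[m[a]];
        for (int b = a + 1; b < Lc; ++b) {
          const double dx = x[m[b]] - xa, dy = y[m[b]] - ya;
          const double d2 = dx * dx + dy * dy;
          if (d2 > rmax2 || d2 <= 0.0) continue;
          int bin = -1;
          for (int k = 0; k < nb; ++k) {
            if (d2 > e2[k] && d2 <= e2[k + 1]) { bin = k; break; }
          }
          if (bin >= 0) out(s, bin) += 2;
        }
      }
    }
    if (s % 128 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
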