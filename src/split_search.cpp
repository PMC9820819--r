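#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Best axis-aligned split over numeric attributes for a multi-target
// variance-reduction criterion (sum over target columns of within-node
// sum-of-squares reduction).  Rows with NA in a candidate attribute are
// excluded from both branches, matching the rule semantics where a missing
// measurement means "not described"; the reference sum-of-squares is then
// computed on the same non-NA subset so gains are comparable.
//
// X:    n x p numeric attribute matrix (may contain NA)
// Y:    n x k 0/1 target membership matrix (no NA)
// rows: 0-based indices of the rows in the current node
// cols: 0-based indices of the attributes to scan (mtry subset for forests)
// min_leaf: minimal rows per branch; max_cuts: cap on candidate thresholds
//
// Returns list(attr = 1-based column or 0 if no valid split, threshold,
//              gain, n_left, n_right).
// [[Rcpp::export]]
List best_numeric_split(NumericMatrix X, NumericMatrix Y,
                        IntegerVector rows, IntegerVector cols,
                        int min_leaf, int max_cuts) {
  const int k = Y.ncol();
  int best_attr = -1;
  double best_thr = NA_REAL, best_gain = 0.0;
  int best_nl = 0, best_nr = 0;

  std::vector<std::pair<double, int> > vals;
  std::vector<double> pre((size_t)k, 0.0), tot((size_t)k, 0.0);

  for (int ci = 0; ci < cols.size(); ++ci) {
    const int j = cols[ci];
    vals.clear();
    for (int ri = 0; ri < rows.size(); ++ri) {
      const int r = rows[ri];
      const double v = X(r, j);
      if (!NumericVector::is_na(v)) vals.push_back(std::make_pair(v, r));
    }
    const int m = (int)vals.size();
    if (m < 2 * min_leaf) continue;
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;

    std::fill(tot.begin(), tot.end(), 0.0);
    for (int i = 0; i < m; ++i)
      for (int t = 0; t < k; ++t) tot[t] += Y(vals[i].second, t);
    double base = 0.0;
    for (int t = 0; t < k; ++t) base += tot[t] * tot[t] / m;

    // candidate cut positions: boundaries between distinct values,
    // subsampled to at most max_cuts evenly spaced positions
    std::vector<int> cutpos;
    for (int i = 0; i + 1 < m; ++i)
      if (vals[i].first < vals[i + 1].first) cutpos.push_back(i);
    if ((int)cutpos.size() > max_cuts) {
      std::vector<int> sub;
      const double step = (double)cutpos.size() / max_cuts;
      for (int s = 0; s < max_cuts; ++s)
        sub.push_back(cutpos[(int)(s * step)]);
      sub.erase(std::unique(sub.begin(), sub.end()), sub.end());
      cutpos.swap(sub);
    }
    if (cutpos.empty()) continue;

    std::fill(pre.begin(), pre.end(), 0.0);
    size_t cidx = 0;
    for (int i = 0; i < m && cidx < cutpos.size(); ++i) {
      for (int t = 0; t < k; ++t) pre[t] += Y(vals[i].second, t);
      if (i == cutpos[cidx]) {
        ++cidx;
        const int nl = i + 1, nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double sc = 0.0;
        for (int t = 0; t < k; ++t) {
          const double sl = pre[t], sr = tot[t] - pre[t];
          sc += sl * sl / nl + sr * sr / nr;
        }
        const double gain = sc - base;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_attr = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
          best_nl = nl; best_nr = nr;
        }
      }
    }
  }
  return List::create(_["attr"] = best_attr + 1, _["threshold"] = best_thr,
                      _["gain"] = best_gain, _["n_left"] = best_nl,
                      _["n_right"] = best_nr);
}

// popcount-based intersection sizes between one support column and a
// support matrix are handled in R via crossprod; no kernel needed there.
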