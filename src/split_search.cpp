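#include <Rcpp.h>
using namespace Rcpp;

// Weighted-Gini best split for a single tree node over pre-binned predictors.
//
// B        n x p integer matrix of bin indices (1..n_bins), built once per fit
//          from quantile bin edges of the training data.
// y        length-n integer vector, 0/1 class labels.
// w        length-n double vector of boosting case weights.
// rows     1-based indices of the cases sitting in this node.
// n_bins   number of bins used when B was built.
// min_leaf minimum number of CASES (not weight) allowed in a child.
//
// A split "var j at bin b" sends bin <= b left, bin > b right. Gain is the
// weight-of-node-scaled Gini decrease W*g(node) - W_l*g(left) - W_r*g(right),
// where g = 2 p (1 - p) on the node's weighted class-1 fraction p. Ties are
// broken toward the lowest predictor index, then the lowest bin, so the
// search is deterministic.
//
// [[Rcpp::export]]
List best_split_cpp(const IntegerMatrix& B, const IntegerVector& y,
                    const NumericVector& w, const IntegerVector& rows,
                    int n_bins, int min_leaf) {
  const int p = B.ncol();
  const int m = rows.size();

  double node_w = 0.0, node_w1 = 0.0;
  for (int k = 0; k < m; ++k) {
    const int i = rows[k] - 1;
    node_w += w[i];
    if (y[i] == 1) node_w1 += w[i];
  }
  double best_gain = 0.0;
  int best_var = 0, best_bin = 0;
  if (node_w <= 0.0 || m < 2 * min_leaf)
    return List::create(_["var"] = 0, _["bin"] = 0, _["gain"] = 0.0);

  const double p_node = node_w1 / node_w;
  const double g_node = 2.0 * p_node * (1.0 - p_node);
  const double node_cost = node_w * g_node;
  if (g_node <= 0.0)  // pure node
    return List::create(_["var"] = 0, _["bin"] = 0, _["gain"] = 0.0);

  std::vector<double> wt(n_bins), w1(n_bins);
  std::vector<int> cnt(n_bins);

  for (int j = 0; j < p; ++j) {
    std::fill(wt.begin(), wt.end(), 0.0);
    std::fill(w1.begin(), w1.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int k = 0; k < m; ++k) {
      const int i = rows[k] - 1;
      const int b = B(i, j) - 1;
      wt[b] += w[i];
      if (y[i] == 1) w1[b] += w[i];
      cnt[b] += 1;
    }
    double lw = 0.0, lw1 = 0.0;
    int lc = 0;
    for (int b = 0; b < n_bins - 1; ++b) {
      lw += wt[b];
      lw1 += w1[b];
      lc += cnt[b];
      if (lc < min_leaf || m - lc < min_leaf) continue;
      const double rw = node_w - lw, rw1 = node_w1 - lw1;
      if (lw <= 0.0 || rw <= 0.0) continue;
      const double pl = lw1 / lw, pr = rw1 / rw;
      const double cost = lw * 2.0 * pl * (1.0 - pl) + rw * 2.0 * pr * (1.0 - pr);
      const double gain = node_cost - cost;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_var = j + 1;
        best_bin = b + 1;
      }
    }
  }
  return List::create(_["var"] = best_var, _["bin"] = best_bin,
                      _["gain"] = best_gain);
}
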