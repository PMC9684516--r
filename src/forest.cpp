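#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Classification forest used only for Gini-importance feature ranking.
// Trees are grown to purity (min leaf 1) on bags of floor(bag_frac * n)
// patients drawn without replacement; `mtry` candidate features per split.
// Importance follows the "risk change per branch node" estimate: for each
// tree, the impurity-risk decreases are accumulated per split feature and
// divided by the tree's number of branch nodes, then averaged over trees.
// Randomness comes from R's RNG, so set.seed() upstream fixes the result.

struct TreeGrower {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n_bag;
  int mtry;
  std::vector<double> imp;
  int branch_nodes;

  TreeGrower(const NumericMatrix &X_, const IntegerVector &y_, int n_bag_,
             int mtry_)
      : X(X_), y(y_), n_bag(n_bag_), mtry(mtry_), imp(X_.ncol(), 0.0),
        branch_nodes(0) {}

  static double gini(int n1, int n) {
    if (n == 0) return 0.0;
    const double p1 = (double)n1 / n;
    return 2.0 * p1 * (1.0 - p1);
  }

  void grow(std::vector<int> &idx) {
    const int n = idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    if (n < 2 || n1 == 0 || n1 == n) return;

    const double node_risk = ((double)n / n_bag) * gini(n1, n);
    const int p = X.ncol();
    const int m = std::min(mtry, p);

    // draw m distinct features (partial Fisher-Yates on 0..p-1)
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    for (int j = 0; j < m; ++j) {
      const int k = j + (int)(unif_rand() * (p - j));
      std::swap(feat[j], feat[std::min(k, p - 1)]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx);
    for (int j = 0; j < m; ++j) {
      const int f = feat[j];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      int nl = 0, nl1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        ++nl;
        nl1 += y[ord[k]];
        if (X(ord[k], f) == X(ord[k + 1], f)) continue;
        const double rl = ((double)nl / n_bag) * gini(nl1, nl);
        const double rr = ((double)(n - nl) / n_bag) * gini(n1 - nl1, n - nl);
        const double gain = node_risk - rl - rr;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
        }
      }
    }
    if (best_f < 0) return;

    imp[best_f] += best_gain;
    ++branch_nodes;
    std::vector<int> left, right;
    left.reserve(n);
    right.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? left : right).push_back(i);
    if (left.empty() || right.empty()) return;  // degenerate; should not occur
    grow(left);
    grow(right);
  }
};

// [[Rcpp::export]]
NumericVector rf_gini_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                          int mtry, double bag_fraction) {
  const int n = X.nrow(), p = X.ncol();
  const int n_bag = std::max(2, (int)std::floor(bag_fraction * n));
  NumericVector total(p);
  std::vector<int> pool(n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) pool[i] = i;
    for (int j = 0; j < n_bag; ++j) {
      const int k = j + (int)(unif_rand() * (n - j));
      std::swap(pool[j], pool[std::min(k, n - 1)]);
    }
    std::vector<int> bag(pool.begin(), pool.begin() + n_bag);
    TreeGrower tg(X, y, n_bag, mtry);
    tg.grow(bag);
    if (tg.branch_nodes > 0)
      for (int f = 0; f < p; ++f) total[f] += tg.imp[f] / tg.branch_nodes;
  }
  for (int f = 0; f < p; ++f) total[f] /= n_trees;
  return total;
}
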