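// Compact CART random forest for binary classification.
//
// Gini-impurity splits with per-node feature subsampling (mtry), bootstrap
// bagging, and leaf class-probability averaging across trees. All
// randomness is drawn from R's RNG stream, so set.seed() in R makes a fit
// bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 marks a leaf
  std::vector<double> threshold; // go left iff x[feature] <= threshold
  std::vector<int> left, right;
  std::vector<double> prob;      // positive-class fraction at the node
};

int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi, int depth,
         int mtry, int max_depth, int min_leaf, Tree& tree) {
  const int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];

  const int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.prob.push_back(static_cast<double>(pos) / n);

  if (depth >= max_depth || n < 2 * min_leaf || pos == 0 || pos == n)
    return node;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {  // partial Fisher-Yates via R's RNG
    int k = j + static_cast<int>(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  const double pp = static_cast<double>(pos) / n;
  const double parent = 2.0 * pp * (1.0 - pp);
  double best_gain = 1e-12, best_thr = 0.0;
  int best_f = -1;

  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < m; ++j) {
    const int f = feats[j];
    for (int i = 0; i < n; ++i) {
      const int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), static_cast<int>(y[r]));
    }
    std::sort(vals.begin(), vals.end());
    int ln = 0, lp = 0;
    for (int i = 0; i < n - 1; ++i) {
      ++ln;
      lp += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int rn = n - ln, rp = pos - lp;
      if (ln < min_leaf || rn < min_leaf) continue;
      const double pl = static_cast<double>(lp) / ln;
      const double pr = static_cast<double>(rp) / rn;
      const double child =
          (ln * 2.0 * pl * (1.0 - pl) + rn * 2.0 * pr * (1.0 - pr)) / n;
      const double gain = parent - child;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return node;  // numerically degenerate split

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  const int l = grow(X, y, idx, lo, mid, depth + 1, mtry, max_depth,
                     min_leaf, tree);
  const int r = grow(X, y, idx, mid, hi, depth + 1, mtry, max_depth,
                     min_leaf, tree);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".forest_fit")]]
List forest_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int max_depth, int min_leaf) {
  const int n = X.nrow();
  if (n < 2) stop("need at least two training rows");
  if (mtry < 1 || ntree < 1 || max_depth < 1 || min_leaf < 1)
    stop("forest hyperparameters must be positive");

  List trees(ntree);
  std::vector<int> idx(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {  // bootstrap resample
      int k = static_cast<int>(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Tree tree;
    grow(X, y, idx, 0, n, 0, mtry, max_depth, min_leaf, tree);
    trees[t] = List::create(_["feature"] = wrap(tree.feature),
                            _["threshold"] = wrap(tree.threshold),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["prob"] = wrap(tree.prob));
  }
  return trees;
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    const List tree = forest[t];
    const IntegerVector feature = tree["feature"];
    const NumericVector threshold = tree["threshold"];
    const IntegerVector left = tree["left"];
    const IntegerVector right = tree["right"];
    const NumericVector prob = tree["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += prob[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
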