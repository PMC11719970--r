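// Randomized-tree ensemble (bootstrap + per-split mtry, Gini impurity) used by
// the stage-1 CpG screen. Importances are normalized impurity decreases; a
// probe that is never split on receives an importance of exactly 0.0, which
// the zero-importance filter relies on.
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child node ids, -1 for leaf
  int pred;         // majority class at the node
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0.0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += (c / n) * (c / n);
  return 1.0 - s;
}

int majority_class(const std::vector<double>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = static_cast<int>(k);
  return best;
}

struct TreeGrower {
  const arma::mat& X;
  const arma::ivec& y;
  int n_classes, mtry, min_node;
  std::mt19937_64& rng;
  std::vector<Node> nodes;
  arma::vec& importance; // accumulated weighted impurity decrease (this tree)
  double n_total;

  TreeGrower(const arma::mat& X_, const arma::ivec& y_, int n_classes_,
             int mtry_, int min_node_, std::mt19937_64& rng_, arma::vec& imp_)
      : X(X_), y(y_), n_classes(n_classes_), mtry(mtry_), min_node(min_node_),
        rng(rng_), importance(imp_), n_total(0.0) {}

  // Recursively grow on the index set [lo, hi) of `idx` (reordered in place).
  int grow(std::vector<int>& idx, int lo, int hi) {
    const int n_node = hi - lo;
    std::vector<double> cnt(n_classes, 0.0);
    for (int i = lo; i < hi; ++i) cnt[y[idx[i]]] += 1.0;
    const double imp_parent = gini_from_counts(cnt, n_node);
    const int node_id = static_cast<int>(nodes.size());
    nodes.push_back({-1, 0.0, -1, -1, majority_class(cnt)});
    if (n_node < 2 * min_node || imp_parent <= 0.0) return node_id;

    // sample mtry candidate features without replacement
    const int p = static_cast<int>(X.n_cols);
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    double best_dec = 0.0, best_thr = 0.0;
    int best_feat = -1, best_nl = 0;
    std::vector<int> order(idx.begin() + lo, idx.begin() + hi);
    std::vector<int> best_order;
    std::vector<double> lc(n_classes), rc(n_classes);

    for (int j = 0; j < mtry; ++j) {
      const int f = feats[j];
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        double va = X(a, f), vb = X(b, f);
        if (va != vb) return va < vb;
        return a < b; // deterministic tie-break
      });
      std::fill(lc.begin(), lc.end(), 0.0);
      rc = cnt;
      for (int i = 0; i + 1 < n_node; ++i) {
        const int cls = y[order[i]];
        lc[cls] += 1.0; rc[cls] -= 1.0;
        const double v = X(order[i], f), vn = X(order[i + 1], f);
        if (v >= vn) continue;
        const int nl = i + 1, nr = n_node - nl;
        if (nl < min_node || nr < min_node) continue;
        const double dec = imp_parent -
          (static_cast<double>(nl) / n_node) * gini_from_counts(lc, nl) -
          (static_cast<double>(nr) / n_node) * gini_from_counts(rc, nr);
        if (dec > best_dec + 1e-15) {
          best_dec = dec; best_feat = f;
          best_thr = v + (vn - v) / 2.0;
          best_nl = nl;
          best_order = order;
        }
      }
    }

    if (best_feat < 0) return node_id;
    importance[best_feat] += (n_node / n_total) * best_dec;
    // partition idx[lo, hi) by the chosen split, preserving sorted order
    std::copy(best_order.begin(), best_order.end(), idx.begin() + lo);
    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    const int mid = lo + best_nl;
    nodes[node_id].left = grow(idx, lo, mid);
    nodes[node_id].right = grow(idx, mid, hi);
    return node_id;
  }
};

int predict_tree(const arma::mat& X, int row, const NumericMatrix& tree) {
  int node = 0;
  while (true) {
    const int f = static_cast<int>(tree(node, 0));
    if (f < 0) return static_cast<int>(tree(node, 4));
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
  }
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(const arma::mat& X, const arma::ivec& y, int n_classes,
                int n_trees, int mtry, int min_node, int seed) {
  const int n = static_cast<int>(X.n_rows);
  const int p = static_cast<int>(X.n_cols);
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  arma::vec importance(p, arma::fill::zeros);
  List forest(n_trees);
  std::uniform_int_distribution<int> boot(0, n - 1);
  int n_trees_used = 0;

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    arma::vec tree_imp(p, arma::fill::zeros);
    TreeGrower g(X, y, n_classes, mtry, min_node, rng, tree_imp);
    g.n_total = static_cast<double>(n);
    g.grow(idx, 0, n);
    const double s = arma::accu(tree_imp);
    if (s > 0.0) { importance += tree_imp / s; ++n_trees_used; }
    NumericMatrix tm(static_cast<int>(g.nodes.size()), 5);
    for (size_t i = 0; i < g.nodes.size(); ++i) {
      tm(i, 0) = g.nodes[i].feature;
      tm(i, 1) = g.nodes[i].threshold;
      tm(i, 2) = g.nodes[i].left;
      tm(i, 3) = g.nodes[i].right;
      tm(i, 4) = g.nodes[i].pred;
    }
    forest[t] = tm;
  }
  if (n_trees_used > 0) importance /= static_cast<double>(n_trees_used);
  return List::create(_["importance"] = importance, _["forest"] = forest,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export]]
IntegerVector rf_predict_cpp(List forest, const arma::mat& X, int n_classes) {
  const int n = static_cast<int>(X.n_rows);
  const int n_trees = forest.size();
  IntegerVector out(n);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int t = 0; t < n_trees; ++t) {
      NumericMatrix tm = forest[t];
      ++votes[predict_tree(X, i, tm)];
    }
    int best = 0;
    for (int k = 1; k < n_classes; ++k)
      if (votes[k] > votes[best]) best = k; // ties -> smaller class index
    out[i] = best;
  }
  return out;
}
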