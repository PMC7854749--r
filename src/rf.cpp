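// Random forest of CART trees with Gini impurity and Mean Decrease Impurity
// (MDI) feature importance. Mirrors the classifier configuration used by
// large-scale cropland mapping platforms: numberOfTrees, minLeafPopulation
// (minimum samples allowed in a leaf), variablesPerSplit (mtry, sampled per
// node), bagFraction (per-tree subsample drawn without replacement).
//
// Randomness comes from R's RNG stream (unif_rand), so set.seed() on the R
// side makes training fully reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;      // split feature (0-based), -1 for leaf
  std::vector<double> threshold; // x <= threshold -> left
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> pred;         // majority class at node (0-based)
};

double gini(const std::vector<int> &counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t k = 0; k < counts.size(); ++k) {
    double p = (double)counts[k] / n;
    g -= p * p;
  }
  return g;
}

int majority(const std::vector<int> &counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = (int)k; // tie -> smallest code
  return best;
}

// Sample m distinct integers from 0..(n-1) via partial Fisher-Yates.
void sample_features(std::vector<int> &pool, int m, std::vector<int> &out) {
  int n = (int)pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix &X, const IntegerVector &y, int n_classes,
              int min_leaf, int mtry, std::vector<double> &importance)
      : X_(X), y_(y), K_(n_classes), min_leaf_(min_leaf), mtry_(mtry),
        imp_(importance), pool_(X.ncol()), chosen_(mtry) {
    for (int j = 0; j < X.ncol(); ++j) pool_[j] = j;
  }

  TreeNodes nodes;
  int n_root = 0;

  int build(std::vector<int> &idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> counts(K_, 0);
    for (int i = lo; i < hi; ++i) counts[y_[idx[i]]]++;
    double imp_node = gini(counts, n);

    int id = new_node(majority(counts));
    bool pure = false;
    for (int k = 0; k < K_; ++k)
      if (counts[k] == n) { pure = true; break; }
    if (pure || n < 2 * min_leaf_) return id;

    // best split over mtry features sampled without replacement
    int best_f = -1, best_pos = -1;
    double best_dec = 0.0, best_thr = 0.0;
    sample_features(pool_, mtry_, chosen_);
    std::vector<std::pair<double, int>> v(n);
    std::vector<int> lcounts(K_);
    for (int m = 0; m < mtry_; ++m) {
      int f = chosen_[m];
      for (int i = 0; i < n; ++i)
        v[i] = std::make_pair(X_(idx[lo + i], f), y_[idx[lo + i]]);
      std::sort(v.begin(), v.end());
      std::fill(lcounts.begin(), lcounts.end(), 0);
      int nl = 0;
      // incremental Gini via the sum of squared class counts on each side
      std::vector<int> rcounts(counts);
      double sq_l = 0.0, sq_r = 0.0;
      for (int k = 0; k < K_; ++k) sq_r += (double)counts[k] * counts[k];
      for (int i = 0; i < n - 1; ++i) {
        int cls = v[i].second;
        sq_l += 2.0 * lcounts[cls] + 1.0;
        lcounts[cls]++;
        sq_r -= 2.0 * rcounts[cls] - 1.0;
        rcounts[cls]--;
        nl++;
        int nr = n - nl;
        if (nl < min_leaf_ || nr < min_leaf_) continue;
        if (v[i].first == v[i + 1].first) continue; // not a boundary
        double g_l = 1.0 - sq_l / ((double)nl * nl);
        double g_r = 1.0 - sq_r / ((double)nr * nr);
        double dec = imp_node - (nl * g_l + nr * g_r) / n;
        if (dec > best_dec + 1e-15) {
          best_dec = dec;
          best_f = f;
          best_pos = nl;
          best_thr = 0.5 * (v[i].first + v[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id; // no admissible split

    imp_[best_f] += (double)n / n_root * best_dec;

    // partition idx[lo,hi) in place
    std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                          [&](int i) { return X_(i, best_f) <= best_thr; });
    int mid = lo + best_pos;
    nodes.feature[id] = best_f;
    nodes.threshold[id] = best_thr;
    nodes.left[id] = build(idx, lo, mid);
    nodes.right[id] = build(idx, mid, hi);
    return id;
  }

private:
  int new_node(int pred) {
    nodes.feature.push_back(-1);
    nodes.threshold.push_back(0.0);
    nodes.left.push_back(-1);
    nodes.right.push_back(-1);
    nodes.pred.push_back(pred);
    return (int)nodes.feature.size() - 1;
  }

  const NumericMatrix &X_;
  const IntegerVector &y_;
  int K_, min_leaf_, mtry_;
  std::vector<double> &imp_;
  std::vector<int> pool_, chosen_;
};

} // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                  int n_trees, int min_leaf, int mtry, double bag_fraction) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  int n_bag = (int)std::floor(bag_fraction * n);
  if (n_bag < 1) n_bag = n;

  List trees(n_trees);
  NumericVector importance(p);
  std::vector<double> imp_sum(p, 0.0);
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    // bag: first n_bag of a partial shuffle (without replacement)
    for (int i = 0; i < n_bag; ++i) {
      int j = i + (int)std::floor(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(all[i], all[j]);
    }
    std::vector<int> idx(all.begin(), all.begin() + n_bag);

    std::vector<double> imp_tree(p, 0.0);
    TreeBuilder tb(X, y, n_classes, min_leaf, mtry, imp_tree);
    tb.n_root = n_bag;
    tb.build(idx, 0, (int)idx.size());

    double s = 0.0;
    for (int f = 0; f < p; ++f) s += imp_tree[f];
    if (s > 0)
      for (int f = 0; f < p; ++f) imp_sum[f] += imp_tree[f] / s;

    trees[t] = List::create(
        _["feature"] = IntegerVector(tb.nodes.feature.begin(), tb.nodes.feature.end()),
        _["threshold"] = NumericVector(tb.nodes.threshold.begin(), tb.nodes.threshold.end()),
        _["left"] = IntegerVector(tb.nodes.left.begin(), tb.nodes.left.end()),
        _["right"] = IntegerVector(tb.nodes.right.begin(), tb.nodes.right.end()),
        _["pred"] = IntegerVector(tb.nodes.pred.begin(), tb.nodes.pred.end()));
  }

  double tot = 0.0;
  for (int f = 0; f < p; ++f) tot += imp_sum[f];
  for (int f = 0; f < p; ++f)
    importance[f] = tot > 0 ? imp_sum[f] / tot : 0.0;

  return List::create(_["trees"] = trees, _["importance"] = importance,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int K = as<int>(forest["n_classes"]);
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, K);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;
}
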