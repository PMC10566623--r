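// CART engine: single classification/regression trees plus bagged forests.
// Backs the decision_tree / random_forest / extremely_randomized_trees
// estimators and the boosting wrappers (which fit regression trees to
// gradients in R and recompute leaf values there via tree_apply).
//
// Conventions:
//   - y is numeric; for classification it holds class codes 0..K-1 and
//     n_classes = K > 0; n_classes = 0 means regression.
//   - criterion: 0 = variance (regression), 1 = gini, 2 = entropy.
//   - splitter: 0 = best (exhaustive over thresholds), 1 = random
//     (one uniform threshold per candidate feature, extra-trees style).
//   - max_features: number of features sampled per split (0 = all).
//   - trees are returned as flat arrays; node i is a leaf iff feature[i] < 0.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Grower {
  const NumericMatrix& X;
  const NumericVector& y;
  int n_classes, criterion, max_depth, min_split, min_leaf, max_features,
      splitter;
  std::mt19937 rng;

  std::vector<int> feature, left, right;
  std::vector<double> threshold;
  std::vector<std::vector<double>> value;  // leaf payload (size K or 1)
  std::vector<double> importance;          // impurity decrease * n, per feature

  Grower(const NumericMatrix& X_, const NumericVector& y_, int K, int crit,
         int maxd, int mins, int minl, int mf, int splt, unsigned int seed)
      : X(X_), y(y_), n_classes(K), criterion(crit), max_depth(maxd),
        min_split(mins), min_leaf(minl), max_features(mf), splitter(splt),
        rng(seed), importance(X_.ncol(), 0.0) {}

  // impurity of a set summarised by class counts / moments
  double impurity_counts(const std::vector<double>& cnt, double n) const {
    if (n <= 0) return 0.0;
    if (criterion == 1) {  // gini
      double s = 0;
      for (double c : cnt) { double p = c / n; s += p * p; }
      return 1.0 - s;
    }
    double s = 0;  // entropy
    for (double c : cnt)
      if (c > 0) { double p = c / n; s -= p * std::log2(p); }
    return s;
  }

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(std::vector<double>());
    return (int)feature.size() - 1;
  }

  void make_leaf(int node, const std::vector<int>& idx) {
    std::vector<double>& v = value[node];
    if (n_classes > 0) {
      v.assign(n_classes, 0.0);
      for (int i : idx) v[(int)y[i]] += 1.0;
      for (double& c : v) c /= idx.size();
    } else {
      double m = 0;
      for (int i : idx) m += y[i];
      v.assign(1, m / idx.size());
    }
  }

  // returns node id
  int grow(std::vector<int>& idx, int depth) {
    int node = new_node();
    int n = (int)idx.size();

    double node_imp;
    std::vector<double> cnt;
    double sum = 0, sumsq = 0;
    if (n_classes > 0) {
      cnt.assign(n_classes, 0.0);
      for (int i : idx) cnt[(int)y[i]] += 1.0;
      node_imp = impurity_counts(cnt, n);
    } else {
      for (int i : idx) { sum += y[i]; sumsq += y[i] * y[i]; }
      node_imp = sumsq / n - (sum / n) * (sum / n);  // variance
      if (node_imp < 0) node_imp = 0;
    }

    bool stop = n < min_split || n < 2 * min_leaf || node_imp <= 1e-12 ||
                (max_depth > 0 && depth >= max_depth);
    if (stop) { make_leaf(node, idx); return node; }

    // sample candidate features without replacement
    int p = X.ncol();
    int mtry = (max_features <= 0 || max_features > p) ? p : max_features;
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    if (mtry < p) {
      for (int j = 0; j < mtry; ++j) {
        std::uniform_int_distribution<int> U(j, p - 1);
        std::swap(feats[j], feats[U(rng)]);
      }
      feats.resize(mtry);
    }

    int best_f = -1;
    double best_thr = 0, best_gain = 1e-12;
    // scratch buffers
    std::vector<std::pair<double, int>> sv;

    for (int f : feats) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i : idx) {
        double v = X(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (!(hi > lo)) continue;

      if (splitter == 1) {  // random threshold
        std::uniform_real_distribution<double> U(lo, hi);
        double thr = U(rng);
        double gain = split_gain(idx, f, thr, node_imp, cnt, sum, sumsq);
        if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = thr; }
      } else {              // exhaustive scan over sorted values
        sv.clear();
        sv.reserve(n);
        for (int i : idx) sv.push_back({X(i, f), i});
        std::sort(sv.begin(), sv.end());
        if (n_classes > 0) {
          std::vector<double> lc(n_classes, 0.0);
          for (int k = 0; k < n - 1; ++k) {
            lc[(int)y[sv[k].second]] += 1.0;
            if (sv[k + 1].first <= sv[k].first) continue;  // tied values
            int nl = k + 1, nr = n - nl;
            if (nl < min_leaf || nr < min_leaf) continue;
            std::vector<double> rc(n_classes);
            for (int c = 0; c < n_classes; ++c) rc[c] = cnt[c] - lc[c];
            double gain = node_imp -
              (nl * impurity_counts(lc, nl) + nr * impurity_counts(rc, nr)) / n;
            if (gain > best_gain) {
              best_gain = gain; best_f = f;
              best_thr = sv[k].first + 0.5 * (sv[k + 1].first - sv[k].first);
            }
          }
        } else {
          double ls = 0, lss = 0;
          for (int k = 0; k < n - 1; ++k) {
            double yv = y[sv[k].second];
            ls += yv; lss += yv * yv;
            if (sv[k + 1].first <= sv[k].first) continue;
            int nl = k + 1, nr = n - nl;
            if (nl < min_leaf || nr < min_leaf) continue;
            double rs = sum - ls, rss = sumsq - lss;
            double lvar = lss / nl - (ls / nl) * (ls / nl);
            double rvar = rss / nr - (rs / nr) * (rs / nr);
            double gain = node_imp - (nl * lvar + nr * rvar) / n;
            if (gain > best_gain) {
              best_gain = gain; best_f = f;
              best_thr = sv[k].first + 0.5 * (sv[k + 1].first - sv[k].first);
            }
          }
        }
      }
    }

    if (best_f < 0) { make_leaf(node, idx); return node; }

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if ((int)li.size() < min_leaf || (int)ri.size() < min_leaf) {
      make_leaf(node, idx);
      return node;
    }
    importance[best_f] += best_gain * n;
    feature[node] = best_f;
    threshold[node] = best_thr;
    std::vector<int>().swap(idx);  // release before recursing
    int l = grow(li, depth + 1);
    int r = grow(ri, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }

  // gain of one fixed split (random-splitter path)
  double split_gain(const std::vector<int>& idx, int f, double thr,
                    double node_imp, const std::vector<double>& cnt,
                    double sum, double sumsq) {
    int n = (int)idx.size(), nl = 0;
    if (n_classes > 0) {
      std::vector<double> lc(n_classes, 0.0);
      for (int i : idx)
        if (X(i, f) <= thr) { lc[(int)y[i]] += 1.0; ++nl; }
      int nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) return -1.0;
      std::vector<double> rc(n_classes);
      for (int c = 0; c < n_classes; ++c) rc[c] = cnt[c] - lc[c];
      return node_imp -
             (nl * impurity_counts(lc, nl) + nr * impurity_counts(rc, nr)) / n;
    }
    double ls = 0, lss = 0;
    for (int i : idx)
      if (X(i, f) <= thr) { ls += y[i]; lss += y[i] * y[i]; ++nl; }
    int nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) return -1.0;
    double rs = sum - ls, rss = sumsq - lss;
    double lvar = lss / nl - (ls / nl) * (ls / nl);
    double rvar = rss / nr - (rs / nr) * (rs / nr);
    return node_imp - (nl * lvar + nr * rvar) / n;
  }

  List as_list() const {
    int nn = (int)feature.size();
    int vk = n_classes > 0 ? n_classes : 1;
    NumericMatrix val(nn, vk);
    for (int i = 0; i < nn; ++i)
      if (!value[i].empty())
        for (int k = 0; k < vk; ++k) val(i, k) = value[i][k];
    return List::create(_["feature"] = IntegerVector(feature.begin(), feature.end()),
                        _["threshold"] = NumericVector(threshold.begin(), threshold.end()),
                        _["left"] = IntegerVector(left.begin(), left.end()),
                        _["right"] = IntegerVector(right.begin(), right.end()),
                        _["value"] = val,
                        _["importance"] = NumericVector(importance.begin(), importance.end()));
  }
};

inline int descend(const IntegerVector& feat, const NumericVector& thr,
                   const IntegerVector& lft, const IntegerVector& rgt,
                   const NumericMatrix& X, int i) {
  int node = 0;
  while (feat[node] >= 0)
    node = X(i, feat[node]) <= thr[node] ? lft[node] : rgt[node];
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cart_fit(NumericMatrix X, NumericVector y, int n_classes,
                  int criterion, int max_depth, int min_split, int min_leaf,
                  int max_features, int splitter, int seed) {
  Grower g(X, y, n_classes, criterion, max_depth, min_split, min_leaf,
           max_features, splitter, (unsigned int)seed);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  g.grow(idx, 0);
  return g.as_list();
}

// [[Rcpp::export]]
NumericMatrix cpp_cart_predict(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], lft = tree["left"], rgt = tree["right"];
  NumericVector thr = tree["threshold"];
  NumericMatrix val = tree["value"];
  NumericMatrix out(X.nrow(), val.ncol());
  for (int i = 0; i < X.nrow(); ++i) {
    int node = descend(feat, thr, lft, rgt, X, i);
    for (int k = 0; k < val.ncol(); ++k) out(i, k) = val(node, k);
  }
  return out;
}

// leaf node id per row (for boosting leaf-value recomputation in R)
// [[Rcpp::export]]
IntegerVector cpp_cart_apply(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], lft = tree["left"], rgt = tree["right"];
  NumericVector thr = tree["threshold"];
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = descend(feat, thr, lft, rgt, X, i) + 1;  // 1-based for R
  return out;
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_classes,
                    int n_trees, int criterion, int max_depth, int min_split,
                    int min_leaf, int max_features, int splitter,
                    bool bootstrap, int seed, bool keep_inbag) {
  int n = X.nrow();
  List trees(n_trees);
  NumericVector importance(X.ncol());
  IntegerMatrix inbag = keep_inbag ? IntegerMatrix(n, n_trees)
                                   : IntegerMatrix(0, 0);
  std::mt19937 rng((unsigned int)seed);
  for (int t = 0; t < n_trees; ++t) {
    unsigned int tree_seed = (unsigned int)rng();
    NumericMatrix Xb = X;
    NumericVector yb = y;
    std::vector<int> counts(n, 0);
    if (bootstrap) {
      Xb = NumericMatrix(n, X.ncol());
      yb = NumericVector(n);
      std::uniform_int_distribution<int> U(0, n - 1);
      for (int i = 0; i < n; ++i) {
        int s = U(rng);
        counts[s]++;
        yb[i] = y[s];
        for (int j = 0; j < X.ncol(); ++j) Xb(i, j) = X(s, j);
      }
    } else {
      for (int i = 0; i < n; ++i) counts[i] = 1;
    }
    if (keep_inbag)
      for (int i = 0; i < n; ++i) inbag(i, t) = counts[i];
    Grower g(Xb, yb, n_classes, criterion, max_depth, min_split, min_leaf,
             max_features, splitter, tree_seed);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    g.grow(idx, 0);
    List tr = g.as_list();
    NumericVector imp = tr["importance"];
    for (int j = 0; j < X.ncol(); ++j) importance[j] += imp[j];
    trees[t] = tr;
  }
  for (int j = 0; j < X.ncol(); ++j) importance[j] /= n_trees;
  List out = List::create(_["trees"] = trees, _["importance"] = importance);
  if (keep_inbag) out["inbag"] = inbag;
  return out;
}

// average prediction over trees (class-probability matrix or n x 1 means)
// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List trees, NumericMatrix X, int n_classes) {
  int vk = n_classes > 0 ? n_classes : 1;
  NumericMatrix out(X.nrow(), vk);
  int T = trees.size();
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    IntegerVector feat = tree["feature"], lft = tree["left"], rgt = tree["right"];
    NumericVector thr = tree["threshold"];
    NumericMatrix val = tree["value"];
    for (int i = 0; i < X.nrow(); ++i) {
      int node = descend(feat, thr, lft, rgt, X, i);
      for (int k = 0; k < vk; ++k) out(i, k) += val(node, k);
    }
  }
  for (int i = 0; i < out.nrow(); ++i)
    for (int k = 0; k < vk; ++k) out(i, k) /= T;
  return out;
}
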