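#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
using namespace Rcpp;

// CART-style trees for the in-package random forest and gradient-boosted
// ensembles. Trees are serialized as numeric matrices, one row per node:
//   col 0 feature (0-based; -1 => leaf), col 1 threshold (go left if x <= thr),
//   col 2 left child row, col 3 right child row (0-based), col 4 leaf value.
// Classification leaves store P(class 1); boosting leaves store the Newton
// step value added to the raw score.

struct TreeBuf {
  std::vector<double> feat, thr, left, right, val;
  int add(double f, double t, double l, double r, double v) {
    feat.push_back(f); thr.push_back(t); left.push_back(l);
    right.push_back(r); val.push_back(v);
    return (int)feat.size() - 1;
  }
  NumericMatrix to_matrix() const {
    int n = (int)feat.size();
    NumericMatrix m(n, 5);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = feat[i]; m(i, 1) = thr[i]; m(i, 2) = left[i];
      m(i, 3) = right[i]; m(i, 4) = val[i];
    }
    return m;
  }
};

static double tree_predict_row(const NumericMatrix &tree, const NumericMatrix &X,
                               int row) {
  int node = 0;
  while (true) {
    int f = (int)tree(node, 0);
    if (f < 0) return tree(node, 4);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
}

// ---------- classification tree (gini) ----------

struct ClsBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, min_node, max_depth;
  std::mt19937 &rng;
  TreeBuf buf;
  std::vector<double> &importance;  // gini decrease accumulator, length p

  ClsBuilder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
             int min_node_, int max_depth_, std::mt19937 &rng_,
             std::vector<double> &imp_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_), importance(imp_) {}

  static double gini(double n1, double n) {
    if (n <= 0) return 0.0;
    double p = n1 / n;
    return 2.0 * p * (1.0 - p);
  }

  int build(std::vector<int> &idx, int depth) {
    double n = (double)idx.size(), n1 = 0;
    for (size_t i = 0; i < idx.size(); ++i) n1 += y[idx[i]];
    double node_gini = gini(n1, n);
    bool pure = (n1 == 0 || n1 == n);
    if (depth >= max_depth || (int)n < min_node || pure)
      return buf.add(-1, 0, -1, -1, n1 / n);

    // sample mtry candidate features without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);

    int best_f = -1;
    double best_gain = 1e-12, best_thr = 0;
    std::vector<std::pair<double, int> > vals(idx.size());
    for (int jj = 0; jj < std::min(mtry, p); ++jj) {
      int f = feats[jj];
      for (size_t i = 0; i < idx.size(); ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      double ln = 0, l1 = 0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        ln += 1; l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double rn = n - ln, r1 = n1 - l1;
        double gain = node_gini - (ln / n) * gini(l1, ln) - (rn / n) * gini(r1, rn);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return buf.add(-1, 0, -1, -1, n1 / n);

    importance[best_f] += best_gain * n;
    std::vector<int> li, ri;
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    int self = buf.add(best_f, best_thr, -1, -1, n1 / n);
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    buf.left[self] = l;
    buf.right[self] = r;
    return self;
  }
};

// [[Rcpp::export(name = ".rf_train")]]
List rf_train(NumericMatrix X, IntegerVector y, int ntree, int mtry,
              int min_node, int max_depth, int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    ClsBuilder b(X, y, mtry, min_node, max_depth, rng, importance);
    b.build(idx, 0);
    trees[t] = b.buf.to_matrix();
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}

// ---------- gradient boosting (second-order, log loss) ----------

struct RegBuilder {
  const NumericMatrix &X;
  const std::vector<double> &g, &h;
  double lambda;
  int min_child, max_depth;
  TreeBuf buf;

  RegBuilder(const NumericMatrix &X_, const std::vector<double> &g_,
             const std::vector<double> &h_, double lambda_, int min_child_,
             int max_depth_)
      : X(X_), g(g_), h(h_), lambda(lambda_), min_child(min_child_),
        max_depth(max_depth_) {}

  double leaf_value(double gs, double hs) { return -gs / (hs + lambda); }
  double score(double gs, double hs) { return gs * gs / (hs + lambda); }

  int build(std::vector<int> &idx, int depth) {
    double gs = 0, hs = 0;
    for (size_t i = 0; i < idx.size(); ++i) { gs += g[idx[i]]; hs += h[idx[i]]; }
    if (depth >= max_depth || (int)idx.size() < 2 * min_child)
      return buf.add(-1, 0, -1, -1, leaf_value(gs, hs));

    int p = X.ncol(), best_f = -1;
    double parent = score(gs, hs), best_gain = 1e-12, best_thr = 0;
    std::vector<std::pair<double, int> > vals(idx.size());
    for (int f = 0; f < p; ++f) {
      for (size_t i = 0; i < idx.size(); ++i)
        vals[i] = std::make_pair(X(idx[i], f), idx[i]);
      std::sort(vals.begin(), vals.end());
      double lg = 0, lh = 0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        lg += g[vals[i].second]; lh += h[vals[i].second];
        if ((int)i + 1 < min_child || (int)(idx.size() - i - 1) < min_child)
          continue;
        if (vals[i].first == vals[i + 1].first) continue;
        double gain = 0.5 * (score(lg, lh) + score(gs - lg, hs - lh) - parent);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return buf.add(-1, 0, -1, -1, leaf_value(gs, hs));

    std::vector<int> li, ri;
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    int self = buf.add(best_f, best_thr, -1, -1, 0);
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    buf.left[self] = l;
    buf.right[self] = r;
    return self;
  }
};

// [[Rcpp::export(name = ".gbt_train")]]
List gbt_train(NumericMatrix X, IntegerVector y, int nrounds, double eta,
               int max_depth, int min_child, double lambda, double subsample,
               int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double ybar = 0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double base = std::log(ybar / (1.0 - ybar));
  std::vector<double> raw(n, base), g(n), h(n);
  List trees(nrounds);
  for (int t = 0; t < nrounds; ++t) {
    std::vector<int> idx;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-raw[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-12);
      if (subsample >= 1.0 || unif(rng) < subsample) idx.push_back(i);
    }
    if (idx.empty()) for (int i = 0; i < n; ++i) idx.push_back(i);
    RegBuilder b(X, g, h, lambda, min_child, max_depth);
    b.build(idx, 0);
    NumericMatrix tree = b.buf.to_matrix();
    trees[t] = tree;
    for (int i = 0; i < n; ++i) raw[i] += eta * tree_predict_row(tree, X, i);
  }
  return List::create(_["trees"] = trees, _["base"] = base, _["eta"] = eta);
}

// [[Rcpp::export(name = ".gbt_predict")]]
NumericVector gbt_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  double base = as<double>(model["base"]), eta = as<double>(model["eta"]);
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = base;
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += eta * tree_predict_row(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
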