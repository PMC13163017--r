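// Flat CART engine shared by the tree-ensemble model families.
//
// One grown tree is returned to R as parallel node arrays (feature index,
// threshold, child ids, leaf payload) plus a per-feature impurity-gain
// accumulator. Classification trees minimize weighted Gini, regression trees
// weighted SSE. `extra = true` switches split search to the Extra-Trees rule
// (one uniform random threshold per candidate feature). All randomness goes
// through R's RNG so seeds set from R control tree growth.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grower {
  const double* X;
  int n, p;
  const int* yc;        // classification targets 0..K-1 (or NULL)
  const double* yr;     // regression targets (or NULL)
  const double* w;      // observation weights
  bool classif;
  int K;
  int max_depth, min_split, min_leaf, mtry;
  bool extra;

  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<double> leaf;   // nodes x K (classif) or nodes x 1 (regression)
  std::vector<double> gain;   // per-feature impurity decrease
  int leaf_width;

  double xv(int i, int j) const { return X[(size_t)i + (size_t)n * j]; }

  // weighted Gini "impurity mass": wsum - sum_k wk^2 / wsum
  double gini_mass(const std::vector<double>& wk, double wsum) const {
    if (wsum <= 0) return 0.0;
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += wk[k] * wk[k];
    return wsum - s / wsum;
  }

  int new_node() {
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    for (int k = 0; k < leaf_width; ++k) leaf.push_back(0.0);
    return (int)feat.size() - 1;
  }

  void set_leaf(int node, const std::vector<int>& idx) {
    if (classif) {
      std::vector<double> wk(K, 0.0);
      double wsum = 0.0;
      for (int i : idx) { wk[yc[i]] += w[i]; wsum += w[i]; }
      for (int k = 0; k < K; ++k)
        leaf[(size_t)node * K + k] = wsum > 0 ? wk[k] / wsum : 1.0 / K;
    } else {
      double sw = 0.0, swy = 0.0;
      for (int i : idx) { sw += w[i]; swy += w[i] * yr[i]; }
      leaf[node] = sw > 0 ? swy / sw : 0.0;
    }
  }

  // sample `mtry` distinct feature indices via partial Fisher-Yates
  void sample_features(std::vector<int>& pool) {
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int r = j + (int)std::floor(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(pool[j], pool[r]);
    }
  }

  bool best_split(const std::vector<int>& idx, int& bf, double& bt, double& bg) {
    bf = -1; bg = 1e-12;
    int nn = (int)idx.size();

    double wsum = 0.0, swy = 0.0, swy2 = 0.0;
    std::vector<double> wk;
    double parent;
    if (classif) {
      wk.assign(K, 0.0);
      for (int i : idx) { wk[yc[i]] += w[i]; wsum += w[i]; }
      parent = gini_mass(wk, wsum);
    } else {
      for (int i : idx) { wsum += w[i]; swy += w[i] * yr[i]; swy2 += w[i] * yr[i] * yr[i]; }
      parent = swy2 - (wsum > 0 ? swy * swy / wsum : 0.0);
    }
    if (parent <= 1e-12) return false;

    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    sample_features(pool);
    int m = std::min(mtry, p);

    std::vector<int> ord;
    std::vector<double> lk(classif ? K : 0);

    for (int jj = 0; jj < m; ++jj) {
      int j = pool[jj];

      if (extra) {
        double lo = R_PosInf, hi = R_NegInf;
        for (int i : idx) { double v = xv(i, j); lo = std::min(lo, v); hi = std::max(hi, v); }
        if (!(hi > lo)) continue;
        double t = lo + unif_rand() * (hi - lo);
        double lw = 0.0, lswy = 0.0, lswy2 = 0.0;
        int lcnt = 0;
        if (classif) std::fill(lk.begin(), lk.end(), 0.0);
        for (int i : idx) {
          if (xv(i, j) <= t) {
            ++lcnt; lw += w[i];
            if (classif) lk[yc[i]] += w[i];
            else { lswy += w[i] * yr[i]; lswy2 += w[i] * yr[i] * yr[i]; }
          }
        }
        if (lcnt < min_leaf || nn - lcnt < min_leaf) continue;
        double g;
        if (classif) {
          std::vector<double> rk(K);
          for (int k = 0; k < K; ++k) rk[k] = wk[k] - lk[k];
          g = parent - gini_mass(lk, lw) - gini_mass(rk, wsum - lw);
        } else {
          double rw = wsum - lw, rswy = swy - lswy, rswy2 = swy2 - lswy2;
          double sl = lswy2 - (lw > 0 ? lswy * lswy / lw : 0.0);
          double sr = rswy2 - (rw > 0 ? rswy * rswy / rw : 0.0);
          g = parent - sl - sr;
        }
        if (g > bg) { bg = g; bf = j; bt = t; }
        continue;
      }

      ord.assign(idx.begin(), idx.end());
      const double* Xj = X + (size_t)n * j;
      std::sort(ord.begin(), ord.end(),
                [Xj](int a, int b) { return Xj[a] < Xj[b]; });
      if (Xj[ord.front()] == Xj[ord.back()]) continue;

      double lw = 0.0, lswy = 0.0, lswy2 = 0.0;
      if (classif) std::fill(lk.begin(), lk.end(), 0.0);
      for (int q = 0; q < nn - 1; ++q) {
        int i = ord[q];
        lw += w[i];
        if (classif) lk[yc[i]] += w[i];
        else { lswy += w[i] * yr[i]; lswy2 += w[i] * yr[i] * yr[i]; }
        if (Xj[i] == Xj[ord[q + 1]]) continue;           // no cut inside ties
        if (q + 1 < min_leaf || nn - q - 1 < min_leaf) continue;
        double g;
        if (classif) {
          std::vector<double> rk(K);
          for (int k = 0; k < K; ++k) rk[k] = wk[k] - lk[k];
          g = parent - gini_mass(lk, lw) - gini_mass(rk, wsum - lw);
        } else {
          double rw = wsum - lw, rswy = swy - lswy, rswy2 = swy2 - lswy2;
          double sl = lswy2 - (lw > 0 ? lswy * lswy / lw : 0.0);
          double sr = rswy2 - (rw > 0 ? rswy * rswy / rw : 0.0);
          g = parent - sl - sr;
        }
        if (g > bg) {
          bg = g; bf = j;
          bt = 0.5 * (Xj[i] + Xj[ord[q + 1]]);
        }
      }
    }
    return bf >= 0;
  }

  int grow(std::vector<int>& idx, int depth) {
    int node = new_node();
    bool pure = true;
    if (classif) {
      for (size_t q = 1; q < idx.size(); ++q)
        if (yc[idx[q]] != yc[idx[0]]) { pure = false; break; }
    } else {
      for (size_t q = 1; q < idx.size(); ++q)
        if (yr[idx[q]] != yr[idx[0]]) { pure = false; break; }
    }
    if (pure || (int)idx.size() < min_split || depth >= max_depth) {
      set_leaf(node, idx);
      return node;
    }
    int bf; double bt, bg;
    if (!best_split(idx, bf, bt, bg)) {
      set_leaf(node, idx);
      return node;
    }
    std::vector<int> li, ri;
    for (int i : idx) (xv(i, bf) <= bt ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) { set_leaf(node, idx); return node; }
    gain[bf] += bg;
    feat[node] = bf;
    thr[node] = bt;
    { std::vector<int>().swap(idx); }   // free before recursing
    left[node] = grow(li, depth + 1);
    right[node] = grow(ri, depth + 1);
    return node;
  }
};

int descend(const IntegerVector& feat, const NumericVector& thr,
            const IntegerVector& left, const IntegerVector& right,
            const double* X, int n, int i) {
  int node = 0;
  while (feat[node] >= 0) {
    double v = X[(size_t)i + (size_t)n * feat[node]];
    node = (v <= thr[node]) ? left[node] : right[node];
  }
  return node;
}

} // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y_class, NumericVector y_reg,
                   NumericVector w, bool classif, int n_class,
                   IntegerVector rows, int max_depth, int min_split,
                   int min_leaf, int mtry, bool extra) {
  Grower g;
  g.X = REAL(X); g.n = X.nrow(); g.p = X.ncol();
  g.yc = classif ? INTEGER(y_class) : nullptr;
  g.yr = classif ? nullptr : REAL(y_reg);
  g.w = REAL(w);
  g.classif = classif; g.K = n_class;
  g.max_depth = max_depth; g.min_split = min_split;
  g.min_leaf = min_leaf; g.mtry = mtry; g.extra = extra;
  g.leaf_width = classif ? n_class : 1;
  g.gain.assign(g.p, 0.0);

  std::vector<int> idx(rows.begin(), rows.end());
  g.grow(idx, 0);

  int nn = (int)g.feat.size();
  NumericMatrix leaf(nn, g.leaf_width);
  for (int node = 0; node < nn; ++node)
    for (int k = 0; k < g.leaf_width; ++k)
      leaf(node, k) = g.leaf[(size_t)node * g.leaf_width + k];

  return List::create(
    _["feature"] = IntegerVector(g.feat.begin(), g.feat.end()),
    _["threshold"] = NumericVector(g.thr.begin(), g.thr.end()),
    _["left"] = IntegerVector(g.left.begin(), g.left.end()),
    _["right"] = IntegerVector(g.right.begin(), g.right.end()),
    _["leaf"] = leaf,
    _["gain"] = NumericVector(g.gain.begin(), g.gain.end()));
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericMatrix predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"];
  NumericMatrix leaf = tree["leaf"];
  int n = X.nrow(), K = leaf.ncol();
  NumericMatrix out(n, K);
  const double* xp = REAL(X);
  for (int i = 0; i < n; ++i) {
    int node = descend(feat, thr, left, right, xp, n, i);
    for (int k = 0; k < K; ++k) out(i, k) = leaf(node, k);
  }
  return out;
}

// [[Rcpp::export(name = ".tree_leaf_ids_cpp")]]
IntegerVector tree_leaf_ids_cpp(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  const double* xp = REAL(X);
  for (int i = 0; i < n; ++i)
    out[i] = descend(feat, thr, left, right, xp, n, i);
  return out;
}
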