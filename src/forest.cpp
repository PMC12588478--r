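// Compact CART / Random-Forest engine for case-control classification.
//
// The forest grows fully deterministic trees given a seed: bootstrap rows,
// draw `mtry` candidate features per node, pick the split maximising the
// Gini decrease (strictly-better wins, earliest candidate on ties), and
// store the class-1 fraction at each leaf.  Prediction is by tree vote
// (leaf fraction > 0.5 votes class 1; an exact 0.5 leaf votes class 0),
// and the returned score is the fraction of trees voting class 1.
// Importance is the mean (over trees) weighted Gini impurity decrease.
//
// All randomness comes from one std::mt19937_64 seeded from R, so results
// are reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeNodes {
  std::vector<int> feature;  // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;  // class-1 fraction of node samples
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p;
  int minSplit;
  int maxDepth;
  std::mt19937_64& rng;
  std::vector<int> idx;    // bootstrap sample indices, partitioned in place
  std::vector<int> perm;   // feature permutation buffer
  std::vector<double>& imp;
  int nBoot;
  TreeNodes t;
  int mtry;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int minSplit_, int maxDepth_, std::mt19937_64& rng_,
         std::vector<double>& imp_)
      : X(X_), y(y_), p(X_.ncol()), minSplit(minSplit_), maxDepth(maxDepth_),
        rng(rng_), imp(imp_), mtry(mtry_) {
    perm.resize(p);
    for (int j = 0; j < p; ++j) perm[j] = j;
  }

  int newNode() {
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.value.push_back(0.0);
    return (int)t.feature.size() - 1;
  }

  int grow(int lo, int hi, int depth) {
    int id = newNode();
    int n = hi - lo;
    int c1 = 0;
    for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
    t.value[id] = (double)c1 / n;
    if (c1 == 0 || c1 == n || n < minSplit || depth >= maxDepth) return id;

    double base = ((double)c1 * c1 + (double)(n - c1) * (n - c1)) / n;
    double bestImp = 1e-12;
    int bestF = -1;
    double bestThr = 0.0;

    // partial Fisher-Yates draw of mtry candidate features
    int m = std::min(mtry, p);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(rng() % (uint64_t)(p - i));
      std::swap(perm[i], perm[j]);
    }

    std::vector<std::pair<double, int> > vals(n);
    for (int c = 0; c < m; ++c) {
      int f = perm[c];
      for (int i = 0; i < n; ++i) {
        int s = idx[lo + i];
        vals[i] = std::make_pair(X(s, f), s);
      }
      std::sort(vals.begin(), vals.end());
      int n1L = 0;
      for (int i = 0; i < n - 1; ++i) {
        n1L += y[vals[i].second];
        if (vals[i].first < vals[i + 1].first) {
          int nL = i + 1, nR = n - nL;
          int n1R = c1 - n1L;
          double score =
              ((double)n1L * n1L + (double)(nL - n1L) * (nL - n1L)) / nL +
              ((double)n1R * n1R + (double)(nR - n1R) * (nR - n1R)) / nR;
          double gain = score - base;
          if (gain > bestImp) {
            bestImp = gain;
            bestF = f;
            bestThr = (vals[i].first + vals[i + 1].first) / 2.0;
          }
        }
      }
    }
    if (bestF < 0) return id;

    imp[bestF] += bestImp / nBoot;
    t.feature[id] = bestF;
    t.threshold[id] = bestThr;
    const NumericMatrix& Xr = X;
    int f = bestF;
    double thr = bestThr;
    std::vector<int>::iterator mid = std::stable_partition(
        idx.begin() + lo, idx.begin() + hi,
        [&Xr, f, thr](int s) { return Xr(s, f) <= thr; });
    int cut = (int)(mid - idx.begin());
    // a midpoint split always separates at least one sample on each side
    t.left[id] = grow(lo, cut, depth + 1);
    t.right[id] = grow(cut, hi, depth + 1);
    return id;
  }
};

double treeVote(const IntegerVector& feature, const NumericVector& threshold,
                const IntegerVector& left, const IntegerVector& right,
                const NumericVector& value, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return value[node] > 0.5 ? 1.0 : 0.0;
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                  int minSplit, int maxDepth, double seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<double> imp(p, 0.0);
  List trees(ntree);

  for (int tr = 0; tr < ntree; ++tr) {
    Grower g(X, y, mtry, minSplit, maxDepth, rng, imp);
    g.idx.resize(n);
    for (int i = 0; i < n; ++i) g.idx[i] = (int)(rng() % (uint64_t)n);
    g.nBoot = n;
    g.grow(0, n, 0);
    trees[tr] = List::create(
        Named("feature") = IntegerVector(g.t.feature.begin(), g.t.feature.end()),
        Named("threshold") = NumericVector(g.t.threshold.begin(), g.t.threshold.end()),
        Named("left") = IntegerVector(g.t.left.begin(), g.t.left.end()),
        Named("right") = IntegerVector(g.t.right.begin(), g.t.right.end()),
        Named("value") = NumericVector(g.t.value.begin(), g.t.value.end()));
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;
  return List::create(Named("trees") = trees, Named("importance") = importance);
}

// Fraction of trees voting class 1, per row of X.
// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int m = X.nrow();
  int ntree = trees.size();
  NumericVector out(m);
  for (int tr = 0; tr < ntree; ++tr) {
    List t = trees[tr];
    IntegerVector feature = t["feature"];
    NumericVector threshold = t["threshold"];
    IntegerVector left = t["left"], right = t["right"];
    NumericVector value = t["value"];
    for (int i = 0; i < m; ++i)
      out[i] += treeVote(feature, threshold, left, right, value, X, i);
  }
  for (int i = 0; i < m; ++i) out[i] /= ntree;
  return out;
}
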