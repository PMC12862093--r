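// CART forest with Gini-gain (classification) or variance-gain
// (regression) splits and per-feature accumulated impurity decrease.
// Splits maximize the count-weighted impurity decrease
//   gain = I(parent) - (n_l/n) I(left) - (n_r/n) I(right),
// thresholds are midpoints between distinct consecutive feature
// values. On exactly tied gains the first candidate encountered wins:
// candidates are scanned in the drawn feature order (the natural
// order when mtry >= p, so single-tree fits are fully deterministic)
// and by increasing threshold, which keeps ties unbiased across
// features inside the forest. Importance accumulates each split gain
// weighted by the node sample fraction n_node/n, the standard forest
// importance accumulation, over all nodes and trees. Uses R RNG so
// results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // node indices, -1 for leaf
  double pred;      // class index (0-based) or mean
};

struct Problem {
  const NumericMatrix& x;
  const NumericVector& y;   // class index as double, or response
  int nClass;               // 0 => regression
  int mtry, minLeaf, maxDepth;
  int nTotal;               // tree sample size (node-fraction weights)
  std::vector<double>& importance;
  std::vector<Node>& nodes;
};

double impurityCounts(const std::vector<double>& cnt, double n) {
  double s = 0.0;
  for (double c : cnt) { double p = c / n; s += p * p; }
  return 1.0 - s;
}

// variance impurity from sufficient statistics
double impurityVar(double sum, double sum2, double n) {
  double m = sum / n;
  double v = sum2 / n - m * m;
  return v > 0 ? v : 0.0;
}

int growNode(Problem& pb, std::vector<int>& idx, int depth) {
  const int n = (int)idx.size();
  const int p = pb.x.ncol();
  const bool classify = pb.nClass > 0;

  std::vector<double> cnt;
  double sum = 0.0, sum2 = 0.0, parentImp;
  if (classify) {
    cnt.assign(pb.nClass, 0.0);
    for (int i : idx) cnt[(int)pb.y[i]] += 1.0;
    parentImp = impurityCounts(cnt, n);
  } else {
    for (int i : idx) { sum += pb.y[i]; sum2 += pb.y[i] * pb.y[i]; }
    parentImp = impurityVar(sum, sum2, n);
  }

  auto makeLeaf = [&]() -> int {
    Node nd; nd.feature = -1; nd.threshold = 0.0; nd.left = nd.right = -1;
    if (classify) {
      int best = 0;
      for (int k = 1; k < pb.nClass; ++k) if (cnt[k] > cnt[best]) best = k;
      nd.pred = best;
    } else nd.pred = sum / n;
    pb.nodes.push_back(nd);
    return (int)pb.nodes.size() - 1;
  };

  if (n < 2 * pb.minLeaf || parentImp <= 1e-15 ||
      (pb.maxDepth > 0 && depth >= pb.maxDepth))
    return makeLeaf();

  // draw mtry candidate features without replacement (partial
  // shuffle); natural order when all features are tried
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = pb.mtry < p ? pb.mtry : p;
  if (m < p) {
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
  }

  double bestGain = 0.0, bestThr = 0.0;
  int bestFeat = -1;
  std::vector<std::pair<double, int> > vals(n);

  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    for (int t = 0; t < n; ++t)
      vals[t] = std::make_pair(pb.x(idx[t], f), idx[t]);
    std::sort(vals.begin(), vals.end());

    std::vector<double> lcnt;
    double lsum = 0.0, lsum2 = 0.0;
    if (classify) lcnt.assign(pb.nClass, 0.0);

    for (int t = 0; t < n - 1; ++t) {
      const int i = vals[t].second;
      if (classify) lcnt[(int)pb.y[i]] += 1.0;
      else { lsum += pb.y[i]; lsum2 += pb.y[i] * pb.y[i]; }
      if (vals[t + 1].first <= vals[t].first) continue;  // no cut here
      const int nl = t + 1, nr = n - nl;
      if (nl < pb.minLeaf || nr < pb.minLeaf) continue;
      double li, ri;
      if (classify) {
        li = impurityCounts(lcnt, nl);
        std::vector<double> rcnt(pb.nClass);
        for (int k = 0; k < pb.nClass; ++k) rcnt[k] = cnt[k] - lcnt[k];
        ri = impurityCounts(rcnt, nr);
      } else {
        li = impurityVar(lsum, lsum2, nl);
        ri = impurityVar(sum - lsum, sum2 - lsum2, nr);
      }
      const double gain =
        parentImp - ((double)nl / n) * li - ((double)nr / n) * ri;
      const double thr = 0.5 * (vals[t].first + vals[t + 1].first);
      const double eps = 1e-12;
      if (gain > bestGain + eps && gain > eps) {
        bestGain = gain; bestFeat = f; bestThr = thr;
      }
    }
  }

  if (bestFeat < 0) return makeLeaf();

  std::vector<int> lidx, ridx;
  lidx.reserve(n); ridx.reserve(n);
  for (int i : idx)
    (pb.x(i, bestFeat) <= bestThr ? lidx : ridx).push_back(i);
  pb.importance[bestFeat] += bestGain * (double)n / pb.nTotal;

  Node nd; nd.feature = bestFeat; nd.threshold = bestThr; nd.pred = 0.0;
  pb.nodes.push_back(nd);
  int self = (int)pb.nodes.size() - 1;
  int l = growNode(pb, lidx, depth + 1);
  int r = growNode(pb, ridx, depth + 1);
  pb.nodes[self].left = l;
  pb.nodes[self].right = r;
  return self;
}

} // namespace

// [[Rcpp::export(name = ".cppGiniForest")]]
List cppGiniForest(NumericMatrix x, NumericVector y, int nClass,
                   int nTrees, int mtry, int minLeaf, int maxDepth,
                   bool bootstrap) {
  const int n = x.nrow(), p = x.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(nTrees);
  RNGScope scope;
  for (int tr = 0; tr < nTrees; ++tr) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int k = (int)(unif_rand() * n);
        idx[i] = k < n ? k : n - 1;
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    std::vector<Node> nodes;
    Problem pb{x, y, nClass, mtry, minLeaf, maxDepth, n, importance,
               nodes};
    growNode(pb, idx, 0);
    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t q = 0; q < nodes.size(); ++q) {
      tm(q, 0) = nodes[q].feature;
      tm(q, 1) = nodes[q].threshold;
      tm(q, 2) = nodes[q].left;
      tm(q, 3) = nodes[q].right;
      tm(q, 4) = nodes[q].pred;
    }
    trees[tr] = tm;
  }
  return List::create(_["importance"] = NumericVector(importance.begin(),
                                                      importance.end()),
                      _["trees"] = trees);
}

// [[Rcpp::export(name = ".cppForestPredict")]]
NumericVector cppForestPredict(List trees, NumericMatrix x, int nClass) {
  const int n = x.nrow();
  const int nt = trees.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<double> votes(nClass > 0 ? nClass : 1, 0.0);
    double acc = 0.0;
    for (int tr = 0; tr < nt; ++tr) {
      NumericMatrix tm = trees[tr];
      int node = 0;
      while ((int)tm(node, 0) >= 0) {
        node = x(i, (int)tm(node, 0)) <= tm(node, 1)
          ? (int)tm(node, 2) : (int)tm(node, 3);
      }
      if (nClass > 0) votes[(int)tm(node, 4)] += 1.0;
      else acc += tm(node, 4);
    }
    if (nClass > 0) {
      int best = 0;
      for (int k = 1; k < nClass; ++k) if (votes[k] > votes[best]) best = k;
      out[i] = best;
    } else out[i] = acc / nt;
  }
  return out;
}
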