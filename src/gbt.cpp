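// Multiclass gradient-boosted regression trees (softmax objective).
//
// Second-order boosting: per round and class, a depth-limited regression
// tree is fit to the gradient/hessian of the softmax log-loss; leaf weight
// is -G/(H + lambda) scaled by the learning rate, split gain is
// 0.5 * (GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l)). Exact greedy splits with
// deterministic tie-breaking (lowest feature index, then lowest threshold),
// so identical inputs give bit-identical ensembles.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitInfo {
  int feat = -1;
  double thr = 0.0;
  double gain = 0.0;
};

// Flat tree arrays; node 0 is the root. feat == -1 marks a leaf.
struct Tree {
  std::vector<int> feat, left, right;
  std::vector<double> thr, value;
  int add_node() {
    feat.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    thr.push_back(0.0);
    value.push_back(0.0);
    return static_cast<int>(feat.size()) - 1;
  }
};

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& g;
  const std::vector<double>& h;
  int max_depth;
  double lambda, min_child_weight, eta;
  std::vector<double>& feat_gain;
  Tree tree;

  Builder(const NumericMatrix& X_, const std::vector<double>& g_,
          const std::vector<double>& h_, int max_depth_, double lambda_,
          double min_child_weight_, double eta_, std::vector<double>& fg)
      : X(X_), g(g_), h(h_), max_depth(max_depth_), lambda(lambda_),
        min_child_weight(min_child_weight_), eta(eta_), feat_gain(fg) {}

  SplitInfo find_split(const std::vector<int>& idx, double G, double H) {
    SplitInfo best;
    const int p = X.ncol();
    const size_t n = idx.size();
    std::vector<std::pair<double, int> > ord(n);
    const double parent = G * G / (H + lambda);
    for (int j = 0; j < p; ++j) {
      for (size_t i = 0; i < n; ++i)
        ord[i] = std::make_pair(X(idx[i], j), idx[i]);
      std::stable_sort(ord.begin(), ord.end());
      double GL = 0.0, HL = 0.0;
      for (size_t i = 0; i + 1 < n; ++i) {
        GL += g[ord[i].second];
        HL += h[ord[i].second];
        if (ord[i].first == ord[i + 1].first) continue;  // no cut within ties
        const double HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        const double GR = G - GL;
        const double gain =
            0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent);
        if (gain > best.gain + 1e-12) {
          best.feat = j;
          best.thr = 0.5 * (ord[i].first + ord[i + 1].first);
          best.gain = gain;
        }
      }
    }
    return best;
  }

  int build(std::vector<int>& idx, int depth) {
    double G = 0.0, H = 0.0;
    for (size_t i = 0; i < idx.size(); ++i) {
      G += g[idx[i]];
      H += h[idx[i]];
    }
    SplitInfo s;
    if (depth < max_depth && idx.size() >= 2) s = find_split(idx, G, H);
    const int node = tree.add_node();
    if (s.feat < 0) {
      tree.value[node] = -eta * G / (H + lambda);
      return node;
    }
    feat_gain[s.feat] += s.gain;
    std::vector<int> li, ri;
    li.reserve(idx.size());
    ri.reserve(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], s.feat) < s.thr)
        li.push_back(idx[i]);
      else
        ri.push_back(idx[i]);
    }
    tree.feat[node] = s.feat;
    tree.thr[node] = s.thr;
    const int l = build(li, depth + 1);
    const int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double tree_predict_row(const NumericMatrix& tr, const NumericMatrix& X,
                        int row) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    const int j = static_cast<int>(tr(node, 0));
    node = (X(row, j) < tr(node, 1)) ? static_cast<int>(tr(node, 2))
                                     : static_cast<int>(tr(node, 3));
  }
  return tr(node, 4);
}

NumericMatrix pack_tree(const Tree& t) {
  const int n = static_cast<int>(t.feat.size());
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feat[i];
    m(i, 1) = t.thr[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  colnames(m) = CharacterVector::create("feat", "thr", "left", "right", "value");
  return m;
}

void softmax_rows(const std::vector<double>& F, int n, int K,
                  std::vector<double>& P) {
  for (int i = 0; i < n; ++i) {
    double mx = F[i];
    for (int k = 1; k < K; ++k) mx = std::max(mx, F[i + n * k]);
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = std::exp(F[i + n * k] - mx);
      P[i + n * k] = e;
      s += e;
    }
    for (int k = 0; k < K; ++k) P[i + n * k] /= s;
  }
}

}  // namespace

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int nrounds,
                 int max_depth, double eta, double lambda,
                 double min_child_weight) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> F(static_cast<size_t>(n) * nclass, 0.0);
  std::vector<double> P(F.size(), 0.0);
  std::vector<double> g(n), h(n), fgain(p, 0.0);
  List trees(nrounds * nclass);

  for (int r = 0; r < nrounds; ++r) {
    softmax_rows(F, n, nclass, P);
    for (int k = 0; k < nclass; ++k) {
      for (int i = 0; i < n; ++i) {
        const double pk = P[i + static_cast<size_t>(n) * k];
        g[i] = pk - (y[i] == k ? 1.0 : 0.0);
        h[i] = std::max(pk * (1.0 - pk), 1e-16);
      }
      Builder b(X, g, h, max_depth, lambda, min_child_weight, eta, fgain);
      std::vector<int> idx(n);
      for (int i = 0; i < n; ++i) idx[i] = i;
      b.build(idx, 0);
      NumericMatrix tm = pack_tree(b.tree);
      trees[r * nclass + k] = tm;
      for (int i = 0; i < n; ++i)
        F[i + static_cast<size_t>(n) * k] += tree_predict_row(tm, X, i);
    }
  }
  return List::create(_["trees"] = trees, _["gain"] = NumericVector(fgain.begin(), fgain.end()),
                      _["nclass"] = nclass, _["nrounds"] = nrounds);
}

// Raw additive scores (margins), one column per class.
// [[Rcpp::export]]
NumericMatrix gbt_margin_cpp(List trees, NumericMatrix X, int nclass) {
  const int n = X.nrow();
  NumericMatrix F(n, nclass);
  const int T = trees.size();
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    const int k = t % nclass;
    for (int i = 0; i < n; ++i) F(i, k) += tree_predict_row(tm, X, i);
  }
  return F;
}
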