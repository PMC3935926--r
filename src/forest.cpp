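#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Bagged CART random forest for binary classification on small cohorts.
// Gini splits, sqrt-mtry candidate sampling, out-of-bag error and
// permutation importance. All randomness is drawn from R's RNG (via
// unif_rand under RNGScope) so a set.seed() on the R side makes every
// fit fully reproducible.

namespace {

struct Node {
  int feat;       // split feature index, -1 for leaf
  double thr;     // split threshold (midpoint between observed values)
  int left;
  int right;
  int pred;       // leaf class, 0 or 1
};

inline int rand_int(int n) {
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

inline int tie_class(int n1, int m) {
  // majority class of a node; exact ties resolved by a coin flip so that
  // neither class is systematically favoured on null data
  if (2 * n1 > m) return 1;
  if (2 * n1 < m) return 0;
  return unif_rand() < 0.5 ? 0 : 1;
}

// n * Gini impurity of a node with n1 positives among n
inline double gini_n(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return n * 2.0 * p * (1.0 - p);
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const IntegerVector& y, int mtry)
      : X_(X), y_(y), p_(X.ncol()), mtry_(mtry), perm_(p_), used_(p_, false) {
    for (int j = 0; j < p_; ++j) perm_[j] = j;
  }

  std::vector<Node> nodes;
  std::vector<int> used_feats;

  void build(std::vector<int>& idx) {
    nodes.clear();
    used_feats.clear();
    std::fill(used_.begin(), used_.end(), false);
    grow(idx);
    for (int j = 0; j < p_; ++j)
      if (used_[j]) used_feats.push_back(j);
  }

private:
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int p_, mtry_;
  std::vector<int> perm_;
  std::vector<bool> used_;
  std::vector<std::pair<double, int> > buf_;

  int leaf(int n1, int m) {
    Node nd;
    nd.feat = -1;
    nd.thr = 0.0;
    nd.left = nd.right = -1;
    nd.pred = tie_class(n1, m);
    nodes.push_back(nd);
    return static_cast<int>(nodes.size()) - 1;
  }

  int grow(std::vector<int>& idx) {
    const int m = static_cast<int>(idx.size());
    int n1 = 0;
    for (int i = 0; i < m; ++i) n1 += y_[idx[i]];
    if (n1 == 0 || n1 == m || m < 2) return leaf(n1, m);

    // draw mtry candidate features by partial Fisher-Yates
    for (int j = 0; j < mtry_; ++j) {
      int k = j + rand_int(p_ - j);
      std::swap(perm_[j], perm_[k]);
    }

    double best_cost = R_PosInf;
    int best_feat = -1;
    double best_thr = 0.0;

    for (int c = 0; c < mtry_; ++c) {
      const int f = perm_[c];
      buf_.resize(m);
      for (int i = 0; i < m; ++i)
        buf_[i] = std::make_pair(X_(idx[i], f), y_[idx[i]]);
      std::sort(buf_.begin(), buf_.end());
      if (buf_[0].first == buf_[m - 1].first) continue;  // constant in node
      int l1 = 0;
      for (int i = 0; i < m - 1; ++i) {
        l1 += buf_[i].second;
        if (buf_[i + 1].first == buf_[i].first) continue;
        const double cost = gini_n(l1, i + 1) + gini_n(n1 - l1, m - i - 1);
        if (cost < best_cost) {
          best_cost = cost;
          best_feat = f;
          best_thr = 0.5 * (buf_[i].first + buf_[i + 1].first);
        }
      }
    }

    if (best_feat < 0) return leaf(n1, m);  // all candidates constant

    std::vector<int> lidx, ridx;
    lidx.reserve(m);
    ridx.reserve(m);
    for (int i = 0; i < m; ++i) {
      if (X_(idx[i], best_feat) <= best_thr)
        lidx.push_back(idx[i]);
      else
        ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) return leaf(n1, m);  // numeric guard

    Node nd;
    nd.feat = best_feat;
    nd.thr = best_thr;
    nd.pred = -1;
    nodes.push_back(nd);
    used_[best_feat] = true;
    const int self = static_cast<int>(nodes.size()) - 1;
    const int l = grow(lidx);
    const int r = grow(ridx);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

// Traverse a tree for sample row i of X; if override_feat >= 0 the value of
// that feature is taken from row j instead (permutation importance).
inline int predict_one(const std::vector<Node>& nodes, const NumericMatrix& X,
                       int i, int override_feat = -1, int override_row = -1) {
  int at = 0;
  while (nodes[at].feat >= 0) {
    const int f = nodes[at].feat;
    const int row = (f == override_feat) ? override_row : i;
    at = (X(row, f) <= nodes[at].thr) ? nodes[at].left : nodes[at].right;
  }
  return nodes[at].pred;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            NumericMatrix Xtest, bool importance) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ntest = Xtest.nrow();
  if (y.size() != n) stop("length of y must match nrow(X)");
  if (mtry < 1 || mtry > p) stop("invalid mtry");

  RNGScope scope;

  IntegerMatrix oob_votes(n, 2);
  IntegerMatrix test_votes(std::max(ntest, 1), 2);
  NumericVector imp(p);
  std::vector<int> inbag(n), bs, oob, pperm;
  TreeBuilder builder(X, y, mtry);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    bs.clear();
    for (int i = 0; i < n; ++i) {
      const int k = rand_int(n);
      inbag[k]++;
      bs.push_back(k);
    }
    builder.build(bs);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);

    for (size_t k = 0; k < oob.size(); ++k) {
      const int i = oob[k];
      oob_votes(i, predict_one(builder.nodes, X, i))++;
    }

    if (importance && !oob.empty()) {
      const int noob = static_cast<int>(oob.size());
      int base = 0;
      for (int k = 0; k < noob; ++k)
        base += (predict_one(builder.nodes, X, oob[k]) == y[oob[k]]);
      for (size_t u = 0; u < builder.used_feats.size(); ++u) {
        const int f = builder.used_feats[u];
        pperm.assign(oob.begin(), oob.end());
        for (int k = noob - 1; k > 0; --k)
          std::swap(pperm[k], pperm[rand_int(k + 1)]);
        int hit = 0;
        for (int k = 0; k < noob; ++k)
          hit += (predict_one(builder.nodes, X, oob[k], f, pperm[k]) == y[oob[k]]);
        imp[f] += static_cast<double>(base - hit) / noob;
      }
    }

    for (int i = 0; i < ntest; ++i)
      test_votes(i, predict_one(builder.nodes, Xtest, i))++;
  }

  int voted = 0, wrong = 0;
  for (int i = 0; i < n; ++i) {
    const int v0 = oob_votes(i, 0), v1 = oob_votes(i, 1);
    if (v0 + v1 == 0) continue;
    ++voted;
    int pred;
    if (v1 > v0)
      pred = 1;
    else if (v0 > v1)
      pred = 0;
    else
      pred = unif_rand() < 0.5 ? 0 : 1;
    if (pred != y[i]) ++wrong;
  }
  const double oob_error =
      (voted > 0) ? static_cast<double>(wrong) / voted : NA_REAL;

  IntegerVector test_pred(ntest);
  for (int i = 0; i < ntest; ++i) {
    const int v0 = test_votes(i, 0), v1 = test_votes(i, 1);
    if (v1 > v0)
      test_pred[i] = 1;
    else if (v0 > v1)
      test_pred[i] = 0;
    else
      test_pred[i] = unif_rand() < 0.5 ? 0 : 1;
  }

  for (int j = 0; j < p; ++j) imp[j] /= ntree;

  return List::create(_["oob_error"] = oob_error, _["importance"] = imp,
                      _["test_pred"] = test_pred, _["oob_votes"] = oob_votes);
}
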