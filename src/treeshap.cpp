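// Interventional tree-SHAP for boosted tree ensembles.
//
// For one foreground row x and one background row b, each leaf defines a
// conjunction game over the "distinguishing" split features on its path:
// the leaf is reached by coalition S iff every path feature routed in the
// foreground direction is in S (set U) and every path feature routed in the
// background direction is not (set V). Shapley values of such games have
// closed forms, so exact interventional SHAP values (and pairwise Shapley
// interaction values) are accumulated leaf by leaf and averaged over the
// background sample. Cost is O(n_fore * n_back * leaves * depth).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr int MAXD = 64;  // bound on distinguishing features per path

struct Trees {
  const int *feature;      // -1 for leaf
  const double *split;
  const int *yes, *no, *missing;
  const double *value;
  const int *roots;
  int n_trees;
};

inline int child_for(const Trees &T, int node, double v) {
  if (ISNAN(v)) return T.missing[node];
  // xgboost evaluates split conditions in single precision
  return (float)v < (float)T.split[node] ? T.yes[node] : T.no[node];
}

double leaf_sum(const Trees &T, const double *row) {
  double tot = 0.0;
  for (int t = 0; t < T.n_trees; ++t) {
    int node = T.roots[t];
    while (T.feature[node] >= 0) node = child_for(T, node, row[T.feature[node]]);
    tot += T.value[node];
  }
  return tot;
}

// POS[u][w] = (u-1)! w! / (u+w)!   (weight for a positive literal, u >= 1)
// NEG[u][w] = u! (w-1)! / (u+w)!   (weight for a negative literal, w >= 1)
struct WeightTables {
  double POS[MAXD + 1][MAXD + 1];
  double NEG[MAXD + 1][MAXD + 1];
  WeightTables() {
    for (int u = 0; u <= MAXD; ++u)
      for (int w = 0; w <= MAXD; ++w) {
        if (u >= 1)
          POS[u][w] = std::exp(std::lgamma(u) + std::lgamma(w + 1.0) -
                               std::lgamma(u + w + 1.0));
        else POS[u][w] = 0.0;
        if (w >= 1)
          NEG[u][w] = std::exp(std::lgamma(u + 1.0) + std::lgamma((double)w) -
                               std::lgamma(u + w + 1.0));
        else NEG[u][w] = 0.0;
      }
  }
};
static const WeightTables WT;

struct PathState {
  std::vector<int> state;      // 0 unseen, 1 in U, 2 in V
  int feat_path[MAXD];
  char side_path[MAXD];        // 1 = U, 2 = V
  const double *x, *b;
  double *phi;                 // length d
  double *inter;               // d x d or nullptr
  int d;
};

void recurse(const Trees &T, PathState &st, int node, int u, int w) {
  int f = T.feature[node];
  if (f < 0) {  // leaf
    if (u + w == 0) return;
    double v = T.value[node];
    int m = u + w;
    for (int a = 0; a < m; ++a) {
      int i = st.feat_path[a];
      if (st.side_path[a] == 1) st.phi[i] += v * WT.POS[u][w];
      else                      st.phi[i] -= v * WT.NEG[u][w];
    }
    if (st.inter && m >= 2) {
      for (int a = 0; a < m; ++a) {
        int i = st.feat_path[a];
        char si = st.side_path[a];
        for (int c = 0; c < m; ++c) {
          if (c == a) continue;
          int j = st.feat_path[c];
          char sj = st.side_path[c];
          double contrib;
          if (si == 1 && sj == 1)      contrib =  0.5 * v * WT.POS[u - 1][w];
          else if (si == 1)            contrib = -0.5 * v * WT.POS[u][w - 1];
          else if (sj == 1)            contrib = -0.5 * v * WT.NEG[u - 1][w];
          else                         contrib =  0.5 * v * WT.NEG[u][w - 1];
          st.inter[(size_t)i * st.d + j] += contrib;
        }
      }
    }
    return;
  }
  double xv = st.x[f], bv = st.b[f];
  int cx = child_for(T, node, xv), cb = child_for(T, node, bv);
  int s = st.state[f];
  if (s == 1) { recurse(T, st, cx, u, w); return; }
  if (s == 2) { recurse(T, st, cb, u, w); return; }
  if (cx == cb) { recurse(T, st, cx, u, w); return; }
  // feature becomes distinguishing: branch both ways
  st.state[f] = 1;
  st.feat_path[u + w] = f; st.side_path[u + w] = 1;
  recurse(T, st, cx, u + 1, w);
  st.state[f] = 2;
  st.side_path[u + w] = 2;
  recurse(T, st, cb, u, w + 1);
  st.state[f] = 0;
}

Trees make_trees(const IntegerVector &feature, const NumericVector &split,
                 const IntegerVector &yes, const IntegerVector &no,
                 const IntegerVector &missing, const NumericVector &value,
                 const IntegerVector &roots) {
  Trees T;
  T.feature = feature.begin(); T.split = split.begin();
  T.yes = yes.begin(); T.no = no.begin(); T.missing = missing.begin();
  T.value = value.begin(); T.roots = roots.begin();
  T.n_trees = roots.size();
  return T;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_tree_margin(NumericMatrix X, IntegerVector feature,
                              NumericVector split, IntegerVector yes,
                              IntegerVector no, IntegerVector missing,
                              NumericVector value, IntegerVector roots) {
  Trees T = make_trees(feature, split, yes, no, missing, value, roots);
  int n = X.nrow(), d = X.ncol();
  NumericVector out(n);
  std::vector<double> row(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) row[j] = X(i, j);
    out[i] = leaf_sum(T, row.data());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_treeshap(NumericMatrix X, NumericMatrix B, IntegerVector feature,
                  NumericVector split, IntegerVector yes, IntegerVector no,
                  IntegerVector missing, NumericVector value,
                  IntegerVector roots, bool interactions) {
  Trees T = make_trees(feature, split, yes, no, missing, value, roots);
  int n = X.nrow(), nb = B.nrow(), d = X.ncol();
  NumericMatrix phi(n, d);
  NumericVector inter;
  double *inter_ptr = nullptr;
  if (interactions) {
    inter = NumericVector((R_xlen_t)n * d * d);
    inter.attr("dim") = IntegerVector::create(d, d, n);
  }
  NumericVector margin_x(n), margin_b(nb);

  std::vector<double> xrow(d), brow(d);
  std::vector<std::vector<double>> brows(nb, std::vector<double>(d));
  for (int k = 0; k < nb; ++k) {
    for (int j = 0; j < d; ++j) brows[k][j] = B(k, j);
    margin_b[k] = leaf_sum(T, brows[k].data());
  }

  PathState st;
  st.state.assign(d, 0);
  st.d = d;
  std::vector<double> phi_acc(d), inter_acc((size_t)(interactions ? d * d : 0));

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xrow[j] = X(i, j);
    margin_x[i] = leaf_sum(T, xrow.data());
    std::fill(phi_acc.begin(), phi_acc.end(), 0.0);
    if (interactions) std::fill(inter_acc.begin(), inter_acc.end(), 0.0);
    for (int k = 0; k < nb; ++k) {
      st.x = xrow.data();
      st.b = brows[k].data();
      st.phi = phi_acc.data();
      st.inter = interactions ? inter_acc.data() : nullptr;
      for (int t = 0; t < T.n_trees; ++t) recurse(T, st, T.roots[t], 0, 0);
    }
    for (int j = 0; j < d; ++j) phi(i, j) = phi_acc[j] / nb;
    if (interactions) {
      inter_ptr = REAL(inter) + (R_xlen_t)i * d * d;
      // off-diagonals, then the diagonal as phi minus the off-diagonal row sum
      for (int a = 0; a < d; ++a)
        for (int c = 0; c < d; ++c)
          if (a != c) inter_ptr[(size_t)a * d + c] = inter_acc[(size_t)a * d + c] / nb;
      for (int a = 0; a < d; ++a) {
        double rs = 0.0;
        for (int c = 0; c < d; ++c) if (c != a) rs += inter_ptr[(size_t)a * d + c];
        inter_ptr[(size_t)a * d + a] = phi(i, a) - rs;
      }
    }
  }

  List out = List::create(_["phi"] = phi, _["margin_x"] = margin_x,
                          _["margin_b"] = margin_b);
  if (interactions) out["interactions"] = inter;
  return out;
}
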