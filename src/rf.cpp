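#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Random forest for two-class problems, grown with CART/Gini splits.
// Uses R's RNG (unif_rand) throughout so that set.seed() makes fits
// bit-reproducible. Trees are returned as flat parallel arrays; leaves are
// marked by feature == -1 and store the in-leaf fraction of class 1.

namespace {

struct TreeBuf {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, frac;
};

inline int runif_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

double gini_pair(int n1, int n) {
  if (n == 0) return 0.0;
  const double p1 = (double)n1 / n;
  return 2.0 * p1 * (1.0 - p1) * n;
}

int grow_node(const NumericMatrix &X, const IntegerVector &y,
              std::vector<int> &idx, int lo, int hi, int mtry, int min_n,
              TreeBuf &tb, std::vector<int> &featpool,
              std::vector<std::pair<double, int> > &buf) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];

  const int node = (int)tb.feature.size();
  tb.feature.push_back(-1);
  tb.threshold.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  tb.frac.push_back((double)n1 / n);
  if (n < min_n || n1 == 0 || n1 == n) return node;

  const int d = X.ncol();
  // partial Fisher-Yates over the feature pool
  for (int i = 0; i < d; ++i) featpool[i] = i;
  int best_f = -1, best_cut = -1;
  double best_imp = R_PosInf, best_thr = 0.0;

  for (int t = 0; t < mtry; ++t) {
    const int j = t + runif_int(d - t);
    std::swap(featpool[t], featpool[j]);
    const int f = featpool[t];

    buf.resize(n);
    for (int i = 0; i < n; ++i)
      buf[i] = std::make_pair(X(idx[lo + i], f), idx[lo + i]);
    std::sort(buf.begin(), buf.end());
    if (!(buf[0].first < buf[n - 1].first)) continue; // constant in node

    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += y[buf[i].second];
      if (buf[i].first < buf[i + 1].first) {
        const double imp =
            gini_pair(l1, i + 1) + gini_pair(n1 - l1, n - i - 1);
        if (imp < best_imp) {
          best_imp = imp;
          best_f = f;
          best_cut = i;
          best_thr = buf[i].first + (buf[i + 1].first - buf[i].first) / 2.0;
        }
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo, hi) by the chosen split (stable to keep determinism)
  std::vector<int> lidx, ridx;
  lidx.reserve(n);
  ridx.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr)
      lidx.push_back(idx[i]);
    else
      ridx.push_back(idx[i]);
  }
  if (lidx.empty() || ridx.empty()) return node; // degenerate, keep leaf
  for (size_t i = 0; i < lidx.size(); ++i) idx[lo + i] = lidx[i];
  for (size_t i = 0; i < ridx.size(); ++i) idx[lo + lidx.size() + i] = ridx[i];

  tb.feature[node] = best_f;
  tb.threshold[node] = best_thr;
  const int mid = lo + (int)lidx.size();
  tb.left[node] = grow_node(X, y, idx, lo, mid, mtry, min_n, tb, featpool, buf);
  tb.right[node] =
      grow_node(X, y, idx, mid, hi, mtry, min_n, tb, featpool, buf);
  return node;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_n) {
  const int n = X.nrow(), d = X.ncol();
  if (mtry < 1 || mtry > d) stop("mtry out of range");
  if (min_n < 2) stop("min_n must be >= 2");
  RNGScope scope;
  List forest(n_trees);
  std::vector<int> idx(n), featpool(d);
  std::vector<std::pair<double, int> > buf;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = runif_int(n); // bootstrap
    TreeBuf tb;
    grow_node(X, y, idx, 0, n, mtry, min_n, tb, featpool, buf);
    forest[t] = List::create(
        _["feature"] = wrap(tb.feature), _["threshold"] = wrap(tb.threshold),
        _["left"] = wrap(tb.left), _["right"] = wrap(tb.right),
        _["frac"] = wrap(tb.frac));
  }
  return forest;
}

// Probability of class 1 = fraction of trees voting class 1 (leaf ties at
// exactly 0.5 contribute half a vote).
// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), n_trees = forest.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"], frac = tree["frac"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      const double f = frac[node];
      out[i] += (f > 0.5) ? 1.0 : (f == 0.5 ? 0.5 : 0.0);
    }
  }
  return out / (double)n_trees;
}

// FNV-1a 64-bit hash of a raw vector; used for run-manifest checksums.
// [[Rcpp::export]]
String fnv1a_hash_cpp(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 1099511628211ULL;
  }
  char out[17];
  snprintf(out, sizeof(out), "%016llx", (unsigned long long)h);
  return String(out);
}
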