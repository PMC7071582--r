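// Compact binary-classification random forest: CART trees, Gini splitting,
// bootstrap bagging, mean-decrease-Gini importance, out-of-bag error.
// Self-contained RNG (splitmix64-seeded xorshift64*) so results are
// bit-reproducible across platforms and independent of R's RNG state.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// weighted Gini cost n * gini(node) = n - (pos^2 + neg^2) / n
inline double gini_cost(double n, double pos) {
  if (n <= 0.0) return 0.0;
  double neg = n - pos;
  return n - (pos * pos + neg * neg) / n;
}

struct Forest {
  std::vector<int> feat;       // -1 marks a leaf
  std::vector<double> thr;
  std::vector<int> left, right; // absolute node indices
  std::vector<double> prob;     // class-1 fraction at the node
  std::vector<int> tree_start;  // ntree entries
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int n, p, mtry, nodesize;
  Rng& rng;
  Forest& fo;
  std::vector<double>& imp;
  std::vector<int> rows;        // bootstrap row ids, partitioned in place
  std::vector<int> featperm;    // scratch for mtry sampling
  std::vector<std::pair<double, int> > buf; // (x value, y) scratch

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_, int nodesize_,
          Rng& rng_, Forest& fo_, std::vector<double>& imp_)
      : X(X_), y(y_), n(X_.nrow()), p(X_.ncol()), mtry(mtry_), nodesize(nodesize_),
        rng(rng_), fo(fo_), imp(imp_) {
    featperm.resize(p);
    for (int j = 0; j < p; ++j) featperm[j] = j;
    buf.reserve(n);
  }

  int new_node() {
    fo.feat.push_back(-1);
    fo.thr.push_back(0.0);
    fo.left.push_back(-1);
    fo.right.push_back(-1);
    fo.prob.push_back(0.0);
    return static_cast<int>(fo.feat.size()) - 1;
  }

  // grow node over rows[lo, hi); returns node index
  int grow(int lo, int hi) {
    int node = new_node();
    int m = hi - lo;
    int pos = 0;
    for (int i = lo; i < hi; ++i) pos += y[rows[i]];
    fo.prob[node] = static_cast<double>(pos) / m;
    if (pos == 0 || pos == m || m < 2 * nodesize) return node;

    double parent_cost = gini_cost(m, pos);
    double best_dec = 0.0;
    int best_f = -1;
    double best_thr = 0.0;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int k = 0; k < mtry; ++k) {
      int j = k + rng.below(p - k);
      std::swap(featperm[k], featperm[j]);
      int f = featperm[k];

      buf.clear();
      for (int i = lo; i < hi; ++i)
        buf.push_back(std::make_pair(X(rows[i], f), y[rows[i]]));
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue; // constant in node

      double posL = 0.0;
      for (int i = 1; i < m; ++i) {
        posL += buf[i - 1].second;
        if (buf[i].first <= buf[i - 1].first) continue; // not a distinct cut
        double nL = i, nR = m - i;
        double dec = parent_cost - gini_cost(nL, posL) - gini_cost(nR, pos - posL);
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_f = f;
          best_thr = (buf[i - 1].first + buf[i].first) / 2.0;
        }
      }
    }

    if (best_f < 0) return node; // no improving split among the sampled features
    imp[best_f] += best_dec;

    // partition rows by the chosen split
    int i = lo, j = hi - 1;
    while (i <= j) {
      if (X(rows[i], best_f) <= best_thr) {
        ++i;
      } else {
        std::swap(rows[i], rows[j]);
        --j;
      }
    }
    fo.feat[node] = best_f;
    fo.thr[node] = best_thr;
    int l = grow(lo, i);
    int r = grow(i, hi);
    fo.left[node] = l;
    fo.right[node] = r;
    return node;
  }
};

inline double predict_row(const Forest& fo, int root, const NumericMatrix& X, int i) {
  int node = root;
  while (fo.feat[node] >= 0)
    node = (X(i, fo.feat[node]) <= fo.thr[node]) ? fo.left[node] : fo.right[node];
  return fo.prob[node];
}

} // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry, int nodesize,
                  double seed, Nullable<NumericMatrix> xtest, bool keep_forest,
                  bool bootstrap) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(x)");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  Rng rng(static_cast<uint64_t>(seed));

  Forest fo;
  std::vector<double> imp(p, 0.0);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> inbag(n);

  NumericMatrix Xt;
  int ntst = 0;
  if (xtest.isNotNull()) {
    Xt = as<NumericMatrix>(xtest);
    if (Xt.ncol() != p) stop("xtest must have the same number of columns as x");
    ntst = Xt.nrow();
  }
  std::vector<double> tst_sum(ntst, 0.0);

  Builder b(X, y, mtry, nodesize, rng, fo, imp);
  for (int t = 0; t < ntree; ++t) {
    b.rows.clear();
    if (bootstrap) {
      std::fill(inbag.begin(), inbag.end(), 0);
      for (int i = 0; i < n; ++i) {
        int r = rng.below(n);
        b.rows.push_back(r);
        inbag[r]++;
      }
    } else {
      for (int i = 0; i < n; ++i) b.rows.push_back(i);
    }
    int root = b.grow(0, n);
    fo.tree_start.push_back(root);

    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        if (inbag[i] == 0) {
          oob_sum[i] += predict_row(fo, root, X, i);
          oob_cnt[i]++;
        }
      }
    }
    for (int i = 0; i < ntst; ++i) tst_sum[i] += predict_row(fo, root, Xt, i);
    if (!keep_forest && t + 1 < ntree) {
      // reclaim node storage; tree_start indices of dropped trees are unused
      fo.feat.clear(); fo.thr.clear(); fo.left.clear(); fo.right.clear(); fo.prob.clear();
    }
  }

  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / ntree;

  double oob_err = NA_REAL;
  NumericVector oob_prob(n, NA_REAL);
  if (bootstrap) {
    int used = 0, wrong = 0;
    for (int i = 0; i < n; ++i) {
      if (oob_cnt[i] > 0) {
        double pr = oob_sum[i] / oob_cnt[i];
        oob_prob[i] = pr;
        used++;
        if ((pr >= 0.5 ? 1 : 0) != y[i]) wrong++;
      }
    }
    if (used > 0) oob_err = static_cast<double>(wrong) / used;
  }

  List out = List::create(
      _["importance"] = importance,
      _["oob_error"] = oob_err,
      _["oob_prob"] = oob_prob);
  if (ntst > 0) {
    NumericVector tp(ntst);
    for (int i = 0; i < ntst; ++i) tp[i] = tst_sum[i] / ntree;
    out["test_prob"] = tp;
  }
  if (keep_forest) {
    out["forest"] = List::create(
        _["feat"] = wrap(fo.feat), _["thr"] = wrap(fo.thr),
        _["left"] = wrap(fo.left), _["right"] = wrap(fo.right),
        _["prob"] = wrap(fo.prob), _["tree_start"] = wrap(fo.tree_start));
  }
  return out;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  Forest fo;
  fo.feat = as<std::vector<int> >(forest["feat"]);
  fo.thr = as<std::vector<double> >(forest["thr"]);
  fo.left = as<std::vector<int> >(forest["left"]);
  fo.right = as<std::vector<int> >(forest["right"]);
  fo.prob = as<std::vector<double> >(forest["prob"]);
  fo.tree_start = as<std::vector<int> >(forest["tree_start"]);
  int ntree = static_cast<int>(fo.tree_start.size());
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = 0; t < ntree; ++t) s += predict_row(fo, fo.tree_start[t], X, i);
    out[i] = s / ntree;
  }
  return out;
}
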