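#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Minimal kd-tree on row-major data with the Chebyshev (max) norm,
// supporting k-nearest-neighbour search and strict range counting.
// This backs the Kraskov-Stoegbauer-Grassberger conditional mutual
// information estimator used for transfer entropy.

struct KDTree {
  const double *data;  // n x d, row major
  int n, d;
  std::vector<int> idx;
  struct Node {
    int lo, hi;        // range in idx
    int split_dim;
    double split_val;
    int left, right;   // children, -1 for leaf
    std::vector<double> bb_lo, bb_hi;
  };
  std::vector<Node> nodes;
  static const int LEAF = 24;

  KDTree(const double *data_, int n_, int d_) : data(data_), n(n_), d(d_) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 4);
    build(0, n);
  }

  inline double at(int i, int j) const { return data[(size_t)i * d + j]; }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo;
    nd.hi = hi;
    nd.bb_lo.assign(d, R_PosInf);
    nd.bb_hi.assign(d, R_NegInf);
    for (int i = lo; i < hi; ++i)
      for (int j = 0; j < d; ++j) {
        const double v = at(idx[i], j);
        if (v < nd.bb_lo[j]) nd.bb_lo[j] = v;
        if (v > nd.bb_hi[j]) nd.bb_hi[j] = v;
      }
    const int me = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= LEAF) {
      nodes[me].left = nodes[me].right = -1;
      return me;
    }
    int dim = 0;
    double wid = -1.0;
    for (int j = 0; j < d; ++j) {
      const double w = nd.bb_hi[j] - nd.bb_lo[j];
      if (w > wid) {
        wid = w;
        dim = j;
      }
    }
    const int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return at(a, dim) < at(b, dim); });
    nodes[me].split_dim = dim;
    nodes[me].split_val = at(idx[mid], dim);
    const int l = build(lo, mid);
    const int r = build(mid, hi);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  inline double box_dist(const Node &nd, const double *q) const {
    double dist = 0.0;
    for (int j = 0; j < d; ++j) {
      double e = 0.0;
      if (q[j] < nd.bb_lo[j]) e = nd.bb_lo[j] - q[j];
      else if (q[j] > nd.bb_hi[j]) e = q[j] - nd.bb_hi[j];
      if (e > dist) dist = e;
    }
    return dist;
  }

  inline double pt_dist(int i, const double *q) const {
    double dist = 0.0;
    for (int j = 0; j < d; ++j) {
      const double e = std::fabs(at(i, j) - q[j]);
      if (e > dist) dist = e;
    }
    return dist;
  }

  // k-th nearest neighbour distance to query q, excluding point `self`
  void knn(int node, const double *q, int self, int k,
           std::vector<double> &heap) const {
    const Node &nd = nodes[node];
    if ((int)heap.size() == k && box_dist(nd, q) >= heap.front()) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        const int p = idx[i];
        if (p == self) continue;
        const double dd = pt_dist(p, q);
        if ((int)heap.size() < k) {
          heap.push_back(dd);
          std::push_heap(heap.begin(), heap.end());
        } else if (dd < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = dd;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    const int first =
        q[nd.split_dim] <= nd.split_val ? nd.left : nd.right;
    const int second = first == nd.left ? nd.right : nd.left;
    knn(first, q, self, k, heap);
    knn(second, q, self, k, heap);
  }

  // indices of the k nearest neighbours (excluding self)
  void knn_idx(int node, const double *q, int self, int k,
               std::vector<std::pair<double, int>> &heap) const {
    const Node &nd = nodes[node];
    if ((int)heap.size() == k && box_dist(nd, q) >= heap.front().first) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        const int p = idx[i];
        if (p == self) continue;
        const double dd = pt_dist(p, q);
        if ((int)heap.size() < k) {
          heap.emplace_back(dd, p);
          std::push_heap(heap.begin(), heap.end());
        } else if (dd < heap.front().first) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = std::make_pair(dd, p);
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    const int first = q[nd.split_dim] <= nd.split_val ? nd.left : nd.right;
    const int second = first == nd.left ? nd.right : nd.left;
    knn_idx(first, q, self, k, heap);
    knn_idx(second, q, self, k, heap);
  }

  // number of points with max-norm distance strictly < eps, excluding self
  int range_count(int node, const double *q, int self, double eps) const {
    const Node &nd = nodes[node];
    if (box_dist(nd, q) >= eps) return 0;
    if (nd.left < 0) {
      int c = 0;
      for (int i = nd.lo; i < nd.hi; ++i) {
        const int p = idx[i];
        if (p == self) continue;
        if (pt_dist(p, q) < eps) ++c;
      }
      return c;
    }
    return range_count(nd.left, q, self, eps) +
           range_count(nd.right, q, self, eps);
  }
};

static std::vector<double> bind_cols(const NumericMatrix &A,
                                     const NumericMatrix &B) {
  const int n = A.nrow(), da = A.ncol(), db = B.ncol();
  std::vector<double> out((size_t)n * (da + db));
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < da; ++j) out[(size_t)i * (da + db) + j] = A(i, j);
    for (int j = 0; j < db; ++j) out[(size_t)i * (da + db) + da + j] = B(i, j);
  }
  return out;
}

// Conditional mutual information I(X; Y | Z) in nats via the
// Frenzel-Pompe / KSG nearest-neighbour construction with k neighbours.
// With dz = 0 this reduces to the KSG mutual information (algorithm 1).
//
// [[Rcpp::export(name = ".ksg_cmi")]]
double ksg_cmi(NumericMatrix X, NumericMatrix Y, NumericMatrix Z, int k) {
  const int n = X.nrow();
  if (n < k + 2) stop("too few points for the KSG estimator");
  const int dx = X.ncol(), dy = Y.ncol(), dz = Z.ncol();
  const int dj = dx + dy + dz;

  std::vector<double> joint((size_t)n * dj);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < dx; ++j) joint[(size_t)i * dj + j] = X(i, j);
    for (int j = 0; j < dy; ++j) joint[(size_t)i * dj + dx + j] = Y(i, j);
    for (int j = 0; j < dz; ++j) joint[(size_t)i * dj + dx + dy + j] = Z(i, j);
  }
  std::vector<double> xz = dz > 0 ? bind_cols(X, Z) : std::vector<double>(X.begin(), X.end());
  std::vector<double> yz = dz > 0 ? bind_cols(Y, Z) : std::vector<double>(Y.begin(), Y.end());
  // NumericMatrix is column-major; rebuild row-major when dz == 0
  if (dz == 0) {
    xz.resize((size_t)n * dx);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < dx; ++j) xz[(size_t)i * dx + j] = X(i, j);
    yz.resize((size_t)n * dy);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < dy; ++j) yz[(size_t)i * dy + j] = Y(i, j);
  }

  KDTree t_joint(joint.data(), n, dj);
  KDTree t_xz(xz.data(), n, dx + dz);
  KDTree t_yz(yz.data(), n, dy + dz);
  std::vector<double> zdat;
  KDTree *t_z = nullptr;
  if (dz > 0) {
    zdat.resize((size_t)n * dz);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < dz; ++j) zdat[(size_t)i * dz + j] = Z(i, j);
    t_z = new KDTree(zdat.data(), n, dz);
  }

  double acc = 0.0;
  std::vector<double> heap;
  std::vector<double> q(dj);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < dj; ++j) q[j] = joint[(size_t)i * dj + j];
    heap.clear();
    t_joint.knn(0, q.data(), i, k, heap);
    const double eps = heap.front();
    // marginal queries: [x, z] and [y, z] blocks of the joint point
    std::vector<double> qxz(dx + dz), qyz(dy + dz);
    for (int j = 0; j < dx; ++j) qxz[j] = q[j];
    for (int j = 0; j < dz; ++j) qxz[dx + j] = q[dx + dy + j];
    for (int j = 0; j < dy; ++j) qyz[j] = q[dx + j];
    for (int j = 0; j < dz; ++j) qyz[dy + j] = q[dx + dy + j];
    const int n_xz = t_xz.range_count(0, qxz.data(), i, eps);
    const int n_yz = t_yz.range_count(0, qyz.data(), i, eps);
    if (dz > 0) {
      const int n_z = t_z->range_count(0, q.data() + dx + dy, i, eps);
      acc += R::digamma(n_z + 1.0) - R::digamma(n_xz + 1.0) -
             R::digamma(n_yz + 1.0);
    } else {
      acc += -R::digamma(n_xz + 1.0) - R::digamma(n_yz + 1.0);
    }
  }
  delete t_z;
  double mi;
  if (dz > 0)
    mi = R::digamma((double)k) + acc / n;
  else
    mi = R::digamma((double)k) + R::digamma((double)n) + acc / n;
  return mi;
}

// Locally-constant one-step predictor error (Ragwitz criterion helper):
// predict target[i] as the mean of target over the k_nn nearest neighbours
// of emb[i, ] and return the mean squared error over an evaluation subsample.
//
// [[Rcpp::export(name = ".local_predictor_mse")]]
double local_predictor_mse(NumericMatrix emb, NumericVector target, int k_nn,
                           int n_eval, int seed) {
  const int n = emb.nrow(), d = emb.ncol();
  std::vector<double> dat((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j) dat[(size_t)i * d + j] = emb(i, j);
  KDTree tree(dat.data(), n, d);

  std::vector<int> eval_idx;
  if (n_eval >= n) {
    eval_idx.resize(n);
    for (int i = 0; i < n; ++i) eval_idx[i] = i;
  } else {
    Xoshiro rng((uint64_t)seed * 0xC0FFEEULL + 1ULL);
    eval_idx.resize(n_eval);
    for (int i = 0; i < n_eval; ++i) eval_idx[i] = (int)(rng.unif() * n);
  }

  double mse = 0.0;
  std::vector<std::pair<double, int>> heap;
  std::vector<double> q(d);
  for (size_t e = 0; e < eval_idx.size(); ++e) {
    const int i = eval_idx[e];
    for (int j = 0; j < d; ++j) q[j] = dat[(size_t)i * d + j];
    heap.clear();
    tree.knn_idx(0, q.data(), i, k_nn, heap);
    double pred = 0.0;
    for (size_t h = 0; h < heap.size(); ++h) pred += target[heap[h].second];
    pred /= heap.size();
    const double err = target[i] - pred;
    mse += err * err;
  }
  return mse / eval_idx.size();
}
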