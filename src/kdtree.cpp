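// Exact k-nearest-neighbor mean distances via a balanced 3D kd-tree.
// Robust to strongly non-uniform density (dense stem surfaces vs sparse
// ground), where a uniform grid degenerates.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct KDTree {
  // implicit balanced tree over index array: node = subrange [lo, hi)
  std::vector<int> idx;
  const double* xs;
  const double* ys;
  const double* zs;
  int n;

  inline double coord(int i, int dim) const {
    return dim == 0 ? xs[i] : (dim == 1 ? ys[i] : zs[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 8) return;                 // leaf bucket
    int mid = (lo + hi) / 2;
    int dim = depth % 3;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, dim) < coord(b, dim); });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  // k best squared distances for query point q (excluding index self)
  void query(int self, double qx, double qy, double qz, int k,
             std::vector<double>& heap) const {
    heap.clear();
    search(0, n, 0, self, qx, qy, qz, k, heap);
  }

  inline void consider(int i, int self, double qx, double qy, double qz,
                       int k, std::vector<double>& heap) const {
    if (i == self) return;
    double dx = xs[i] - qx, dy = ys[i] - qy, dz = zs[i] - qz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if ((int)heap.size() < k) {
      heap.push_back(d2);
      std::push_heap(heap.begin(), heap.end());
    } else if (d2 < heap.front()) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = d2;
      std::push_heap(heap.begin(), heap.end());
    }
  }

  void search(int lo, int hi, int depth, int self, double qx, double qy,
              double qz, int k, std::vector<double>& heap) const {
    if (hi - lo <= 8) {
      for (int j = lo; j < hi; ++j)
        consider(idx[j], self, qx, qy, qz, k, heap);
      return;
    }
    int mid = (lo + hi) / 2;
    int dim = depth % 3;
    int p = idx[mid];
    consider(p, self, qx, qy, qz, k, heap);
    double q = dim == 0 ? qx : (dim == 1 ? qy : qz);
    double diff = q - coord(p, dim);
    int first_lo = diff <= 0;
    for (int side = 0; side < 2; ++side) {
      bool go_lo = (side == 0) == (bool)first_lo;
      if (side == 1) {
        // prune the far side when the splitting slab is beyond the kth best
        if ((int)heap.size() == k && diff * diff > heap.front()) break;
      }
      if (go_lo) search(lo, mid, depth + 1, self, qx, qy, qz, k, heap);
      else search(mid + 1, hi, depth + 1, self, qx, qy, qz, k, heap);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".knn_mean_dist_kd_cpp")]]
NumericVector knn_mean_dist_kd_cpp(NumericVector x, NumericVector y,
                                   NumericVector z, int k) {
  int n = x.size();
  NumericVector out(n, NA_REAL);
  if (n <= k) return out;
  KDTree tree;
  tree.xs = x.begin(); tree.ys = y.begin(); tree.zs = z.begin();
  tree.n = n;
  tree.idx.resize(n);
  for (int i = 0; i < n; ++i) tree.idx[i] = i;
  tree.build(0, n, 0);
  std::vector<double> heap;
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    tree.query(i, x[i], y[i], z[i], k, heap);
    double s = 0;
    for (double d2 : heap) s += std::sqrt(d2);
    out[i] = s / heap.size();
  }
  return out;
}
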