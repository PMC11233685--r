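// Grid-hashed neighbor queries for unorganized point clouds.
// Both kernels bucket points into a uniform 3D grid and visit neighboring
// cells only, which keeps SOR and Euclidean clustering near-linear for the
// multi-million-point clouds a mobile scan of an orchard produces.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Grid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<uint64_t, std::vector<int>> cells;

  static uint64_t key(int ix, int iy, int iz) {
    // 21 bits per axis, offset to keep indices positive
    const uint64_t B = 1u << 20;
    return ((uint64_t)(ix + B) << 42) | ((uint64_t)(iy + B) << 21) |
           (uint64_t)(iz + B);
  }

  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    int n = pts.nrow();
    ox = oy = oz = 0.0;
    if (n > 0) { ox = pts(0, 0); oy = pts(0, 1); oz = pts(0, 2); }
    cells.reserve(n / 2 + 1);
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor((pts(i, 0) - ox) / cell);
      int iy = (int)std::floor((pts(i, 1) - oy) / cell);
      int iz = (int)std::floor((pts(i, 2) - oz) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }

  void cell_of(const NumericMatrix& pts, int i, int& ix, int& iy, int& iz) const {
    ix = (int)std::floor((pts(i, 0) - ox) / cell);
    iy = (int)std::floor((pts(i, 1) - oy) / cell);
    iz = (int)std::floor((pts(i, 2) - oz) / cell);
  }
};

inline double sqdist(const NumericMatrix& p, int i, int j) {
  double dx = p(i, 0) - p(j, 0), dy = p(i, 1) - p(j, 1), dz = p(i, 2) - p(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// [[Rcpp::export(name = ".euclidean_cluster_cpp")]]
IntegerVector euclidean_cluster_cpp(NumericMatrix pts, double eps) {
  int n = pts.nrow();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid g;
  g.build(pts, eps);
  double eps2 = eps * eps;
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int cx, cy, cz;
      g.cell_of(pts, i, cx, cy, cz);
      for (int ix = cx - 1; ix <= cx + 1; ++ix)
        for (int iy = cy - 1; iy <= cy + 1; ++iy)
          for (int iz = cz - 1; iz <= cz + 1; ++iz) {
            auto it = g.cells.find(Grid::key(ix, iy, iz));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              if (labels[j] != 0) continue;
              if (sqdist(pts, i, j) <= eps2) {
                labels[j] = next;
                stack.push_back(j);
              }
            }
          }
    }
  }
  return labels;
}
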