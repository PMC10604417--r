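// Density-based clustering of voxel point clouds (DBSCAN).
// A point is a core point if its closed eps-ball contains >= min_pts points
// (the point itself included). Clusters are grown by breadth-first expansion
// through core points in ascending index order, so the labelling is fully
// deterministic for a given point order.
#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <cmath>
using namespace Rcpp;

static inline long long cell_key(int a, int b, int c) {
  // pack three signed cell indices (each fits easily in 21 bits here)
  return (((long long)(a + 1048576)) << 42) |
         (((long long)(b + 1048576)) << 21) | (long long)(c + 1048576);
}

// [[Rcpp::export(name = ".dbscan_points")]]
IntegerVector dbscan_points(const NumericMatrix &pts, double eps,
                            int min_pts) {
  const int n = pts.nrow();
  IntegerVector labels(n, 0); // 0 = noise/unassigned
  if (n == 0) return labels;
  const double eps2 = eps * eps;

  // spatial hash with cell edge = eps: all neighbours lie in the 27 cells
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve((size_t)n);
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(pts(i, 0) / eps);
    cy[i] = (int)std::floor(pts(i, 1) / eps);
    cz[i] = (int)std::floor(pts(i, 2) / eps);
    grid[cell_key(cx[i], cy[i], cz[i])].push_back(i);
  }

  std::vector<int> nbr;
  auto neighbours = [&](int i) {
    nbr.clear();
    for (int a = cx[i] - 1; a <= cx[i] + 1; ++a)
      for (int b = cy[i] - 1; b <= cy[i] + 1; ++b)
        for (int c = cz[i] - 1; c <= cz[i] + 1; ++c) {
          auto it = grid.find(cell_key(a, b, c));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double dx = pts(i, 0) - pts(j, 0);
            const double dy = pts(i, 1) - pts(j, 1);
            const double dz = pts(i, 2) - pts(j, 2);
            if (dx * dx + dy * dy + dz * dz <= eps2) nbr.push_back(j);
          }
        }
    std::sort(nbr.begin(), nbr.end());
  };

  std::vector<char> visited(n, 0);
  int ncl = 0;
  std::deque<int> queue;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = 1;
    neighbours(i);
    if ((int)nbr.size() < min_pts) continue; // noise (may become border later)
    ++ncl;
    labels[i] = ncl;
    queue.assign(nbr.begin(), nbr.end());
    while (!queue.empty()) {
      const int j = queue.front();
      queue.pop_front();
      if (labels[j] == 0) labels[j] = ncl; // border or core, first claim wins
      if (visited[j]) continue;
      visited[j] = 1;
      neighbours(j);
      if ((int)nbr.size() >= min_pts)
        queue.insert(queue.end(), nbr.begin(), nbr.end());
    }
  }
  return labels;
}
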