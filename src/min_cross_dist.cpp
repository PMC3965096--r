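#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Minimum Euclidean distance between two point clouds (n x 3 matrices),
// via a uniform-grid cell list over B with expanding-shell queries from
// each point of A. Exact: pruning uses the conservative bound that any
// point in a cell at Chebyshev shell k from the query cell is at least
// (k-1)*h away.
// [[Rcpp::export]]
double cpp_min_cross_distance(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0 || nb == 0)
    stop("both chains must have at least one point");

  // bounding box of B
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nb; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = B(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }

  // uniform cell size: target ~cbrt(nb) cells per dimension, capped
  double maxext = 0.0;
  for (int d = 0; d < 3; ++d) maxext = std::max(maxext, hi[d] - lo[d]);
  int m = std::max(1, std::min(48, (int)std::floor(std::cbrt((double)nb))));
  // lower bound on the cell size keeps indices sane for degenerate
  // (near-zero-extent) point sets and far-away query points
  double h = std::max(maxext / m, 1.0);

  int nc[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
  }
  const long long ncells = (long long)nc[0] * nc[1] * nc[2];
  std::vector< std::vector<int> > cells((size_t)ncells);
  std::vector<int> ci(nb), cj(nb), ck(nb);
  for (int i = 0; i < nb; ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int cc = (int)std::floor((B(i, d) - lo[d]) / h);
      if (cc < 0) cc = 0;
      if (cc >= nc[d]) cc = nc[d] - 1;
      c[d] = cc;
    }
    cells[(size_t)(c[0] + (long long)nc[0] * (c[1] + (long long)nc[1] * c[2]))]
        .push_back(i);
  }

  double best2 = std::numeric_limits<double>::infinity();

  for (int i = 0; i < na; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    // query cell (may lie outside the grid; clamp only for shell bounds)
    int q[3];
    for (int d = 0; d < 3; ++d) {
      double qc = std::floor((A(i, d) - lo[d]) / h);
      if (qc < -1e6) qc = -1e6;      // clamping only loosens the shell
      if (qc > 1e6) qc = 1e6;        // bound, which stays conservative
      q[d] = (int)qc;
    }
    // max Chebyshev shell needed to have covered the entire grid
    int kmax = 0;
    for (int d = 0; d < 3; ++d)
      kmax = std::max(kmax, std::max(q[d] - 0, (nc[d] - 1) - q[d]));
    kmax = std::max(kmax, 0);

    for (int k = 0; k <= kmax; ++k) {
      // prune: nothing in shell >= k can beat the current best
      if (k > 0) {
        double bound = (double)(k - 1) * h;
        if (bound * bound > best2) break;
      }
      for (int dx = -k; dx <= k; ++dx) {
        int x = q[0] + dx;
        if (x < 0 || x >= nc[0]) continue;
        for (int dy = -k; dy <= k; ++dy) {
          int y = q[1] + dy;
          if (y < 0 || y >= nc[1]) continue;
          bool face_xy = (std::abs(dx) == k) || (std::abs(dy) == k);
          for (int dz = -k; dz <= k; ++dz) {
            // only the surface of the shell (interior seen at smaller k)
            if (!face_xy && std::abs(dz) != k) continue;
            int z = q[2] + dz;
            if (z < 0 || z >= nc[2]) continue;
            const std::vector<int>& cell =
              cells[(size_t)(x + (long long)nc[0] * (y + (long long)nc[1] * z))];
            for (size_t t = 0; t < cell.size(); ++t) {
              int j = cell[t];
              double ddx = ax - B(j, 0), ddy = ay - B(j, 1), ddz = az - B(j, 2);
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best2) best2 = d2;
            }
          }
        }
      }
      if (best2 == 0.0) break;
    }
  }
  return std::sqrt(best2);
}
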