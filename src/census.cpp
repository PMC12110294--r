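#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Vietoris-Rips k-simplexes at a fixed epsilon are exactly the (k+1)-cliques
// of the epsilon-neighborhood graph, so the census reduces to edge, triangle
// and (optionally) 4-clique counting. Pairs are enumerated through a uniform
// grid of cell size epsilon (only the 3^d neighboring cells can hold a point
// within epsilon); cliques are counted on sorted forward-adjacency lists.

namespace {

struct KeyHash {
  std::size_t operator()(const std::vector<int>& k) const {
    std::size_t h = 1469598103934665603ULL;
    for (int v : k) {
      h ^= static_cast<std::size_t>(static_cast<uint32_t>(v));
      h *= 1099511628211ULL;
    }
    return h;
  }
};

inline double sq_dist(const NumericMatrix& pts, int i, int j, int d) {
  double s = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = pts(i, c) - pts(j, c);
    s += diff * diff;
  }
  return s;
}

// neighbours with index > i, sorted, using squared distances (<= eps^2, closed ball)
std::vector<std::vector<int>> forward_adjacency(const NumericMatrix& pts,
                                                double eps) {
  const int n = pts.nrow(), d = pts.ncol();
  const double eps2 = eps * eps;

  std::unordered_map<std::vector<int>, std::vector<int>, KeyHash> grid;
  grid.reserve(static_cast<std::size_t>(n) * 2);
  std::vector<std::vector<int>> cell_of(n, std::vector<int>(d));
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < d; ++c)
      cell_of[i][c] = static_cast<int>(std::floor(pts(i, c) / eps));
    grid[cell_of[i]].push_back(i);
  }

  std::vector<std::vector<int>> fadj(n);
  std::vector<int> probe(d);
  for (int i = 0; i < n; ++i) {
    // walk the 3^d neighbouring cells
    std::vector<int> offs(d, -1);
    while (true) {
      for (int c = 0; c < d; ++c) probe[c] = cell_of[i][c] + offs[c];
      auto it = grid.find(probe);
      if (it != grid.end()) {
        for (int j : it->second) {
          if (j > i && sq_dist(pts, i, j, d) <= eps2) fadj[i].push_back(j);
        }
      }
      int c = 0;
      for (; c < d; ++c) {
        if (offs[c] < 1) { ++offs[c]; break; }
        offs[c] = -1;
      }
      if (c == d) break;
    }
    std::sort(fadj[i].begin(), fadj[i].end());
  }
  return fadj;
}

} // namespace

// [[Rcpp::export(name = ".census_counts")]]
NumericVector census_counts(NumericMatrix pts, double eps, int K) {
  const int n = pts.nrow();
  std::vector<std::vector<int>> fadj = forward_adjacency(pts, eps);

  double n_edge = 0.0, n_tri = 0.0, n_tet = 0.0;
  for (int i = 0; i < n; ++i) n_edge += fadj[i].size();

  if (K >= 2) {
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& Ni = fadj[i];
      for (std::size_t a = 0; a < Ni.size(); ++a) {
        int j = Ni[a];
        const std::vector<int>& Nj = fadj[j];
        // |{k > j} in Ni  intersect  Nj|, two-pointer merge
        std::size_t p = a + 1, q = 0;
        std::vector<int> common;
        while (p < Ni.size() && q < Nj.size()) {
          if (Ni[p] < Nj[q]) ++p;
          else if (Ni[p] > Nj[q]) ++q;
          else { common.push_back(Ni[p]); ++p; ++q; }
        }
        n_tri += common.size();
        if (K >= 3 && common.size() >= 2) {
          // 4-cliques {i<j<c1<c2}: pairs of common neighbours that are adjacent
          for (std::size_t u = 0; u + 1 < common.size(); ++u) {
            const std::vector<int>& Nu = fadj[common[u]];
            for (std::size_t v = u + 1; v < common.size(); ++v) {
              if (std::binary_search(Nu.begin(), Nu.end(), common[v])) n_tet += 1.0;
            }
          }
        }
      }
    }
  }

  NumericVector out(K + 1);
  out[0] = n;
  if (K >= 1) out[1] = n_edge;
  if (K >= 2) out[2] = n_tri;
  if (K >= 3) out[3] = n_tet;
  return out;
}
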