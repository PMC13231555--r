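#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// Distance-ordered homotopic thinning producing a 1-voxel curve skeleton.
//
// Border voxels are eroded in increasing order of their Euclidean distance
// transform value (ties by linear index, so the result is deterministic),
// subject to two guards:
//   * topology: only "simple" points are removed, where simplicity uses the
//     standard 26-connectivity for foreground / 6-connectivity for
//     background characterization (Malandain & Bertrand);
//   * geometry: curve endpoints (voxels with at most one foreground
//     26-neighbour) are never removed, so centerlines keep their length.
// Eroding thin-first (low EDT) keeps the surviving curve on the medial axis.

namespace {

struct QItem {
  double key;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.key != b.key) return a.key > b.key;   // min-heap on EDT
    return a.idx > b.idx;                        // then on linear index
  }
};

int NX, NY, NZ;

inline bool inside(int x, int y, int z) {
  return x >= 0 && x < NX && y >= 0 && y < NY && z >= 0 && z < NZ;
}
inline R_xlen_t lin(int x, int y, int z) {
  return x + (R_xlen_t)NX * (y + (R_xlen_t)NY * z);
}

// Extract the 3x3x3 neighbourhood of p as 27 flags (center position 13).
// Out-of-grid counts as background.
inline void neighbourhood(const std::vector<uint8_t>& fg, int x, int y, int z,
                          uint8_t nb[27]) {
  int t = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++t) {
        const int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[t] = inside(xx, yy, zz) ? fg[lin(xx, yy, zz)] : 0;
      }
}

// Number of 26-connected foreground components among the 26 neighbours.
int n26_components(const uint8_t nb[27]) {
  uint8_t seen[27];
  std::memset(seen, 0, 27);
  int comps = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack{s};
    seen[s] = 1;
    while (!stack.empty()) {
      const int c = stack.back(); stack.pop_back();
      const int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            const int nx2 = cx + dx, ny2 = cy + dy, nz2 = cz + dz;
            if (nx2 < 0 || nx2 > 2 || ny2 < 0 || ny2 > 2 ||
                nz2 < 0 || nz2 > 2) continue;
            const int t = nx2 + 3 * ny2 + 9 * nz2;
            if (t == 13 || !nb[t] || seen[t]) continue;
            seen[t] = 1;
            stack.push_back(t);
          }
    }
  }
  return comps;
}

// Number of 6-connected background components within the 18-neighbourhood
// that touch the center by a face (seeded from the 6 face neighbours).
int n6_background_components(const uint8_t nb[27]) {
  static const int face[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  uint8_t seen[27];
  std::memset(seen, 0, 27);
  int comps = 0;
  for (int fi = 0; fi < 6; ++fi) {
    const int s = face[fi];
    if (nb[s] || seen[s]) continue;
    ++comps;
    std::vector<int> stack{s};
    seen[s] = 1;
    while (!stack.empty()) {
      const int c = stack.back(); stack.pop_back();
      const int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int step[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        const int nx2 = cx + step[k][0], ny2 = cy + step[k][1], nz2 = cz + step[k][2];
        if (nx2 < 0 || nx2 > 2 || ny2 < 0 || ny2 > 2 || nz2 < 0 || nz2 > 2)
          continue;
        // restrict to the 18-neighbourhood: at most two coords differ from 1
        if ((nx2 != 1) + (ny2 != 1) + (nz2 != 1) > 2) continue;
        const int t = nx2 + 3 * ny2 + 9 * nz2;
        if (t == 13 || nb[t] || seen[t]) continue;
        seen[t] = 1;
        stack.push_back(t);
      }
    }
  }
  return comps;
}

inline bool is_simple(const uint8_t nb[27]) {
  return n26_components(nb) == 1 && n6_background_components(nb) == 1;
}

inline int count_fg_neighbours26(const uint8_t nb[27]) {
  int c = 0;
  for (int t = 0; t < 27; ++t) if (t != 13 && nb[t]) ++c;
  return c;
}

inline bool is_border(const std::vector<uint8_t>& fg, int x, int y, int z) {
  static const int step[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  for (int k = 0; k < 6; ++k) {
    const int xx = x + step[k][0], yy = y + step[k][1], zz = z + step[k][2];
    if (!inside(xx, yy, zz) || !fg[lin(xx, yy, zz)]) return true;
  }
  return false;
}

}  // namespace

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalVector thin_cpp(IntegerVector fg_in, IntegerVector dims,
                       NumericVector edt_sq) {
  NX = dims[0]; NY = dims[1]; NZ = dims[2];
  const R_xlen_t n = (R_xlen_t)NX * NY * NZ;
  std::vector<uint8_t> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = fg_in[i] ? 1 : 0;

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  std::vector<uint8_t> queued(n, 0);

  for (int z = 0; z < NZ; ++z)
    for (int y = 0; y < NY; ++y)
      for (int x = 0; x < NX; ++x) {
        const R_xlen_t i = lin(x, y, z);
        if (fg[i] && is_border(fg, x, y, z)) {
          pq.push({edt_sq[i], i});
          queued[i] = 1;
        }
      }

  uint8_t nb[27];
  while (!pq.empty()) {
    const QItem it = pq.top(); pq.pop();
    const R_xlen_t i = it.idx;
    queued[i] = 0;
    if (!fg[i]) continue;
    const int x = (int)(i % NX), y = (int)((i / NX) % NY), z = (int)(i / ((R_xlen_t)NX * NY));
    if (!is_border(fg, x, y, z)) continue;
    neighbourhood(fg, x, y, z, nb);
    if (count_fg_neighbours26(nb) <= 1) continue;  // endpoint or isolated
    if (!is_simple(nb)) continue;
    fg[i] = 0;                                     // erode
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          const int xx = x + dx, yy = y + dy, zz = z + dz;
          if (!inside(xx, yy, zz)) continue;
          const R_xlen_t j = lin(xx, yy, zz);
          if (fg[j] && !queued[j]) {
            pq.push({edt_sq[j], j});
            queued[j] = 1;
          }
        }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}
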