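#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Constrained nearest-neighbour radius propagation.
//
// For a non-centerline foreground voxel v the admissible candidates are the
// centerline points c with dist(v, c) < radius(c) (strict, physical mm).
// Among them the geometrically closest wins; with no candidate the globally
// nearest centerline point is used as a flagged fallback. Ties on distance
// prefer the larger radius, then the smaller centerline list position
// (centerline points are supplied in increasing linear-index order).
//
// A uniform bucket grid over the centerline points accelerates the search;
// distance arithmetic is ordered identically to the plain R reference scan
// (((dx*sx)^2 + (dy*sy)^2) + (dz*sz)^2) so results are bit-identical.

namespace {

struct Best {
  double d2 = R_PosInf;
  double r = -1.0;
  int j = -1;  // centerline list position
};

inline void consider(Best& b, double d2, double r, int j) {
  if (d2 < b.d2 || (d2 == b.d2 && (r > b.r || (r == b.r && j < b.j)))) {
    b.d2 = d2; b.r = r; b.j = j;
  }
}

}  // namespace

// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(IntegerMatrix vox,      // n x 3, 0-based voxel indices
                   IntegerMatrix cl,       // m x 3, 0-based centerline indices
                   NumericVector cl_radius,
                   NumericVector spacing,
                   IntegerVector is_centerline  // length n, 1 if vox is a cl point
) {
  const int n = vox.nrow(), m = cl.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector radius(n);
  IntegerVector provenance(n);  // 1 centerline, 2 constrained, 3 fallback
  IntegerVector source(n);      // 1-based centerline list position

  // physical coordinates of centerline points
  std::vector<double> cx(m), cy(m), cz(m);
  double rmax = 0.0;
  for (int j = 0; j < m; ++j) {
    cx[j] = cl(j, 0) * sx;
    cy[j] = cl(j, 1) * sy;
    cz[j] = cl(j, 2) * sz;
    if (cl_radius[j] > rmax) rmax = cl_radius[j];
  }

  // bucket grid with cell edge h
  const double h = std::max(sx, std::max(sy, sz));
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(2 * m);
  auto cell_of = [&](double x, double y, double z) {
    const long long ix = (long long)std::floor(x / h);
    const long long iy = (long long)std::floor(y / h);
    const long long iz = (long long)std::floor(z / h);
    return (ix * 73856093LL) ^ (iy * 19349663LL) ^ (iz * 83492791LL);
  };
  std::vector<long long> kx(m), ky(m), kz(m);
  for (int j = 0; j < m; ++j) {
    kx[j] = (long long)std::floor(cx[j] / h);
    ky[j] = (long long)std::floor(cy[j] / h);
    kz[j] = (long long)std::floor(cz[j] / h);
    grid[(kx[j] * 73856093LL) ^ (ky[j] * 19349663LL) ^ (kz[j] * 83492791LL)]
        .push_back(j);
  }
  // max Chebyshev cell extent ever needed: whole point cloud
  long long minx = 0, maxx = 0, miny = 0, maxy = 0, minz = 0, maxz = 0;
  if (m > 0) {
    minx = maxx = kx[0]; miny = maxy = ky[0]; minz = maxz = kz[0];
    for (int j = 1; j < m; ++j) {
      minx = std::min(minx, kx[j]); maxx = std::max(maxx, kx[j]);
      miny = std::min(miny, ky[j]); maxy = std::max(maxy, ky[j]);
      minz = std::min(minz, kz[j]); maxz = std::max(maxz, kz[j]);
    }
  }

  for (int i = 0; i < n; ++i) {
    if (is_centerline[i]) continue;  // handled by the caller
    const double vx = vox(i, 0) * sx, vy = vox(i, 1) * sy, vz = vox(i, 2) * sz;
    const long long vcx = (long long)std::floor(vx / h);
    const long long vcy = (long long)std::floor(vy / h);
    const long long vcz = (long long)std::floor(vz / h);

    Best constrained, nearest;
    const long long maxring =
        std::max({std::llabs(vcx - minx), std::llabs(maxx - vcx),
                  std::llabs(vcy - miny), std::llabs(maxy - vcy),
                  std::llabs(vcz - minz), std::llabs(maxz - vcz)});
    for (long long ring = 0; ring <= maxring; ++ring) {
      // lower bound on distance to any point in a ring-`ring` cell
      const double lb = (ring > 0) ? (ring - 1) * h : 0.0;
      const double lb2 = lb * lb;
      const bool need_constrained =
          constrained.j < 0 ? (lb2 < rmax * rmax) : (lb2 <= constrained.d2);
      const bool need_nearest = nearest.j < 0 || lb2 <= nearest.d2;
      if (!need_constrained && !need_nearest) break;

      for (long long dz = -ring; dz <= ring; ++dz)
        for (long long dy = -ring; dy <= ring; ++dy)
          for (long long dx = -ring; dx <= ring; ++dx) {
            if (std::max({std::llabs(dx), std::llabs(dy), std::llabs(dz)}) != ring)
              continue;
            auto it = grid.find(((vcx + dx) * 73856093LL) ^
                                ((vcy + dy) * 19349663LL) ^
                                ((vcz + dz) * 83492791LL));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              // guard against hash collisions: check true cell
              if (kx[j] != vcx + dx || ky[j] != vcy + dy || kz[j] != vcz + dz)
                continue;
              const double ddx = (vox(i, 0) - cl(j, 0)) * sx;
              const double ddy = (vox(i, 1) - cl(j, 1)) * sy;
              const double ddz = (vox(i, 2) - cl(j, 2)) * sz;
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              consider(nearest, d2, cl_radius[j], j);
              if (d2 < cl_radius[j] * cl_radius[j])
                consider(constrained, d2, cl_radius[j], j);
            }
          }
    }

    if (constrained.j >= 0) {
      radius[i] = constrained.r;
      provenance[i] = 2;
      source[i] = constrained.j + 1;
    } else {
      radius[i] = nearest.r;
      provenance[i] = 3;
      source[i] = nearest.j + 1;
    }
  }

  return List::create(_["radius"] = radius, _["provenance"] = provenance,
                      _["source"] = source);
}
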