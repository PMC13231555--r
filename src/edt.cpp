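#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Large finite stand-in for "no background seen yet": keeps the parabola
// intersection arithmetic finite on all-foreground scan lines.
static const double BIG = 1e20;
static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (lower envelope of parabolas) with sample
// spacing w. f holds squared distances; d receives the transformed row.
static void dt1d(const std::vector<double>& f, double w,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& z) {
  const int n = (int)f.size();
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * (double)v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = (q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel center to the
// nearest background voxel center, honouring anisotropic spacing.
// fg: 0/1 grid in R's column-major layout. Background voxels get 0.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i] ? BIG : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      f.assign(out.begin() + base, out.begin() + base + nx);
      dt1d(f, spacing[0], d, v, z);
      std::copy(d.begin(), d.begin() + nx, out.begin() + base);
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      f.resize(ny);
      for (int j = 0; j < ny; ++j)
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      f.resize(nz);
      for (int k = 0; k < nz; ++k)
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  return out;
}
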