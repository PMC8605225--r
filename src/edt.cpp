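#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// generalized to anisotropic sample spacing. Distances are in physical mm^2
// between voxel centers. Voxels with no seed anywhere stay at a large
// sentinel which the R side maps to Inf.

static const double SENTINEL = 1e20;

// 1D lower envelope of parabolas rooted at (i*s, f[i]).
static void dt1d(const double *f, double *d, int n, double s,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sep;
    while (true) {
      double ps = v[k] * s;
      sep = ((f[q] + qs * qs) - (f[v[k]] + ps * ps)) / (2.0 * (qs - ps));
      if (sep > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double diff = qs - v[k] * s;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector occ, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (occ.size() != n) stop("occupancy length does not match dims");
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = occ[i] ? 0.0 : SENTINEL;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = d[base + i];
      dt1d(f.data(), g.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) d[base + i] = g[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = d[base + (R_xlen_t)nx * j];
      dt1d(f.data(), g.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = g[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = d[base + nxy * k];
      dt1d(f.data(), g.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) d[base + nxy * k] = g[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (d[i] >= 1e19) d[i] = R_PosInf;
  return d;
}
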