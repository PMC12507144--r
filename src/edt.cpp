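#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher 2012) with sample spacing h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double h2 = h * h;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (k > 0 && s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    const double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared distance from every voxel to the nearest TRUE voxel of `mask`,
// on an axis-aligned grid with per-axis spacing (same length unit as the
// returned distances). Column-major [nx, ny, nz].
// [[Rcpp::export(name = ".edt3_sq")]]
NumericVector edt3_sq(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (mask.size() != ntot) stop("mask length does not match dims");
  // large finite sentinel: infinities break the parabola-intersection
  // arithmetic (INF - INF)
  const double diag = nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  const double BIG = 4.0 * diag * diag;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      const R_xlen_t base = (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  }
  // pass along y
  for (int k = 0; k < nz; k++) {
    for (int i = 0; i < nx; i++) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)k * nx * ny;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }
  }
  // pass along z
  const R_xlen_t strz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++) {
    for (int i = 0; i < nx; i++) {
      const R_xlen_t base = (R_xlen_t)i + (R_xlen_t)j * nx;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * strz];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * strz] = d[k];
    }
  }
  return out;
}
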