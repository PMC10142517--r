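#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. `f` holds squared distances so far; grid
// step is `s` (mm), so the parabola at cell q is f[q] + s^2 (x - q)^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double sep;
    for (;;) {
      if (f[v[k]] == INF) { // first finite parabola dominates everywhere
        --k;
        if (k < 0) break;
        continue;
      }
      sep = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
            (2.0 * s2 * (q - v[k]));
      if (sep <= z[k]) { --k; if (k < 0) break; } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = sep; z[k + 1] = INF;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    if (f[v[k]] == INF) d[q] = INF;
    else d[q] = s2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exterior Euclidean distance (mm) from each voxel center to the nearest
// voxel center inside `mask`, honoring anisotropic spacing; 0 inside.
// [[Rcpp::export(name = ".edtExterior")]]
NumericVector edt_exterior(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  // pass along x (fastest-varying index)
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        bool any = false;
        for (int x = 0; x < nx; ++x) { f[x] = g[base + x]; if (f[x] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) g[base + x] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        bool any = false;
        for (int y = 0; y < ny; ++y) { f[y] = g[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        bool any = false;
        for (int z = 0; z < nz; ++z) { f[z] = g[base + z * stride]; if (f[z] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) g[base + z * stride] = d[z];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  return out;
}
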