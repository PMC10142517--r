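#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Inverse-square point-kernel superposition over the full voxel lattice:
// dose(v) = sum_i w_i * k / max(r_vi, r_min)^2, distances in mm. Voxel
// centers sit at origin + index * spacing (0-based indices).
// [[Rcpp::export(name = ".doseKernel")]]
NumericVector dose_kernel(IntegerVector dim, NumericVector spacing,
                          NumericVector origin, NumericMatrix dwell_mm,
                          NumericVector weights, double kernel_constant,
                          double r_min_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int nd = dwell_mm.nrow();
  if (weights.size() != nd) stop("weights length must match dwell count");
  NumericVector out(n); // zero-initialized
  const double rmin2 = r_min_mm * r_min_mm;
  for (int i = 0; i < nd; ++i) {
    const double px = dwell_mm(i, 0), py = dwell_mm(i, 1), pz = dwell_mm(i, 2);
    const double wk = weights[i] * kernel_constant;
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z) {
      const double dz = origin[2] + z * spacing[2] - pz;
      for (int y = 0; y < ny; ++y) {
        const double dy = origin[1] + y * spacing[1] - py;
        const double d2yz = dz * dz + dy * dy;
        for (int x = 0; x < nx; ++x, ++idx) {
          const double dx = origin[0] + x * spacing[0] - px;
          double r2 = d2yz + dx * dx;
          if (r2 < rmin2) r2 = rmin2;
          out[idx] += wk / r2;
        }
      }
    }
  }
  return out;
}
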