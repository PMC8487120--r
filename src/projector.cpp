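#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam ray caster over an axis-aligned integer label grid.
// For each detector pixel center the ray  p(s) = u*U + v*V + s*ray  is
// sampled at spacing `step` with nearest-neighbor voxel lookup. Sample
// positions lie on an absolute lattice of multiples of `step` along the ray
// (anchored at s = 0, not at the volume surface), so translating the scene
// along the ray by a multiple of `step` reproduces the identical sample
// pattern and hence a bit-identical mask. Rays are clipped to the bounding
// box of the voxels of interest (slab test), which only discards samples
// that could not hit.
//
// mode 0 (silhouette): pixel is 1 iff any sample hits a voxel with value
//   `label` (early exit).
// mode 1 (thickness): pixel value = step * number of samples with value > 0,
//   i.e. the foreground path length in mm.
// [[Rcpp::export]]
NumericMatrix cpp_cast_rays(IntegerVector vol, IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            int label, NumericVector ray, NumericVector U,
                            NumericVector V, NumericVector det0,
                            double pixelSize, int nu, int nv, double step,
                            int mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *v = INTEGER(vol);
  NumericMatrix out(nu, nv);

  // tight index-space bounding box of the voxels of interest
  int blo[3] = {nx, ny, nz}, bhi[3] = {-1, -1, -1};
  {
    size_t idx = 0;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          const int val = v[idx];
          const bool hit = (mode == 0) ? (val == label) : (val > 0);
          if (hit) {
            if (ix < blo[0]) blo[0] = ix;
            if (iy < blo[1]) blo[1] = iy;
            if (iz < blo[2]) blo[2] = iz;
            if (ix > bhi[0]) bhi[0] = ix;
            if (iy > bhi[1]) bhi[1] = iy;
            if (iz > bhi[2]) bhi[2] = iz;
          }
        }
  }
  if (bhi[0] < 0) return out;  // nothing to project

  // box in mm (outer faces of the bounding voxels)
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = origin[k] + (blo[k] - 0.5) * spacing[k];
    hi[k] = origin[k] + (bhi[k] + 0.5) * spacing[k];
  }

  for (int j = 0; j < nv; ++j) {
    const double vc = det0[1] + (j + 0.5) * pixelSize;
    for (int i = 0; i < nu; ++i) {
      const double uc = det0[0] + (i + 0.5) * pixelSize;
      const double b[3] = {uc * U[0] + vc * V[0], uc * U[1] + vc * V[1],
                           uc * U[2] + vc * V[2]};
      // slab clipping of  b + s*ray  against the box
      double s0 = R_NegInf, s1 = R_PosInf;
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        if (ray[k] == 0.0) {
          if (b[k] < lo[k] || b[k] > hi[k]) { miss = true; break; }
        } else {
          double ta = (lo[k] - b[k]) / ray[k];
          double tb = (hi[k] - b[k]) / ray[k];
          if (ta > tb) std::swap(ta, tb);
          if (ta > s0) s0 = ta;
          if (tb < s1) s1 = tb;
        }
      }
      if (miss || s0 > s1) continue;
      const long k0 = (long)std::floor(s0 / step) - 1;
      const long k1 = (long)std::ceil(s1 / step) + 1;
      long hits = 0;
      for (long k = k0; k <= k1; ++k) {
        const double s = k * step;
        const int ix = (int)std::lround((b[0] + s * ray[0] - origin[0]) / spacing[0]);
        if (ix < 0 || ix >= nx) continue;
        const int iy = (int)std::lround((b[1] + s * ray[1] - origin[1]) / spacing[1]);
        if (iy < 0 || iy >= ny) continue;
        const int iz = (int)std::lround((b[2] + s * ray[2] - origin[2]) / spacing[2]);
        if (iz < 0 || iz >= nz) continue;
        const int val = v[(size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz)];
        if (mode == 0) {
          if (val == label) { hits = 1; break; }
        } else {
          if (val > 0) ++hits;
        }
      }
      out(i, j) = (mode == 0) ? (double)hits : step * (double)hits;
    }
  }
  return out;
}
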