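// Volume-domain kernels for the acquisition simulator: exact parity
// voxelization of a closed mesh and separable Gaussian blur (the point-spread
// stand-in for partial-volume averaging).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian blur, sigma per axis in voxel units, reflected borders,
// kernel truncated at 3 sigma. Volume is laid out x-fastest (R array order).
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector vals, int nx, int ny, int nz,
                                NumericVector sigma_vox) {
  std::vector<double> buf(vals.begin(), vals.end());
  std::vector<double> tmp(buf.size());
  const int n[3] = {nx, ny, nz};
  const int64_t stride[3] = {1, nx, (int64_t)nx * ny};

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      kern[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += kern[i + r];
    }
    for (auto& k : kern) k /= sum;

    int na = n[axis];
    int64_t sa = stride[axis];
    // iterate over all lines along `axis`
    int b1 = (axis + 1) % 3, b2 = (axis + 2) % 3;
    for (int j2 = 0; j2 < n[b2]; ++j2) {
      for (int j1 = 0; j1 < n[b1]; ++j1) {
        int64_t base = (int64_t)j1 * stride[b1] + (int64_t)j2 * stride[b2];
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int src = i + t;
            if (src < 0) src = -src - 1;           // reflect
            if (src >= na) src = 2 * na - src - 1;
            acc += kern[t + r] * buf[base + (int64_t)src * sa];
          }
          tmp[base + (int64_t)i * sa] = acc;
        }
      }
    }
    std::swap(buf, tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Binary occupancy of the interior of a closed triangle mesh, by parity of
// x-ray crossings through each (y, z) voxel-column. Triangles are binned by
// their (y, z) bounding rectangle so each column only tests nearby faces.
// A deterministic sub-nanometre ray offset avoids exact edge/vertex hits.
// [[Rcpp::export]]
NumericVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nf = F.nrow();
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const double epsy = 1e-7 * dy, epsz = 1e-7 * dz;  // degeneracy offset

  // bin triangles into (j, k) column ranges
  std::vector<std::vector<int>> bins((size_t)ny * nz);
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ylo = std::min({V(a, 1), V(b, 1), V(c, 1)});
    double yhi = std::max({V(a, 1), V(b, 1), V(c, 1)});
    double zlo = std::min({V(a, 2), V(b, 2), V(c, 2)});
    double zhi = std::max({V(a, 2), V(b, 2), V(c, 2)});
    int j0 = std::max(0, (int)std::ceil((ylo - oy - epsy) / dy - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - oy - epsy) / dy + 1e-9));
    int k0 = std::max(0, (int)std::ceil((zlo - oz - epsz) / dz - 1e-9));
    int k1 = std::min(nz - 1, (int)std::floor((zhi - oz - epsz) / dz + 1e-9));
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        bins[(size_t)k * ny + j].push_back(f);
  }

  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> xs;
  for (int k = 0; k < nz; ++k) {
    double rz = oz + k * dz + epsz;
    for (int j = 0; j < ny; ++j) {
      double ry = oy + j * dy + epsy;
      const std::vector<int>& cand = bins[(size_t)k * ny + j];
      xs.clear();
      for (int f : cand) {
        int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
        double ay = V(a, 1) - ry, az = V(a, 2) - rz;
        double by = V(b, 1) - ry, bz = V(b, 2) - rz;
        double cy = V(c, 1) - ry, cz = V(c, 2) - rz;
        // 2D edge functions in the (y, z) projection
        double w0 = by * cz - bz * cy;
        double w1 = cy * az - cz * ay;
        double w2 = ay * bz - az * by;
        bool pos = (w0 > 0 && w1 > 0 && w2 > 0);
        bool neg = (w0 < 0 && w1 < 0 && w2 < 0);
        if (!pos && !neg) continue;
        double wsum = w0 + w1 + w2;
        double x = (w0 * V(a, 0) + w1 * V(b, 0) + w2 * V(c, 0)) / wsum;
        xs.push_back(x);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // walk voxel centres; inside when an odd number of crossings lie beyond
      size_t ci = 0;
      int64_t base = (int64_t)j * nx + (int64_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) {
        double x = ox + i * dx;
        while (ci < xs.size() && xs[ci] <= x) ++ci;
        if ((xs.size() - ci) % 2 == 1) out[base + i] = 1.0;
      }
    }
  }
  return out;
}
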