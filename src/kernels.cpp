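#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All 3D arrays use R's column-major layout with dim = (nz, ny, nx):
// linear index = z + nz * (y + ny * x), zero-based here.
// Voxel centres sit at ((i + 0.5) * pitch) in micrometres, i zero-based.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Neighbour offsets for 6/18/26-connectivity.
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off = conn_offsets(connectivity);
  std::vector<int> stack;
  stack.reserve(1024);
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back((int)start);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v / (nz * ny);
      int rem = v - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        int w = idx3(zz, yy, xx, nz, ny);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n") = current;
  return labels;
}

// Separable 1D convolution along one axis (0 = z, 1 = y, 2 = x) with
// reflected boundaries. Kernel is assumed symmetric-normalised by the
// caller. The array is viewed as (inner, len, outer) blocks so the hot loop
// always runs over contiguous memory.
// [[Rcpp::export(name = ".conv_axis_3d")]]
NumericVector conv_axis_3d(NumericVector x, IntegerVector dims, NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int kl = kernel.size();
  const int half = (kl - 1) / 2;
  NumericVector out(x.size());
  const int len = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  const R_xlen_t inner = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nz : (R_xlen_t)nz * ny;
  const R_xlen_t outer = x.size() / ((R_xlen_t)len * inner);
  const double *xp = x.begin();
  double *op = out.begin();
  std::vector<int> src(kl);
  for (R_xlen_t o = 0; o < outer; ++o) {
    const R_xlen_t base = o * inner * len;
    for (int t = 0; t < len; ++t) {
      for (int k = 0; k < kl; ++k) {
        int s = t + k - half;
        if (s < 0) s = -s - 1;
        if (s >= len) s = 2 * len - s - 1;
        if (s < 0) s = 0;
        if (s >= len) s = len - 1;
        src[k] = s;
      }
      double *od = op + base + (R_xlen_t)t * inner;
      if (inner == 1) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) acc += kernel[k] * xp[base + src[k]];
        od[0] = acc;
      } else {
        const double k0 = kernel[0];
        const double *s0 = xp + base + (R_xlen_t)src[0] * inner;
        for (R_xlen_t i = 0; i < inner; ++i) od[i] = k0 * s0[i];
        for (int k = 1; k < kl; ++k) {
          const double kk = kernel[k];
          const double *sp = xp + base + (R_xlen_t)src[k] * inner;
          for (R_xlen_t i = 0; i < inner; ++i) od[i] += kk * sp[i];
        }
      }
    }
  }
  return out;
}

// Binary morphology over an explicit offset neighbourhood.
// dilate: scatter from foreground voxels (out-of-bounds ignored);
// erode:  foreground voxel survives iff all neighbours are foreground
//         (out-of-bounds treated as true, so structures touching the border
//         are not eroded from outside the field).
// [[Rcpp::export(name = ".morph_3d")]]
LogicalVector morph_3d(LogicalVector mask, IntegerVector dims, IntegerMatrix offsets, bool dilate) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int no = offsets.nrow();
  LogicalVector out(mask.size());
  if (dilate) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          if (!mask[idx3(z, y, x, nz, ny)]) continue;
          for (int k = 0; k < no; ++k) {
            int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            out[idx3(zz, yy, xx, nz, ny)] = true;
          }
        }
  } else {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          const int v = idx3(z, y, x, nz, ny);
          if (!mask[v]) { out[v] = false; continue; }
          bool acc = true;
          for (int k = 0; k < no; ++k) {
            int zz = z + offsets(k, 0), yy = y + offsets(k, 1), xx = x + offsets(k, 2);
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (!mask[idx3(zz, yy, xx, nz, ny)]) { acc = false; break; }
          }
          out[v] = acc;
        }
  }
  return out;
}

// Rasterise a tube (union of balls along a sampled path) into voxel indices.
// pts: m x 3 matrix of path points in µm, columns (z, y, x); radius in µm.
// Returns 1-based linear indices of covered voxels (unique, sorted).
// [[Rcpp::export(name = ".raster_tube")]]
IntegerVector raster_tube(NumericMatrix pts, double radius, IntegerVector dims,
                          NumericVector pitch) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = pitch[0], dy = pitch[1], dx = pitch[2];
  std::vector<int> hits;
  const double r2 = radius * radius;
  for (int p = 0; p < pts.nrow(); ++p) {
    const double pz = pts(p, 0), py = pts(p, 1), px = pts(p, 2);
    int z0 = (int)std::floor((pz - radius) / dz - 0.5), z1 = (int)std::ceil((pz + radius) / dz - 0.5);
    int y0 = (int)std::floor((py - radius) / dy - 0.5), y1 = (int)std::ceil((py + radius) / dy - 0.5);
    int x0 = (int)std::floor((px - radius) / dx - 0.5), x1 = (int)std::ceil((px + radius) / dx - 0.5);
    if (z0 < 0) z0 = 0; if (z1 >= nz) z1 = nz - 1;
    if (y0 < 0) y0 = 0; if (y1 >= ny) y1 = ny - 1;
    if (x0 < 0) x0 = 0; if (x1 >= nx) x1 = nx - 1;
    for (int xx = x0; xx <= x1; ++xx) {
      double ddx = (xx + 0.5) * dx - px;
      for (int yy = y0; yy <= y1; ++yy) {
        double ddy = (yy + 0.5) * dy - py;
        double dxy2 = ddx * ddx + ddy * ddy;
        if (dxy2 > r2) continue;
        for (int zz = z0; zz <= z1; ++zz) {
          double ddz = (zz + 0.5) * dz - pz;
          if (dxy2 + ddz * ddz <= r2)
            hits.push_back(idx3(zz, yy, xx, nz, ny) + 1);
        }
      }
    }
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  return IntegerVector(hits.begin(), hits.end());
}

// Clamp to [0, maxv] and round half away from zero (matching R's round for
// the non-negative values that remain after clamping).
// [[Rcpp::export(name = ".clip_round")]]
NumericVector clip_round(NumericVector x, double maxv) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (v < 0) v = 0;
    if (v > maxv) v = maxv;
    out[i] = std::nearbyint(v);
  }
  return out;
}

// Solid ellipsoid voxelisation: voxel centre inside the (rotated) ellipsoid.
// centre in µm (z,y,x); rot is a 3x3 matrix whose ROWS are the ellipsoid
// principal axes expressed in stack (z,y,x) coordinates; semi in µm for the
// axes in the same row order.
// [[Rcpp::export(name = ".ellipsoid_mask_cpp")]]
LogicalVector ellipsoid_mask_cpp(IntegerVector dims, NumericVector pitch,
                                 NumericVector centre, NumericMatrix rot,
                                 NumericVector semi) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = pitch[0], dy = pitch[1], dx = pitch[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  for (int x = 0; x < nx; ++x) {
    double vx = (x + 0.5) * dx - centre[2];
    for (int y = 0; y < ny; ++y) {
      double vy = (y + 0.5) * dy - centre[1];
      for (int z = 0; z < nz; ++z) {
        double vz = (z + 0.5) * dz - centre[0];
        double q = 0.0;
        for (int k = 0; k < 3; ++k) {
          double proj = rot(k, 0) * vz + rot(k, 1) * vy + rot(k, 2) * vx;
          double t = proj / semi[k];
          q += t * t;
        }
        out[idx3(z, y, x, nz, ny)] = (q <= 1.0);
      }
    }
  }
  return out;
}
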