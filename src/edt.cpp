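#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), spacing w.
// f: input squared distances sampled on the line; d: output. Exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  static const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) {  // no sites on this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;  // not a site
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; continue; }  // z[0] = -Inf guards underflow
      break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    int p = v[j];
    double dq = w * (q - p);
    d[q] = dq * dq + f[p];
  }
}

// Exact squared Euclidean distance transform of a 3D mask with anisotropic
// voxel spacing. mask: logical array (dim nz x ny x nx, column-major),
// TRUE = feature (root). spacing: c(dz, dy, dx) in mm.
// Returns squared distances in mm^2 (0 on feature voxels).
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);

  // pass along z (fastest-varying index)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = ((R_xlen_t)x * ny + y) * nz;
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = out[base + z]; if (f[z] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, dz);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = (R_xlen_t)x * ny * nz + z;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = out[base + (R_xlen_t)y * nz]; if (f[y] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, dy);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nz] = d[y];
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = (R_xlen_t)y * nz + z;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = out[base + (R_xlen_t)x * ny * nz]; if (f[x] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, dx);
      for (int x = 0; x < nx; ++x) out[base + (R_xlen_t)x * ny * nz] = d[x];
    }
  return out;
}

// Distance from each probe point to the nearest pattern point (2D).
// [[Rcpp::export]]
NumericVector nearest_point_dist(NumericVector px, NumericVector py,
                                 NumericVector qx, NumericVector qy) {
  const R_xlen_t n = px.size(), m = qx.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double xi = px[i], yi = py[i];
    for (R_xlen_t j = 0; j < m; ++j) {
      double ddx = xi - qx[j], ddy = yi - qy[j];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Label voxels within `radius` of the segment a-b as root (value 2) in a
// label grid, restricted to voxels currently inside the column (label != 0).
// Grid: dim (nz, ny, nx) column-major; voxel centers at (i + 0.5) * spacing
// along each axis (0-based i). Coordinates in mm: (z, y, x).
// [[Rcpp::export]]
IntegerVector rasterize_segment(IntegerVector labels, IntegerVector dim,
                       NumericVector spacing, NumericVector a,
                       NumericVector b, double radius) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double az = a[0], ay = a[1], ax = a[2];
  const double bz = b[0], by = b[1], bx = b[2];
  const double vz = bz - az, vy = by - ay, vx = bx - ax;
  const double L2 = vz * vz + vy * vy + vx * vx;
  // bounding box in voxel indices
  int z0 = std::max(0, (int)std::floor((std::min(az, bz) - radius) / dz - 0.5));
  int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + radius) / dz - 0.5));
  int y0 = std::max(0, (int)std::floor((std::min(ay, by) - radius) / dy - 0.5));
  int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + radius) / dy - 0.5));
  int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - radius) / dx - 0.5));
  int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + radius) / dx - 0.5));
  const double r2 = radius * radius;
  for (int x = x0; x <= x1; ++x) {
    double cx = (x + 0.5) * dx;
    for (int y = y0; y <= y1; ++y) {
      double cy = (y + 0.5) * dy;
      for (int z = z0; z <= z1; ++z) {
        double cz = (z + 0.5) * dz;
        double t = 0.0;
        if (L2 > 0.0) {
          t = ((cz - az) * vz + (cy - ay) * vy + (cx - ax) * vx) / L2;
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        }
        double ez = cz - (az + t * vz), ey = cy - (ay + t * vy),
               ex = cx - (ax + t * vx);
        if (ez * ez + ey * ey + ex * ex <= r2) {
          R_xlen_t idx = ((R_xlen_t)x * ny + y) * nz + z;
          if (labels[idx] != 0) labels[idx] = 2;
        }
      }
    }
  }
  return labels;
}
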