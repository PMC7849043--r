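#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All kernels use 0-based voxel coordinates; R wrappers shift by 1.
// Out-of-bounds continuous coordinates are clamped to the grid (border
// replicate), matching the sampling contract of the R API.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear interpolation on a column-major (nx,ny,nz) array.
static double trilinear(const double* v, int nx, int ny, int nz,
                        double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx > 1 ? nx - 2 : 0;
  if (y0 > ny - 2) y0 = ny > 1 ? ny - 2 : 0;
  if (z0 > nz - 2) z0 = nz > 1 ? nz - 2 : 0;
  int x1 = nx > 1 ? x0 + 1 : x0;
  int y1 = ny > 1 ? y0 + 1 : y0;
  int z1 = nz > 1 ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  #define V(i, j, k) v[(i) * sx + (j) * sy + (k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts) {
  const double* v = vol.begin();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = trilinear(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Warp: out(v) = src(v + u(v)); u is (nx,ny,nz,3) on the output grid.
// nearest = 1 rounds the sample coordinate to the closest grid node
// (label-safe sampling); nearest = 0 interpolates trilinearly.
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector src, IntegerVector sdims,
                       NumericVector u, IntegerVector odims, int nearest) {
  int nx = odims[0], ny = odims[1], nz = odims[2];
  int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double* s = src.begin();
  const double* uu = u.begin();
  NumericVector out(nvox);
  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        double px = x + uu[i];
        double py = y + uu[i + nvox];
        double pz = z + uu[i + 2 * nvox];
        if (nearest) {
          int ix = clampi((int)std::floor(px + 0.5), 0, sx - 1);
          int iy = clampi((int)std::floor(py + 0.5), 0, sy - 1);
          int iz = clampi((int)std::floor(pz + 0.5), 0, sz - 1);
          out[i] = s[ix + (R_xlen_t)sx * (iy + (R_xlen_t)sy * iz)];
        } else {
          out[i] = trilinear(s, sx, sy, sz, px, py, pz);
        }
      }
  return out;
}

// Windowed-PCC (or SSD) data term for one voxel and one candidate label.
// The warped patch is rigid w.r.t. the centre voxel: the source is sampled
// at w + u(v) + l*delta for every window node w of the *target* grid; nodes
// falling outside the target grid are dropped (border truncation).
static double data_term_one(const double* tgt, int tx, int ty, int tz,
                            const double* src, int sx, int sy, int sz,
                            int vx, int vy, int vz,
                            double ox, double oy, double oz,
                            const int* woff, int nw, int metric) {
  if (metric == 1) { // squared difference at the centre voxel only
    double sv = trilinear(src, sx, sy, sz, vx + ox, vy + oy, vz + oz);
    double d = tgt[vx + (R_xlen_t)tx * (vy + (R_xlen_t)ty * vz)] - sv;
    return d * d;
  }
  double tv[512], svv[512];
  int n = 0;
  for (int k = 0; k < nw; ++k) {
    int wx = vx + woff[k];
    int wy = vy + woff[k + nw];
    int wz = vz + woff[k + 2 * nw];
    if (wx < 0 || wy < 0 || wz < 0 || wx >= tx || wy >= ty || wz >= tz)
      continue;
    tv[n] = tgt[wx + (R_xlen_t)tx * (wy + (R_xlen_t)ty * wz)];
    svv[n] = trilinear(src, sx, sy, sz, wx + ox, wy + oy, wz + oz);
    ++n;
  }
  if (n < 2) return 0.5;
  double mt = 0, ms = 0;
  for (int k = 0; k < n; ++k) { mt += tv[k]; ms += svv[k]; }
  mt /= n; ms /= n;
  double vtt = 0, vss = 0, vts = 0;
  for (int k = 0; k < n; ++k) {
    double a = tv[k] - mt, b = svv[k] - ms;
    vtt += a * a; vss += b * b; vts += a * b;
  }
  double p = 0.0; // zero-variance windows carry no evidence -> PCC 0
  if (vtt > 1e-24 && vss > 1e-24) p = vts / std::sqrt(vtt * vss);
  if (p > 1.0) p = 1.0;
  if (p < -1.0) p = -1.0;
  return 0.5 * (1.0 - p);
}

// Unary tables phi_v(0), phi_v(1) for all voxels of one block, in the
// block's column-major order (x fastest). lo/hi are 0-based inclusive.
// [[Rcpp::export]]
NumericMatrix cpp_block_unary(NumericVector tgt, IntegerVector tdims,
                              NumericVector src, IntegerVector sdims,
                              NumericVector u,
                              IntegerVector lo, IntegerVector hi,
                              NumericVector delta, IntegerMatrix woff,
                              int metric) {
  int tx = tdims[0], ty = tdims[1], tz = tdims[2];
  int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  int nw = woff.nrow();
  if (nw > 512) stop("window too large (max 512 nodes)");
  R_xlen_t nvox = (R_xlen_t)tx * ty * tz;
  const double* t = tgt.begin();
  const double* s = src.begin();
  const double* uu = u.begin();
  const int* wo = woff.begin();
  R_xlen_t nb = (R_xlen_t)(hi[0] - lo[0] + 1) * (hi[1] - lo[1] + 1) *
                (hi[2] - lo[2] + 1);
  NumericMatrix out(nb, 2);
  R_xlen_t i = 0;
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x, ++i) {
        R_xlen_t vi = x + (R_xlen_t)tx * (y + (R_xlen_t)ty * z);
        double ux = uu[vi], uy = uu[vi + nvox], uz = uu[vi + 2 * nvox];
        out(i, 0) = data_term_one(t, tx, ty, tz, s, sx, sy, sz, x, y, z,
                                  ux, uy, uz, wo, nw, metric);
        out(i, 1) = data_term_one(t, tx, ty, tz, s, sx, sy, sz, x, y, z,
                                  ux + delta[0], uy + delta[1],
                                  uz + delta[2], wo, nw, metric);
      }
  return out;
}

// Total data term D(u) over the whole grid (label 0, i.e. the current u).
// [[Rcpp::export]]
double cpp_data_energy(NumericVector tgt, IntegerVector tdims,
                       NumericVector src, IntegerVector sdims,
                       NumericVector u, IntegerMatrix woff, int metric) {
  int tx = tdims[0], ty = tdims[1], tz = tdims[2];
  int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  int nw = woff.nrow();
  if (nw > 512) stop("window too large (max 512 nodes)");
  R_xlen_t nvox = (R_xlen_t)tx * ty * tz;
  const double* t = tgt.begin();
  const double* s = src.begin();
  const double* uu = u.begin();
  const int* wo = woff.begin();
  double acc = 0.0;
  R_xlen_t i = 0;
  for (int z = 0; z < tz; ++z)
    for (int y = 0; y < ty; ++y)
      for (int x = 0; x < tx; ++x, ++i)
        acc += data_term_one(t, tx, ty, tz, s, sx, sy, sz, x, y, z,
                             uu[i], uu[i + nvox], uu[i + 2 * nvox],
                             wo, nw, metric);
  return acc;
}
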