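#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major 3D indexing, 0-based.
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}
static inline double fetch(const double *vol, int nx, int ny, int nz,
                           int x, int y, int z) {
  x = clampi(x, 0, nx - 1);
  y = clampi(y, 0, ny - 1);
  z = clampi(z, 0, nz - 1);
  return vol[x + (size_t)nx * (y + (size_t)ny * z)];
}

// Keys cubic convolution kernel, a = -0.5 (C1 continuous).
static inline double keys_w(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0)  return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}
static inline double keys_dw(double t) {
  double s = t < 0 ? -1.0 : 1.0;
  t = std::fabs(t);
  if (t <= 1.0) return s * (4.5 * t * t - 5.0 * t);
  if (t < 2.0)  return s * (-1.5 * t * t + 5.0 * t - 4.0);
  return 0.0;
}

// Interpolate a 3D volume at points given in 0-based voxel coordinates.
// order: 1 (trilinear) or 3 (Keys cubic convolution). Border handling is
// replicate-clamp; callers restrict points to the physical domain.
// [[Rcpp::export]]
List cpp_interp3(NumericVector vol, IntegerVector dim, NumericMatrix pts,
                 int order, bool want_gradient) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  const double *v = REAL(vol);
  NumericVector out(n);
  NumericMatrix grad(want_gradient ? n : 1, 3);

  for (int p = 0; p < n; ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    if (order == 1) {
      int ix = (int)std::floor(px), iy = (int)std::floor(py),
          iz = (int)std::floor(pz);
      double fx = px - ix, fy = py - iy, fz = pz - iz;
      double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double wx = dx ? fx : 1.0 - fx;
            double wy = dy ? fy : 1.0 - fy;
            double wz = dz ? fz : 1.0 - fz;
            double c = fetch(v, nx, ny, nz, ix + dx, iy + dy, iz + dz);
            val += wx * wy * wz * c;
            if (want_gradient) {
              gx += (dx ? 1.0 : -1.0) * wy * wz * c;
              gy += (dy ? 1.0 : -1.0) * wx * wz * c;
              gz += (dz ? 1.0 : -1.0) * wx * wy * c;
            }
          }
      out[p] = val;
      if (want_gradient) { grad(p, 0) = gx; grad(p, 1) = gy; grad(p, 2) = gz; }
    } else {
      int ix = (int)std::floor(px), iy = (int)std::floor(py),
          iz = (int)std::floor(pz);
      double wx[4], wy[4], wz[4], dwx[4], dwy[4], dwz[4];
      for (int k = 0; k < 4; ++k) {
        double dx = px - (ix - 1 + k);
        double dy = py - (iy - 1 + k);
        double dz = pz - (iz - 1 + k);
        wx[k] = keys_w(dx); wy[k] = keys_w(dy); wz[k] = keys_w(dz);
        if (want_gradient) {
          // d/dp of w(p - node) = w'(p - node)
          dwx[k] = keys_dw(dx); dwy[k] = keys_dw(dy); dwz[k] = keys_dw(dz);
        }
      }
      double val = 0.0, gx = 0.0, gy = 0.0, gz = 0.0;
      for (int kz = 0; kz < 4; ++kz)
        for (int ky = 0; ky < 4; ++ky)
          for (int kx = 0; kx < 4; ++kx) {
            double c = fetch(v, nx, ny, nz, ix - 1 + kx, iy - 1 + ky,
                             iz - 1 + kz);
            val += wx[kx] * wy[ky] * wz[kz] * c;
            if (want_gradient) {
              gx += dwx[kx] * wy[ky] * wz[kz] * c;
              gy += wx[kx] * dwy[ky] * wz[kz] * c;
              gz += wx[kx] * wy[ky] * dwz[kz] * c;
            }
          }
      out[p] = val;
      if (want_gradient) { grad(p, 0) = gx; grad(p, 1) = gy; grad(p, 2) = gz; }
    }
  }
  if (want_gradient) return List::create(_["value"] = out, _["gradient"] = grad);
  return List::create(_["value"] = out);
}

// Uniform cubic B-spline basis.
static inline void bspline_basis(double t, double *b) {
  double t2 = t * t, t3 = t2 * t;
  b[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  b[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  b[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  b[3] = t3 / 6.0;
}

// Free-form deformation: control point j (0-based) sits at origin + j*delta
// (mm); displacement interpolated with uniform cubic B-splines.
// coef is an (ngx, ngy, ngz, 3) array; points are world mm.
// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp(NumericMatrix pts, NumericVector coef,
                           IntegerVector grid_dim, NumericVector delta,
                           NumericVector origin) {
  const int gx = grid_dim[0], gy = grid_dim[1], gz = grid_dim[2];
  const size_t plane = (size_t)gx * gy * gz;
  const double *cf = REAL(coef);
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    double sx = (pts(p, 0) - origin[0]) / delta[0];
    double sy = (pts(p, 1) - origin[1]) / delta[1];
    double sz = (pts(p, 2) - origin[2]) / delta[2];
    int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
        iz = (int)std::floor(sz);
    ix = clampi(ix, 1, gx - 3); iy = clampi(iy, 1, gy - 3);
    iz = clampi(iz, 1, gz - 3);
    double bx[4], by[4], bz[4];
    bspline_basis(sx - ix, bx); bspline_basis(sy - iy, by);
    bspline_basis(sz - iz, bz);
    double ux = 0.0, uy = 0.0, uz = 0.0;
    for (int kz = 0; kz < 4; ++kz)
      for (int ky = 0; ky < 4; ++ky) {
        size_t base = (size_t)(ix - 1) +
          (size_t)gx * ((iy - 1 + ky) + (size_t)gy * (iz - 1 + kz));
        double byz = by[ky] * bz[kz];
        for (int kx = 0; kx < 4; ++kx) {
          double w = bx[kx] * byz;
          size_t idx = base + kx;
          ux += w * cf[idx];
          uy += w * cf[idx + plane];
          uz += w * cf[idx + 2 * plane];
        }
      }
    out(p, 0) = ux; out(p, 1) = uy; out(p, 2) = uz;
  }
  return out;
}

// Adjoint of cpp_ffd_disp: scatter per-point 3-vectors into the coefficient
// grid with the same B-spline weights (used to assemble metric gradients).
// [[Rcpp::export]]
NumericVector cpp_ffd_scatter(NumericMatrix pts, NumericMatrix vals,
                              IntegerVector grid_dim, NumericVector delta,
                              NumericVector origin) {
  const int gx = grid_dim[0], gy = grid_dim[1], gz = grid_dim[2];
  const size_t plane = (size_t)gx * gy * gz;
  NumericVector out(plane * 3);
  double *o = REAL(out);
  const int n = pts.nrow();
  for (int p = 0; p < n; ++p) {
    double sx = (pts(p, 0) - origin[0]) / delta[0];
    double sy = (pts(p, 1) - origin[1]) / delta[1];
    double sz = (pts(p, 2) - origin[2]) / delta[2];
    int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
        iz = (int)std::floor(sz);
    ix = clampi(ix, 1, gx - 3); iy = clampi(iy, 1, gy - 3);
    iz = clampi(iz, 1, gz - 3);
    double bx[4], by[4], bz[4];
    bspline_basis(sx - ix, bx); bspline_basis(sy - iy, by);
    bspline_basis(sz - iz, bz);
    double vx = vals(p, 0), vy = vals(p, 1), vz = vals(p, 2);
    for (int kz = 0; kz < 4; ++kz)
      for (int ky = 0; ky < 4; ++ky) {
        size_t base = (size_t)(ix - 1) +
          (size_t)gx * ((iy - 1 + ky) + (size_t)gy * (iz - 1 + kz));
        double byz = by[ky] * bz[kz];
        for (int kx = 0; kx < 4; ++kx) {
          double w = bx[kx] * byz;
          size_t idx = base + kx;
          o[idx] += w * vx;
          o[idx + plane] += w * vy;
          o[idx + 2 * plane] += w * vz;
        }
      }
  }
  return out;
}

// Warp one volume through an FFD: out(x) = in(x + u(x)), x in mm on the
// voxel lattice. Voxels mapped outside the domain get `fill`.
// [[Rcpp::export]]
NumericVector cpp_resample_ffd(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector coef,
                               IntegerVector grid_dim, NumericVector delta,
                               NumericVector origin, int order, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  // evaluate in z-slabs to bound the temporary point matrix
  NumericMatrix pts((size_t)nx * ny, 3);
  const double *v = REAL(vol);
  double *o = REAL(out);
  for (int z = 0; z < nz; ++z) {
    int q = 0;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++q) {
        pts(q, 0) = x * spacing[0];
        pts(q, 1) = y * spacing[1];
        pts(q, 2) = z * spacing[2];
      }
    NumericMatrix disp = cpp_ffd_disp(pts, coef, grid_dim, delta, origin);
    q = 0;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++q) {
        double px = (pts(q, 0) + disp(q, 0)) / spacing[0];
        double py = (pts(q, 1) + disp(q, 1)) / spacing[1];
        double pz = (pts(q, 2) + disp(q, 2)) / spacing[2];
        size_t oi = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (px < 0 || px > nx - 1 || py < 0 || py > ny - 1 ||
            pz < 0 || pz > nz - 1) {
          o[oi] = fill;
          continue;
        }
        if (order == 1) {
          int ix = (int)std::floor(px), iy = (int)std::floor(py),
              iz = (int)std::floor(pz);
          double fx = px - ix, fy = py - iy, fz = pz - iz;
          double val = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                val += (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                       (dz ? fz : 1 - fz) *
                       fetch(v, nx, ny, nz, ix + dx, iy + dy, iz + dz);
          o[oi] = val;
        } else {
          int ix = (int)std::floor(px), iy = (int)std::floor(py),
              iz = (int)std::floor(pz);
          double wx[4], wy[4], wz[4];
          for (int k = 0; k < 4; ++k) {
            wx[k] = keys_w(px - (ix - 1 + k));
            wy[k] = keys_w(py - (iy - 1 + k));
            wz[k] = keys_w(pz - (iz - 1 + k));
          }
          double val = 0.0;
          for (int kz = 0; kz < 4; ++kz)
            for (int ky = 0; ky < 4; ++ky)
              for (int kx = 0; kx < 4; ++kx)
                val += wx[kx] * wy[ky] * wz[kz] *
                       fetch(v, nx, ny, nz, ix - 1 + kx, iy - 1 + ky,
                             iz - 1 + kz);
          o[oi] = val;
        }
      }
  }
  return out;
}

// Separable Gaussian smoothing with replicate borders and a kernel
// renormalized after truncation, so constants are preserved exactly.
// [[Rcpp::export]]
NumericVector cpp_smooth_gaussian(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> cur(REAL(vol), REAL(vol) + (size_t)nx * ny * nz);
  std::vector<double> nxt(cur.size());
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0.0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (double &w : k) w /= sum;
    // iterate over all lines along axis ax
    int la = n[ax];
    int ob[2], osd = 0; // other axes
    for (int a = 0; a < 3; ++a) if (a != ax) ob[osd++] = a;
    for (int j = 0; j < n[ob[1]]; ++j)
      for (int i = 0; i < n[ob[0]]; ++i) {
        size_t base = stride[ob[0]] * i + stride[ob[1]] * j;
        for (int t = 0; t < la; ++t) {
          double acc = 0.0;
          for (int u = -r; u <= r; ++u) {
            int tt = clampi(t + u, 0, la - 1);
            acc += k[u + r] * cur[base + stride[ax] * tt];
          }
          nxt[base + stride[ax] * t] = acc;
        }
      }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  return out;
}

// 26-connected component of `mask` containing (or none) the given 0-based
// seed voxel. Returns an integer mask (0/1).
// [[Rcpp::export]]
IntegerVector cpp_label_component(IntegerVector mask, IntegerVector dim,
                                  IntegerVector seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((size_t)nx * ny * nz);
  size_t s0 = (size_t)seed[0] + (size_t)nx * (seed[1] + (size_t)ny * seed[2]);
  if (mask[s0] == 0) return out;
  std::vector<size_t> stack;
  stack.push_back(s0);
  out[s0] = 1;
  while (!stack.empty()) {
    size_t v = stack.back();
    stack.pop_back();
    int z = v / ((size_t)nx * ny);
    int rem = v - (size_t)z * nx * ny;
    int y = rem / nx, x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          size_t w = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
          if (mask[w] != 0 && out[w] == 0) {
            out[w] = 1;
            stack.push_back(w);
          }
        }
  }
  return out;
}

// Binary dilation/erosion with an explicit offset list (structuring
// element). Outside the volume counts as background.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dim,
                               IntegerMatrix offsets, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector out((size_t)nx * ny * nz);
  const int no = offsets.nrow();
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool any = false, all = true;
        for (int o = 0; o < no; ++o) {
          int xx = x + offsets(o, 0), yy = y + offsets(o, 1),
              zz = z + offsets(o, 2);
          bool in = xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 &&
                    zz < nz &&
                    mask[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)];
          any = any || in;
          all = all && in;
          if (dilate && any) break;
          if (!dilate && !all) break;
        }
        out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] =
          dilate ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}
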