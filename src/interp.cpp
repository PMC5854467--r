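// Hot numerical loops: central-slice extraction / insertion in Fourier
// space (trilinear), real-space image/volume rotation, and 3D connected
// component labelling. Everything else lives in R.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int wrap_index(int h, int n) { return ((h % n) + n) % n; }

// Extract a central slice from a full (unshifted) 3D complex transform.
// vol_re/vol_im: n^3 arrays; rot: 3x3 rotation applied to the 2D frequency
// (hx, hy, 0) in voxel-frequency units; returns complex values at each
// (hx, hy). Frequencies rotated beyond Nyquist give 0.
// [[Rcpp::export]]
ComplexVector cp_slice_extract(NumericVector vol_re, NumericVector vol_im,
                               int n, NumericMatrix rot,
                               NumericVector hx, NumericVector hy) {
  const int m = hx.size();
  ComplexVector out(m);
  const double lim = n / 2.0 - 1.0;
  const double r00 = rot(0,0), r01 = rot(0,1);
  const double r10 = rot(1,0), r11 = rot(1,1);
  const double r20 = rot(2,0), r21 = rot(2,1);
  for (int i = 0; i < m; ++i) {
    const double X = r00 * hx[i] + r01 * hy[i];
    const double Y = r10 * hx[i] + r11 * hy[i];
    const double Z = r20 * hx[i] + r21 * hy[i];
    Rcomplex v; v.r = 0.0; v.i = 0.0;
    if (std::fabs(X) <= lim && std::fabs(Y) <= lim && std::fabs(Z) <= lim) {
      const int x0 = (int)std::floor(X), y0 = (int)std::floor(Y),
                z0 = (int)std::floor(Z);
      const double fx = X - x0, fy = Y - y0, fz = Z - z0;
      double re = 0.0, im = 0.0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                             (dz ? fz : 1.0 - fz);
            if (w == 0.0) continue;
            const int ix = wrap_index(x0 + dx, n);
            const int iy = wrap_index(y0 + dy, n);
            const int iz = wrap_index(z0 + dz, n);
            const R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)n * (iy + (R_xlen_t)n * iz);
            re += w * vol_re[idx];
            im += w * vol_im[idx];
          }
      v.r = re; v.i = im;
    }
    out[i] = v;
  }
  return out;
}

// Spread one particle's 2D transform into accumulator grids (in place).
// num_re/num_im/den are n^3 arrays owned by the caller. val is the
// CTF-multiplied, weighted particle transform at (hx, hy); den_val the
// matching CTF^2 weights. The Friedel mate is inserted as well so the
// accumulated numerator keeps Hermitian symmetry.
// [[Rcpp::export]]
void cp_insert_slice(NumericVector num_re, NumericVector num_im,
                     NumericVector den, int n, NumericMatrix rot,
                     NumericVector hx, NumericVector hy,
                     ComplexVector val, NumericVector den_val) {
  const int m = hx.size();
  const double lim = n / 2.0 - 1.0;
  const double r00 = rot(0,0), r01 = rot(0,1);
  const double r10 = rot(1,0), r11 = rot(1,1);
  const double r20 = rot(2,0), r21 = rot(2,1);
  for (int i = 0; i < m; ++i) {
    const double X = r00 * hx[i] + r01 * hy[i];
    const double Y = r10 * hx[i] + r11 * hy[i];
    const double Z = r20 * hx[i] + r21 * hy[i];
    if (std::fabs(X) > lim || std::fabs(Y) > lim || std::fabs(Z) > lim)
      continue;
    const double vr = val[i].r, vi = val[i].i, dv = den_val[i];
    for (int mate = 0; mate < 2; ++mate) {
      const double sX = mate ? -X : X, sY = mate ? -Y : Y, sZ = mate ? -Z : Z;
      const double sv = mate ? -vi : vi;
      const int x0 = (int)std::floor(sX), y0 = (int)std::floor(sY),
                z0 = (int)std::floor(sZ);
      const double fx = sX - x0, fy = sY - y0, fz = sZ - z0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                             (dz ? fz : 1.0 - fz);
            if (w == 0.0) continue;
            const int ix = wrap_index(x0 + dx, n);
            const int iy = wrap_index(y0 + dy, n);
            const int iz = wrap_index(z0 + dz, n);
            const R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)n * (iy + (R_xlen_t)n * iz);
            num_re[idx] += w * vr;
            num_im[idx] += w * sv;
            den[idx]    += w * dv;
          }
      // the zero-frequency plane hosts both mates; skip duplicate at exact 0
      if (X == 0.0 && Y == 0.0 && Z == 0.0) break;
    }
  }
}

// Rotate a square image counter-clockwise by `angle` radians about the box
// center (n/2, 0-based), bilinear interpolation, `fill` outside.
// [[Rcpp::export]]
NumericMatrix cp_rotate2d(NumericMatrix img, double angle, double fill) {
  const int n = img.nrow();
  NumericMatrix out(n, n);
  const double c = std::cos(angle), s = std::sin(angle), h = n / 2.0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      const double x = i - h, y = j - h;
      // inverse rotation to sample the source
      const double xs =  c * x + s * y + h;
      const double ys = -s * x + c * y + h;
      double v = fill;
      if (xs >= 0 && xs <= n - 1 && ys >= 0 && ys <= n - 1) {
        const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
        const double fx = xs - x0, fy = ys - y0;
        const int x1 = x0 + 1 < n ? x0 + 1 : x0;
        const int y1 = y0 + 1 < n ? y0 + 1 : y0;
        v = (1 - fx) * (1 - fy) * img(x0, y0) + fx * (1 - fy) * img(x1, y0) +
            (1 - fx) * fy * img(x0, y1) + fx * fy * img(x1, y1);
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Rotate a cubic volume by 3x3 matrix `rot` about the box center,
// trilinear interpolation, `fill` outside. rot maps output coords to the
// rotated object: sampled source coordinate is rot^T applied to (x,y,z).
// [[Rcpp::export]]
NumericVector cp_rotate3d(NumericVector vol, int n, NumericMatrix rot,
                          double fill) {
  NumericVector out((R_xlen_t)n * n * n);
  const double h = n / 2.0;
  // inverse rotation = transpose
  const double a00 = rot(0,0), a01 = rot(1,0), a02 = rot(2,0);
  const double a10 = rot(0,1), a11 = rot(1,1), a12 = rot(2,1);
  const double a20 = rot(0,2), a21 = rot(1,2), a22 = rot(2,2);
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        const double x = i - h, y = j - h, z = k - h;
        const double xs = a00 * x + a01 * y + a02 * z + h;
        const double ys = a10 * x + a11 * y + a12 * z + h;
        const double zs = a20 * x + a21 * y + a22 * z + h;
        double v = fill;
        if (xs >= 0 && xs <= n - 1 && ys >= 0 && ys <= n - 1 &&
            zs >= 0 && zs <= n - 1) {
          const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys),
                    z0 = (int)std::floor(zs);
          const double fx = xs - x0, fy = ys - y0, fz = zs - z0;
          const int x1 = x0 + 1 < n ? x0 + 1 : x0;
          const int y1 = y0 + 1 < n ? y0 + 1 : y0;
          const int z1 = z0 + 1 < n ? z0 + 1 : z0;
          auto at = [&](int a, int b, int cc) {
            return vol[(R_xlen_t)a + (R_xlen_t)n * (b + (R_xlen_t)n * cc)];
          };
          v = (1-fx)*(1-fy)*(1-fz)*at(x0,y0,z0) + fx*(1-fy)*(1-fz)*at(x1,y0,z0)
            + (1-fx)*fy*(1-fz)*at(x0,y1,z0)     + fx*fy*(1-fz)*at(x1,y1,z0)
            + (1-fx)*(1-fy)*fz*at(x0,y0,z1)     + fx*(1-fy)*fz*at(x1,y0,z1)
            + (1-fx)*fy*fz*at(x0,y1,z1)         + fx*fy*fz*at(x1,y1,z1);
        }
        out[(R_xlen_t)i + (R_xlen_t)n * (j + (R_xlen_t)n * k)] = v;
      }
  return out;
}

// Label 6-connected components of a binary 3D mask; returns integer labels
// (0 = background, components numbered from 1 in discovery order).
// [[Rcpp::export]]
IntegerVector cp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector lab((R_xlen_t)nx * ny * nz, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const R_xlen_t total = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t seed = 0; seed < total; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    lab[seed] = ++next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      const int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      const int dx[6] = {1,-1,0,0,0,0}, dy[6] = {0,0,1,-1,0,0},
                dz[6] = {0,0,0,0,1,-1};
      for (int d = 0; d < 6; ++d) {
        const int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const R_xlen_t q = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Batched slice extraction: `rots` is 9 x k (column-major 3x3 matrices);
// returns a k x m complex matrix of slice values.
// [[Rcpp::export]]
ComplexMatrix cp_slice_extract_many(NumericVector vol_re, NumericVector vol_im,
                                    int n, NumericMatrix rots,
                                    NumericVector hx, NumericVector hy) {
  const int m = hx.size(), k = rots.ncol();
  ComplexMatrix out(k, m);
  const double lim = n / 2.0 - 1.0;
  for (int r = 0; r < k; ++r) {
    const double r00 = rots(0,r), r10 = rots(1,r), r20 = rots(2,r);
    const double r01 = rots(3,r), r11 = rots(4,r), r21 = rots(5,r);
    for (int i = 0; i < m; ++i) {
      const double X = r00 * hx[i] + r01 * hy[i];
      const double Y = r10 * hx[i] + r11 * hy[i];
      const double Z = r20 * hx[i] + r21 * hy[i];
      Rcomplex v; v.r = 0.0; v.i = 0.0;
      if (std::fabs(X) <= lim && std::fabs(Y) <= lim && std::fabs(Z) <= lim) {
        const int x0 = (int)std::floor(X), y0 = (int)std::floor(Y),
                  z0 = (int)std::floor(Z);
        const double fx = X - x0, fy = Y - y0, fz = Z - z0;
        double re = 0.0, im = 0.0;
        for (int dz = 0; dz < 2; ++dz)
          for (int dy = 0; dy < 2; ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) *
                               (dz ? fz : 1.0 - fz);
              if (w == 0.0) continue;
              const int ix = wrap_index(x0 + dx, n);
              const int iy = wrap_index(y0 + dy, n);
              const int iz = wrap_index(z0 + dz, n);
              const R_xlen_t idx = (R_xlen_t)ix + (R_xlen_t)n * (iy + (R_xlen_t)n * iz);
              re += w * vol_re[idx];
              im += w * vol_im[idx];
            }
        v.r = re; v.i = im;
      }
      out(r, i) = v;
    }
  }
  return out;
}
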