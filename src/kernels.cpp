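#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Voxel indexing is 0-based and column-major: idx = x + nx*(y + ny*z).
// Sample coordinates are in 0-based voxel units of the source volume.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector vol, IntegerVector dim,
                                     NumericVector cx, NumericVector cy,
                                     NumericVector cz, double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = cx.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = cx[i], y = cy[i], z = cz[i];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[i] = background;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const double *v = REAL(vol);
    const R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double c000 = v[base], c100 = v[base + sx];
    double c010 = v[base + sy], c110 = v[base + sx + sy];
    double c001 = v[base + sz], c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz], c111 = v[base + sx + sy + sz];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_resample_nn(IntegerVector vol, IntegerVector dim,
                              NumericVector cx, NumericVector cy,
                              NumericVector cz, int background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = cx.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = cx[i], y = cy[i], z = cz[i];
    int xi = (int)std::floor(x + 0.5), yi = (int)std::floor(y + 0.5),
        zi = (int)std::floor(z + 0.5);
    if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) {
      out[i] = background;
    } else {
      out[i] = vol[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
    }
  }
  return out;
}

// Sample a volume and three companion volumes (typically its gradient
// components) at the same coordinates with shared trilinear weights.
// Returns an n x 4 matrix [value, g1, g2, g3].
// [[Rcpp::export]]
NumericMatrix cpp_sample4(NumericVector vol, NumericVector g1,
                          NumericVector g2, NumericVector g3,
                          IntegerVector dim, NumericVector cx,
                          NumericVector cy, NumericVector cz,
                          double background) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = cx.size();
  NumericMatrix out(n, 4);
  const double *vs[4] = {REAL(vol), REAL(g1), REAL(g2), REAL(g3)};
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = cx[i], y = cy[i], z = cz[i];
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out(i, 0) = background;
      out(i, 1) = out(i, 2) = out(i, 3) = 0.0;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double w000 = (1 - fx) * (1 - fy) * (1 - fz);
    double w100 = fx * (1 - fy) * (1 - fz);
    double w010 = (1 - fx) * fy * (1 - fz);
    double w110 = fx * fy * (1 - fz);
    double w001 = (1 - fx) * (1 - fy) * fz;
    double w101 = fx * (1 - fy) * fz;
    double w011 = (1 - fx) * fy * fz;
    double w111 = fx * fy * fz;
    for (int v = 0; v < 4; ++v) {
      const double *a = vs[v];
      out(i, v) = w000 * a[base] + w100 * a[base + sx] + w010 * a[base + sy] +
                  w110 * a[base + sx + sy] + w001 * a[base + sz] +
                  w101 * a[base + sx + sz] + w011 * a[base + sy + sz] +
                  w111 * a[base + sx + sy + sz];
    }
  }
  return out;
}

// Separable Gaussian with reflected boundaries; sigma per axis in voxels.
static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &w : k) w /= s;
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int dims[3] = {nx, ny, nz};
  const int n = dims[axis];
  const R_xlen_t stride = strides[axis];
  int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
  std::vector<double> line(n);
  for (int j2 = 0; j2 < dims[d2]; ++j2) {
    for (int j1 = 0; j1 < dims[d1]; ++j1) {
      R_xlen_t base = strides[d1] * j1 + strides[d2] * j2;
      for (int i = 0; i < n; ++i) line[i] = a[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int t = -radius; t <= radius; ++t) {
          int p = i + t;
          if (p < 0) p = -p - 1;
          if (p >= n) p = 2 * n - 1 - p;
          p = clampi(p, 0, n - 1);
          acc += k[t + radius] * line[p];
        }
        a[base + stride * i] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(a, nx, ny, nz, axis, sigma_vox[axis]);
  NumericVector out(vol.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

static inline void bspline_weights(double u, double *w) {
  double u2 = u * u, u3 = u2 * u;
  w[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  w[1] = (4 - 6 * u2 + 3 * u3) / 6.0;
  w[2] = (1 + 3 * u + 3 * u2 - 3 * u3) / 6.0;
  w[3] = u3 / 6.0;
}

// Per-axis lookup tables for a cubic B-spline control grid with spacing hv
// (voxel units). Control point j sits at voxel coordinate (j-1)*hv, so the
// support of the 4 basis functions at voxel x starts at index floor(x/hv).
static void axis_tables(int n, double hv, std::vector<int> &j0,
                        std::vector<double> &w) {
  j0.resize(n);
  w.resize(4 * n);
  for (int i = 0; i < n; ++i) {
    double t = i / hv;
    int fi = (int)std::floor(t);
    j0[i] = fi;
    bspline_weights(t - fi, &w[4 * i]);
  }
}

// Number of control points needed along an axis of n voxels: indices
// floor((n-1)/hv) .. floor((n-1)/hv)+3 must exist.
// [[Rcpp::export]]
IntegerVector cpp_ffd_ctrl_dim(IntegerVector dim, NumericVector hv) {
  IntegerVector out(3);
  for (int d = 0; d < 3; ++d)
    out[d] = (int)std::floor((dim[d] - 1) / hv[d]) + 4;
  return out;
}

// coef: array (cx, cy, cz, 3) flattened column-major; returns n x 3 matrix of
// displacements at every voxel of `dim` (same units as coef, i.e. mm).
// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp(NumericVector coef, IntegerVector cdim,
                           NumericVector hv, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  std::vector<int> jx, jy, jz;
  std::vector<double> wx, wy, wz;
  axis_tables(nx, hv[0], jx, wx);
  axis_tables(ny, hv[1], jy, wy);
  axis_tables(nz, hv[2], jz, wz);
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t cn = (R_xlen_t)cx * cy * cz;
  NumericMatrix out(n, 3);
  const double *cf = REAL(coef);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      double wyz[16];
      int cyz[16];
      for (int l = 0; l < 4; ++l)
        for (int m = 0; m < 4; ++m) {
          wyz[l + 4 * m] = wy[4 * y + l] * wz[4 * z + m];
          cyz[l + 4 * m] = cx * ((jy[y] + l) + cy * (jz[z] + m));
        }
      R_xlen_t row = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        double acc0 = 0, acc1 = 0, acc2 = 0;
        for (int lm = 0; lm < 16; ++lm) {
          const double wlm = wyz[lm];
          const int base = cyz[lm] + jx[x];
          double sub0 = 0, sub1 = 0, sub2 = 0;
          for (int k = 0; k < 4; ++k) {
            const double wk = wx[4 * x + k];
            sub0 += wk * cf[base + k];
            sub1 += wk * cf[base + k + cn];
            sub2 += wk * cf[base + k + 2 * cn];
          }
          acc0 += wlm * sub0;
          acc1 += wlm * sub1;
          acc2 += wlm * sub2;
        }
        out(row + x, 0) = acc0;
        out(row + x, 1) = acc1;
        out(row + x, 2) = acc2;
      }
    }
  }
  return out;
}

// Scatter per-voxel cost gradients v (n x 3) back onto the control grid.
// [[Rcpp::export]]
NumericVector cpp_ffd_grad(NumericMatrix v, IntegerVector dim,
                           NumericVector hv, IntegerVector cdim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  std::vector<int> jx, jy, jz;
  std::vector<double> wx, wy, wz;
  axis_tables(nx, hv[0], jx, wx);
  axis_tables(ny, hv[1], jy, wy);
  axis_tables(nz, hv[2], jz, wz);
  const R_xlen_t cn = (R_xlen_t)cx * cy * cz;
  NumericVector grad(cn * 3);
  double *g = REAL(grad);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      double wyz[16];
      int cyz[16];
      for (int l = 0; l < 4; ++l)
        for (int m = 0; m < 4; ++m) {
          wyz[l + 4 * m] = wy[4 * y + l] * wz[4 * z + m];
          cyz[l + 4 * m] = cx * ((jy[y] + l) + cy * (jz[z] + m));
        }
      R_xlen_t row = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        const double v0 = v(row + x, 0), v1 = v(row + x, 1), v2 = v(row + x, 2);
        if (v0 == 0 && v1 == 0 && v2 == 0) continue;
        for (int lm = 0; lm < 16; ++lm) {
          const double wlm = wyz[lm];
          const int base = cyz[lm] + jx[x];
          for (int k = 0; k < 4; ++k) {
            const double w = wlm * wx[4 * x + k];
            g[base + k] += w * v0;
            g[base + k + cn] += w * v1;
            g[base + k + 2 * cn] += w * v2;
          }
        }
      }
    }
  }
  grad.attr("dim") = IntegerVector::create(cx, cy, cz, 3);
  return grad;
}

// Fused FFD sum-of-squared-differences objective: evaluates the B-spline
// displacement, maps voxels into the moving image, samples all channels and
// their gradients, and scatters the cost gradient back to the control grid,
// in one pass. y_aff carries the affine part plus any base displacement
// (world mm); u_base==0 there is fine. Returns value and coef-shaped grad.
// [[Rcpp::export]]
List cpp_ffd_ssd(NumericVector coef, IntegerVector cdim, NumericVector hv,
                 IntegerVector dim, NumericMatrix y_aff, NumericVector spm,
                 IntegerVector mdim, List fixed, List moving, List mgx,
                 List mgy, List mgz, IntegerVector subset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int cx = cdim[0], cy = cdim[1], cz = cdim[2];
  const int mnx = mdim[0], mny = mdim[1], mnz = mdim[2];
  const int nch = fixed.size();
  std::vector<int> jx, jy, jz;
  std::vector<double> wx, wy, wz;
  axis_tables(nx, hv[0], jx, wx);
  axis_tables(ny, hv[1], jy, wy);
  axis_tables(nz, hv[2], jz, wz);
  const R_xlen_t cn = (R_xlen_t)cx * cy * cz;
  const bool use_subset = subset.size() > 0;
  const R_xlen_t nvox = use_subset ? subset.size()
                                   : (R_xlen_t)nx * ny * nz;
  std::vector<const double *> fv(nch), mv(nch), gx(nch), gy(nch), gz(nch);
  for (int ch = 0; ch < nch; ++ch) {
    fv[ch] = REAL((SEXP)fixed[ch]);
    mv[ch] = REAL((SEXP)moving[ch]);
    gx[ch] = REAL((SEXP)mgx[ch]);
    gy[ch] = REAL((SEXP)mgy[ch]);
    gz[ch] = REAL((SEXP)mgz[ch]);
  }
  NumericVector grad(cn * 3);
  double *g = REAL(grad);
  const double *cf = REAL(coef);
  double value = 0.0;
  const double invn = 1.0 / (double)nvox;

  for (R_xlen_t s = 0; s < nvox; ++s) {
    R_xlen_t i;
    int x, y, z;
    if (use_subset) {
      i = subset[s];
      x = (int)(i % nx);
      y = (int)((i / nx) % ny);
      z = (int)(i / ((R_xlen_t)nx * ny));
    } else {
      i = s;
      x = (int)(i % nx);
      y = (int)((i / nx) % ny);
      z = (int)(i / ((R_xlen_t)nx * ny));
    }
    {
      {
        double wyz[16];
        int cyz[16];
        for (int l = 0; l < 4; ++l)
          for (int m = 0; m < 4; ++m) {
            wyz[l + 4 * m] = wy[4 * y + l] * wz[4 * z + m];
            cyz[l + 4 * m] = cx * ((jy[y] + l) + cy * (jz[z] + m));
          }
        double u0 = 0, u1 = 0, u2 = 0;
        for (int lm = 0; lm < 16; ++lm) {
          const double wlm = wyz[lm];
          const int base = cyz[lm] + jx[x];
          double s0 = 0, s1 = 0, s2 = 0;
          for (int k = 0; k < 4; ++k) {
            const double wk = wx[4 * x + k];
            s0 += wk * cf[base + k];
            s1 += wk * cf[base + k + cn];
            s2 += wk * cf[base + k + 2 * cn];
          }
          u0 += wlm * s0;
          u1 += wlm * s1;
          u2 += wlm * s2;
        }
        double px = (y_aff(i, 0) + u0) / spm[0];
        double py = (y_aff(i, 1) + u1) / spm[1];
        double pz = (y_aff(i, 2) + u2) / spm[2];
        double v0 = 0, v1 = 0, v2 = 0;
        bool inside = (px >= 0.0 && px <= mnx - 1.0 && py >= 0.0 &&
                       py <= mny - 1.0 && pz >= 0.0 && pz <= mnz - 1.0);
        if (inside) {
          int x0 = (int)px, y0 = (int)py, z0 = (int)pz;
          if (x0 == mnx - 1) x0--;
          if (y0 == mny - 1) y0--;
          if (z0 == mnz - 1) z0--;
          double fx2 = px - x0, fy2 = py - y0, fz2 = pz - z0;
          const R_xlen_t b = (R_xlen_t)x0 + (R_xlen_t)mnx * (y0 + (R_xlen_t)mny * z0);
          const R_xlen_t sy = mnx, sz = (R_xlen_t)mnx * mny;
          double w000 = (1 - fx2) * (1 - fy2) * (1 - fz2);
          double w100 = fx2 * (1 - fy2) * (1 - fz2);
          double w010 = (1 - fx2) * fy2 * (1 - fz2);
          double w110 = fx2 * fy2 * (1 - fz2);
          double w001 = (1 - fx2) * (1 - fy2) * fz2;
          double w101 = fx2 * (1 - fy2) * fz2;
          double w011 = (1 - fx2) * fy2 * fz2;
          double w111 = fx2 * fy2 * fz2;
          for (int ch = 0; ch < nch; ++ch) {
            const double *a = mv[ch];
            double w = w000 * a[b] + w100 * a[b + 1] + w010 * a[b + sy] +
                       w110 * a[b + 1 + sy] + w001 * a[b + sz] +
                       w101 * a[b + 1 + sz] + w011 * a[b + sy + sz] +
                       w111 * a[b + 1 + sy + sz];
            double r = w - fv[ch][i];
            value += r * r * invn;
            double cc = 2.0 * r * invn;
            const double *ax = gx[ch];
            const double *ay = gy[ch];
            const double *az = gz[ch];
            v0 += cc * (w000 * ax[b] + w100 * ax[b + 1] + w010 * ax[b + sy] +
                        w110 * ax[b + 1 + sy] + w001 * ax[b + sz] +
                        w101 * ax[b + 1 + sz] + w011 * ax[b + sy + sz] +
                        w111 * ax[b + 1 + sy + sz]);
            v1 += cc * (w000 * ay[b] + w100 * ay[b + 1] + w010 * ay[b + sy] +
                        w110 * ay[b + 1 + sy] + w001 * ay[b + sz] +
                        w101 * ay[b + 1 + sz] + w011 * ay[b + sy + sz] +
                        w111 * ay[b + 1 + sy + sz]);
            v2 += cc * (w000 * az[b] + w100 * az[b + 1] + w010 * az[b + sy] +
                        w110 * az[b + 1 + sy] + w001 * az[b + sz] +
                        w101 * az[b + 1 + sz] + w011 * az[b + sy + sz] +
                        w111 * az[b + 1 + sy + sz]);
          }
        } else {
          for (int ch = 0; ch < nch; ++ch) {
            double r = 0.0 - fv[ch][i];
            value += r * r * invn;
          }
        }
        if (v0 != 0 || v1 != 0 || v2 != 0) {
          for (int lm = 0; lm < 16; ++lm) {
            const double wlm = wyz[lm];
            const int base = cyz[lm] + jx[x];
            for (int k = 0; k < 4; ++k) {
              const double w = wlm * wx[4 * x + k];
              g[base + k] += w * v0;
              g[base + k + cn] += w * v1;
              g[base + k + 2 * cn] += w * v2;
            }
          }
        }
      }
    }
  }
  grad.attr("dim") = IntegerVector::create(cx, cy, cz, 3);
  return List::create(_["value"] = value, _["gradient"] = grad);
}

// Per-voxel plurality vote over propagated label volumes (columns of `lab`).
// Ties broken by smallest label id; background (0) competes like any label.
// [[Rcpp::export]]
List cpp_vote_fuse(IntegerMatrix lab) {
  const R_xlen_t n = lab.nrow();
  const int m = lab.ncol();
  IntegerVector winner(n), votes(n);
  std::vector<int> ids(m), cnt(m);
  for (R_xlen_t i = 0; i < n; ++i) {
    int nid = 0;
    for (int j = 0; j < m; ++j) {
      int v = lab(i, j);
      int k = 0;
      for (; k < nid; ++k)
        if (ids[k] == v) { cnt[k]++; break; }
      if (k == nid) { ids[nid] = v; cnt[nid] = 1; nid++; }
    }
    int best = 0;
    for (int k = 1; k < nid; ++k)
      if (cnt[k] > cnt[best] || (cnt[k] == cnt[best] && ids[k] < ids[best]))
        best = k;
    winner[i] = ids[best];
    votes[i] = cnt[best];
  }
  return List::create(_["label"] = winner, _["votes"] = votes);
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), with
// anisotropic scale `s` (distance between neighbouring samples).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; continue; }
    double sq = s * s;
    double sfq = f[q] + sq * q * q;
    while (k >= 0) {
      double sv = f[v[k]] + sq * v[k] * v[k];
      double z = (sfq - sv) / (2.0 * sq * (q - v[k]));
      if (z <= zz[k]) k--; else break;
    }
    k++;
    v[k] = q;
    zz[k] = k == 0 ? -INF
                   : (f[q] + s * s * q * q - (f[v[k - 1]] + s * s * v[k - 1] * v[k - 1])) /
                         (2.0 * s * s * (q - v[k - 1]));
    zz[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[j + 1] < q) j++;
    double dq = s * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest zero voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dim,
                      NumericVector spacing) {
  static const double INF = std::numeric_limits<double>::infinity();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? INF : 0.0;
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int dims[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const R_xlen_t stride = strides[axis];
    int d1 = (axis + 1) % 3, d2 = (axis + 2) % 3;
    std::vector<double> f(len), d(len);
    for (int j2 = 0; j2 < dims[d2]; ++j2) {
      for (int j1 = 0; j1 < dims[d1]; ++j1) {
        R_xlen_t base = strides[d1] * j1 + strides[d2] * j2;
        bool any_finite = false;
        for (int i = 0; i < len; ++i) {
          f[i] = a[base + stride * i];
          if (f[i] < INF) any_finite = true;
        }
        if (!any_finite) continue;
        dt1d(f, d, len, spacing[axis]);
        for (int i = 0; i < len; ++i) a[base + stride * i] = d[i];
      }
    }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = a[i] == INF ? R_PosInf : std::sqrt(a[i]);
  out.attr("dim") = dim;
  return out;
}
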