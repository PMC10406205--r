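#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel layout throughout: column-major R arrays, dims (nx, ny, nz),
// linear index x + nx*(y + ny*z).

static inline int reflect_idx(int i, int n) {
  // half-sample symmetric reflection: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
  if (n == 1) return 0;
  int period = 2 * n;
  i = ((i % period) + period) % period;
  return (i < n) ? i : (period - 1 - i);
}

// [[Rcpp::export]]
IntegerVector cc_label_26_cpp(IntegerVector mask, int nx, int ny, int nz) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int idx0 = 0; idx0 < (int)mask.size(); ++idx0) {
    if (mask[idx0] == 0 || lab[idx0] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(idx0);
    lab[idx0] = next;
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int nidx = xx + nx * (yy + ny * zz);
            if (mask[nidx] != 0 && lab[nidx] == 0) {
              lab[nidx] = next;
              stack.push_back(nidx);
            }
          }
        }
      }
    }
  }
  return lab;
}

// 1D convolution along one axis (0,1,2) with reflective boundaries.
// kernel has odd length; output grid equals input grid.
// [[Rcpp::export]]
NumericVector sepconv_reflect_cpp(NumericVector vol, int nx, int ny, int nz,
                                  NumericVector kernel, int axis) {
  int klen = kernel.size();
  int r = (klen - 1) / 2;
  NumericVector out(vol.size());
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int na = n[axis], sa = stride[axis];
  // iterate over all lines along `axis`
  int n1, n2, s1, s2;
  if (axis == 0)      { n1 = ny; s1 = nx;      n2 = nz; s2 = nx * ny; }
  else if (axis == 1) { n1 = nx; s1 = 1;       n2 = nz; s2 = nx * ny; }
  else                { n1 = nx; s1 = 1;       n2 = ny; s2 = nx; }
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int src = reflect_idx(i + k - r, na);
          acc += kernel[k] * vol[base + src * sa];
        }
        out[base + i * sa] = acc;
      }
    }
  }
  return out;
}

// Mean filter of width sz along one axis with edge replication.
// Window for output i covers [i - (sz-1)/2, i + sz/2] (integer division).
// [[Rcpp::export]]
NumericVector meanfilter_axis_cpp(NumericVector vol, int nx, int ny, int nz,
                                  int sz, int axis) {
  NumericVector out(vol.size());
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int na = n[axis], sa = stride[axis];
  int lo = (sz - 1) / 2, hi = sz / 2;
  int n1, n2, s1, s2;
  if (axis == 0)      { n1 = ny; s1 = nx;      n2 = nz; s2 = nx * ny; }
  else if (axis == 1) { n1 = nx; s1 = 1;       n2 = nz; s2 = nx * ny; }
  else                { n1 = nx; s1 = 1;       n2 = ny; s2 = nx; }
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int k = -lo; k <= hi; ++k) {
          int src = i + k;
          if (src < 0) src = 0;
          if (src >= na) src = na - 1;
          acc += vol[base + src * sa];
        }
        out[base + i * sa] = acc / sz;
      }
    }
  }
  return out;
}

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return 0.5 * ((2.0 * p1) + (-p0 + p2) * t +
                (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3) * t * t +
                (-p0 + 3.0 * p1 - 3.0 * p2 + p3) * t * t * t);
}

// Cubic (Catmull-Rom) resampling along one axis at fractional positions
// (0-based input coordinates); edge-clamped. Output axis length = length(pos).
// [[Rcpp::export]]
NumericVector interp_axis_cubic_cpp(NumericVector vol, int nx, int ny, int nz,
                                    int axis, NumericVector pos) {
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int na = n[axis], sa = stride[axis];
  int m = pos.size();
  int outdim[3] = {nx, ny, nz};
  outdim[axis] = m;
  NumericVector out((double)outdim[0] * outdim[1] * outdim[2]);
  int ostride[3] = {1, outdim[0], outdim[0] * outdim[1]};
  int osa = ostride[axis];
  int n1, n2, s1, s2, os1, os2;
  if (axis == 0)      { n1 = ny; s1 = nx; os1 = outdim[0]; n2 = nz; s2 = nx * ny; os2 = outdim[0] * outdim[1]; }
  else if (axis == 1) { n1 = nx; s1 = 1;  os1 = 1;         n2 = nz; s2 = nx * ny; os2 = outdim[0] * outdim[1]; }
  else                { n1 = nx; s1 = 1;  os1 = 1;         n2 = ny; s2 = nx;      os2 = outdim[0]; }
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int base = j1 * s1 + j2 * s2;
      int obase = j1 * os1 + j2 * os2;
      for (int i = 0; i < m; ++i) {
        double p = pos[i];
        if (p < 0) p = 0;
        if (p > na - 1) p = na - 1;
        int i1 = (int)std::floor(p);
        if (i1 > na - 2) i1 = na - 2;
        if (i1 < 0) i1 = 0;
        double t = p - i1;
        int i0 = std::max(i1 - 1, 0);
        int i2 = std::min(i1 + 1, na - 1);
        int i3 = std::min(i1 + 2, na - 1);
        out[obase + i * osa] = catmull_rom(vol[base + i0 * sa], vol[base + i1 * sa],
                                           vol[base + i2 * sa], vol[base + i3 * sa], t);
      }
    }
  }
  return out;
}

// Trilinear resampling under an affine map about the volume centre:
// source coordinate = A (x - c) + c + t, out-of-bounds -> fill.
// [[Rcpp::export]]
NumericVector affine_resample_cpp(NumericVector vol, int nx, int ny, int nz,
                                  NumericMatrix A, NumericVector t, double fill) {
  NumericVector out(vol.size());
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        double dx = x - cx, dy = y - cy, dz = z - cz;
        double sx = A(0,0)*dx + A(0,1)*dy + A(0,2)*dz + cx + t[0];
        double sy = A(1,0)*dx + A(1,1)*dy + A(1,2)*dz + cy + t[1];
        double sz = A(2,0)*dx + A(2,1)*dy + A(2,2)*dz + cz + t[2];
        int idx = x + nx * (y + ny * z);
        if (sx < 0 || sx > nx - 1 || sy < 0 || sy > ny - 1 || sz < 0 || sz > nz - 1) {
          out[idx] = fill;
          continue;
        }
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
        int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
        double fx = sx - x0, fy = sy - y0, fz = sz - z0;
        double c000 = vol[x0 + nx*(y0 + ny*z0)], c100 = vol[x1 + nx*(y0 + ny*z0)];
        double c010 = vol[x0 + nx*(y1 + ny*z0)], c110 = vol[x1 + nx*(y1 + ny*z0)];
        double c001 = vol[x0 + nx*(y0 + ny*z1)], c101 = vol[x1 + nx*(y0 + ny*z1)];
        double c011 = vol[x0 + nx*(y1 + ny*z1)], c111 = vol[x1 + nx*(y1 + ny*z1)];
        double c00 = c000 * (1-fx) + c100 * fx;
        double c10 = c010 * (1-fx) + c110 * fx;
        double c01 = c001 * (1-fx) + c101 * fx;
        double c11 = c011 * (1-fx) + c111 * fx;
        double c0 = c00 * (1-fy) + c10 * fy;
        double c1 = c01 * (1-fy) + c11 * fy;
        out[idx] = c0 * (1-fz) + c1 * fz;
      }
    }
  }
  return out;
}

// Cubic B-spline interpolation along one axis with IIR prefiltering
// (pole sqrt(3)-2, mirror boundaries) so that integer positions are
// interpolated exactly.
static void bspline_prefilter_line(std::vector<double> &c) {
  const double z = std::sqrt(3.0) - 2.0;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  int n = c.size();
  if (n == 1) return;
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal init: truncated sum over the mirrored signal
  int horizon = std::min(n, 30);
  double sum = c[0];
  double zn = 1.0;
  for (int k = 1; k < horizon; ++k) {
    zn *= z;
    sum += zn * c[k];
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
  c[n - 1] = (z / (z * z - 1.0)) * (c[n - 1] + z * c[n - 2]);
  for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// [[Rcpp::export]]
NumericVector interp_axis_bspline_cpp(NumericVector vol, int nx, int ny, int nz,
                                      int axis, NumericVector pos) {
  int n[3] = {nx, ny, nz};
  int stride[3] = {1, nx, nx * ny};
  int na = n[axis], sa = stride[axis];
  int m = pos.size();
  int outdim[3] = {nx, ny, nz};
  outdim[axis] = m;
  NumericVector out((double)outdim[0] * outdim[1] * outdim[2]);
  int ostride[3] = {1, outdim[0], outdim[0] * outdim[1]};
  int osa = ostride[axis];
  int n1, n2, s1, s2, os1, os2;
  if (axis == 0)      { n1 = ny; s1 = nx; os1 = outdim[0]; n2 = nz; s2 = nx * ny; os2 = outdim[0] * outdim[1]; }
  else if (axis == 1) { n1 = nx; s1 = 1;  os1 = 1;         n2 = nz; s2 = nx * ny; os2 = outdim[0] * outdim[1]; }
  else                { n1 = nx; s1 = 1;  os1 = 1;         n2 = ny; s2 = nx;      os2 = outdim[0]; }
  std::vector<double> line(na);
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int base = j1 * s1 + j2 * s2;
      int obase = j1 * os1 + j2 * os2;
      for (int i = 0; i < na; ++i) line[i] = vol[base + i * sa];
      bspline_prefilter_line(line);
      for (int i = 0; i < m; ++i) {
        double p = pos[i];
        if (p < 0) p = 0;
        if (p > na - 1) p = na - 1;
        int i1 = (int)std::floor(p);
        double t = p - i1;
        double t2 = t * t, t3 = t2 * t;
        double w0 = (1 - 3 * t + 3 * t2 - t3) / 6.0;
        double w1 = (4 - 6 * t2 + 3 * t3) / 6.0;
        double w2 = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
        double w3 = t3 / 6.0;
        out[obase + i * osa] =
          w0 * line[mirror_idx(i1 - 1, na)] + w1 * line[mirror_idx(i1, na)] +
          w2 * line[mirror_idx(i1 + 1, na)] + w3 * line[mirror_idx(i1 + 2, na)];
      }
    }
  }
  return out;
}
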