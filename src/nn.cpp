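#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Tensor layout: column-major R arrays (nx, ny, nz, channels),
// weights (k, k, k, cin, cout), "same" zero padding, odd k.

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector input, int nx, int ny, int nz, int cin,
                             NumericVector w, int k, int cout, NumericVector b) {
  int r = (k - 1) / 2;
  long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * cout);
  const double *in = input.begin();
  const double *wp = w.begin();
  double *op = out.begin();
  for (int co = 0; co < cout; ++co) {
    long obase = (long)co * nvox;
    double bias = b[co];
    for (long i = 0; i < nvox; ++i) op[obase + i] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      long ibase = (long)ci * nvox;
      const double *wk = wp + (long)k * k * k * (ci + (long)cin * co);
      for (int kz = 0; kz < k; ++kz) {
        int dz = kz - r;
        for (int ky = 0; ky < k; ++ky) {
          int dy = ky - r;
          for (int kx = 0; kx < k; ++kx) {
            int dx = kx - r;
            double wv = wk[kx + k * (ky + k * kz)];
            if (wv == 0.0) continue;
            int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
            int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
            int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                long orow = obase + (long)nx * (y + (long)ny * z);
                long irow = ibase + (long)(x0 + dx) + (long)nx * ((y + dy) + (long)ny * (z + dz));
                double *orp = op + orow + x0;
                const double *irp = in + irow;
                int len = x1 - x0;
                for (int x = 0; x < len; ++x) orp[x] += wv * irp[x];
              }
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector input, int nx, int ny, int nz, int cin,
                    NumericVector w, int k, int cout, NumericVector gout) {
  int r = (k - 1) / 2;
  long nvox = (long)nx * ny * nz;
  NumericVector gin(nvox * cin);
  NumericVector gw(w.size());
  NumericVector gb(cout);
  const double *in = input.begin();
  const double *wp = w.begin();
  const double *go = gout.begin();
  double *gi = gin.begin();
  double *gwp = gw.begin();
  for (int co = 0; co < cout; ++co) {
    long obase = (long)co * nvox;
    double acc = 0.0;
    for (long i = 0; i < nvox; ++i) acc += go[obase + i];
    gb[co] = acc;
    for (int ci = 0; ci < cin; ++ci) {
      long ibase = (long)ci * nvox;
      const double *wk = wp + (long)k * k * k * (ci + (long)cin * co);
      double *gwk = gwp + (long)k * k * k * (ci + (long)cin * co);
      for (int kz = 0; kz < k; ++kz) {
        int dz = kz - r;
        for (int ky = 0; ky < k; ++ky) {
          int dy = ky - r;
          for (int kx = 0; kx < k; ++kx) {
            int dx = kx - r;
            double wv = wk[kx + k * (ky + k * kz)];
            double gwacc = 0.0;
            int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
            int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
            int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            for (int z = z0; z < z1; ++z) {
              for (int y = y0; y < y1; ++y) {
                long orow = obase + (long)x0 + (long)nx * (y + (long)ny * z);
                long irow = ibase + (long)(x0 + dx) + (long)nx * ((y + dy) + (long)ny * (z + dz));
                const double *gor = go + orow;
                const double *irp = in + irow;
                double *gir = gi + irow;
                int len = x1 - x0;
                for (int x = 0; x < len; ++x) {
                  gwacc += gor[x] * irp[x];
                  gir[x] += wv * gor[x];
                }
              }
            }
            gwk[kx + k * (ky + k * kz)] += gwacc;
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  gw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  return List::create(Named("gin") = gin, Named("gw") = gw, Named("gb") = gb);
}

// 2x2x2 average pooling (dims must be even).
// [[Rcpp::export]]
NumericVector avgpool2_fwd_cpp(NumericVector input, int nx, int ny, int nz, int c) {
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  long onvox = (long)ox * oy * oz;
  NumericVector out(onvox * c);
  const double *in = input.begin();
  double *op = out.begin();
  for (int ch = 0; ch < c; ++ch) {
    long ib = (long)ch * nx * ny * nz;
    long ob = (long)ch * onvox;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                acc += in[ib + (2*x+dx) + (long)nx * ((2*y+dy) + (long)ny * (2*z+dz))];
          op[ob + x + (long)ox * (y + (long)oy * z)] = acc / 8.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return out;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd_cpp(NumericVector gout, int nx, int ny, int nz, int c) {
  // nx,ny,nz are the *input* (fine) dims
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  long onvox = (long)ox * oy * oz;
  NumericVector gin((long)nx * ny * nz * c);
  const double *go = gout.begin();
  double *gi = gin.begin();
  for (int ch = 0; ch < c; ++ch) {
    long ib = (long)ch * nx * ny * nz;
    long ob = (long)ch * onvox;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x) {
          double g = go[ob + x + (long)ox * (y + (long)oy * z)] / 8.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                gi[ib + (2*x+dx) + (long)nx * ((2*y+dy) + (long)ny * (2*z+dz))] = g;
        }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, c);
  return gin;
}

// Nearest-neighbour x2 upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector input, int nx, int ny, int nz, int c) {
  int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  NumericVector out((long)ox * oy * oz * c);
  const double *in = input.begin();
  double *op = out.begin();
  for (int ch = 0; ch < c; ++ch) {
    long ib = (long)ch * nx * ny * nz;
    long ob = (long)ch * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x)
          op[ob + x + (long)ox * (y + (long)oy * z)] =
            in[ib + (x/2) + (long)nx * ((y/2) + (long)ny * (z/2))];
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz, c);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector gout, int nx, int ny, int nz, int c) {
  // nx,ny,nz are the *input* (coarse) dims
  int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  NumericVector gin((long)nx * ny * nz * c);
  const double *go = gout.begin();
  double *gi = gin.begin();
  for (int ch = 0; ch < c; ++ch) {
    long ib = (long)ch * nx * ny * nz;
    long ob = (long)ch * ox * oy * oz;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y)
        for (int x = 0; x < ox; ++x)
          gi[ib + (x/2) + (long)nx * ((y/2) + (long)ny * (z/2))] +=
            go[ob + x + (long)ox * (y + (long)oy * z)];
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, c);
  return gin;
}

// im2col for k x k x k "same" zero-padded convolution: output matrix
// (nvox x k^3*cin), column index kx + k*(ky + k*(kz + k*ci)) to match the
// column-major reshape of weights (k,k,k,cin,cout).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector input, int nx, int ny, int nz, int cin,
                         int k) {
  int r = (k - 1) / 2;
  long nvox = (long)nx * ny * nz;
  NumericMatrix cols(nvox, (long)k * k * k * cin);
  const double *in = input.begin();
  double *cp = cols.begin();
  for (int ci = 0; ci < cin; ++ci) {
    long ibase = (long)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      int dz = kz - r;
      for (int ky = 0; ky < k; ++ky) {
        int dy = ky - r;
        for (int kx = 0; kx < k; ++kx) {
          int dx = kx - r;
          long col = kx + (long)k * (ky + (long)k * (kz + (long)k * ci));
          double *dst = cp + col * nvox;
          int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              long drow = (long)x0 + (long)nx * (y + (long)ny * z);
              long srow = ibase + (long)(x0 + dx) + (long)nx * ((y + dy) + (long)ny * (z + dz));
              const double *sp = in + srow;
              double *dp = dst + drow;
              int len = x1 - x0;
              for (int x = 0; x < len; ++x) dp[x] = sp[x];
            }
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add a (nvox x k^3*cin) gradient matrix back to
// the input grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix gcols, int nx, int ny, int nz, int cin,
                         int k) {
  int r = (k - 1) / 2;
  long nvox = (long)nx * ny * nz;
  NumericVector gin(nvox * cin);
  const double *cp = gcols.begin();
  double *gi = gin.begin();
  for (int ci = 0; ci < cin; ++ci) {
    long ibase = (long)ci * nvox;
    for (int kz = 0; kz < k; ++kz) {
      int dz = kz - r;
      for (int ky = 0; ky < k; ++ky) {
        int dy = ky - r;
        for (int kx = 0; kx < k; ++kx) {
          int dx = kx - r;
          long col = kx + (long)k * (ky + (long)k * (kz + (long)k * ci));
          const double *src = cp + col * nvox;
          int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              long srow = (long)x0 + (long)nx * (y + (long)ny * z);
              long drow = ibase + (long)(x0 + dx) + (long)nx * ((y + dy) + (long)ny * (z + dz));
              const double *sp = src + srow;
              double *dp = gi + drow;
              int len = x1 - x0;
              for (int x = 0; x < len; ++x) dp[x] += sp[x];
            }
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return gin;
}
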