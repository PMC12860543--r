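#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parallel-beam SPECT projector with attenuation and distance-dependent
// collimator-detector response (CDR).
//
// Volume layout: x fastest, dims (nx, ny, nz); rotation is in-plane (x, y)
// about the grid centre ((nx-1)/2, (ny-1)/2); rays run along +y towards a
// detector plane at distance r0 (cm) from the rotation axis.  The adjoint is
// exact: rotation is a gather with bilinear weights, its adjoint a scatter
// with the same weights; the depth-dependent Gaussian blur is symmetric with
// zero padding, hence self-adjoint; the depth sum's adjoint is a broadcast.
// ---------------------------------------------------------------------------

static inline double fwhm_at(double d, double intercept, double slope) {
  double f = intercept + slope * d;
  return f > 1e-6 ? f : 1e-6;
}

// Bilinear in-plane rotation (gather).  theta rotates the sampling frame.
static void rotate_gather(const double* vol, double* out,
                          int nx, int ny, int nz, double theta) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      // source position in original frame
      double dx = x - cx, dy = y - cy;
      double sx = cx + ct * dx - st * dy;
      double sy = cy + st * dx + ct * dy;
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      double w01 = (1 - fx) * fy, w11 = fx * fy;
      bool i00 = x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny;
      bool i10 = x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny;
      bool i01 = x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      bool i11 = x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      for (int z = 0; z < nz; ++z) {
        const double* s = vol + (size_t)z * nx * ny;
        double v = 0.0;
        if (i00) v += w00 * s[y0 * nx + x0];
        if (i10) v += w10 * s[y0 * nx + x0 + 1];
        if (i01) v += w01 * s[(y0 + 1) * nx + x0];
        if (i11) v += w11 * s[(y0 + 1) * nx + x0 + 1];
        out[(size_t)z * nx * ny + y * nx + x] = v;
      }
    }
  }
}

// Adjoint of rotate_gather: scatter with the same weights.
static void rotate_scatter(const double* rot, double* acc,
                           int nx, int ny, int nz, double theta) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      double dx = x - cx, dy = y - cy;
      double sx = cx + ct * dx - st * dy;
      double sy = cy + st * dx + ct * dy;
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      double w01 = (1 - fx) * fy, w11 = fx * fy;
      bool i00 = x0 >= 0 && x0 < nx && y0 >= 0 && y0 < ny;
      bool i10 = x0 + 1 >= 0 && x0 + 1 < nx && y0 >= 0 && y0 < ny;
      bool i01 = x0 >= 0 && x0 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      bool i11 = x0 + 1 >= 0 && x0 + 1 < nx && y0 + 1 >= 0 && y0 + 1 < ny;
      for (int z = 0; z < nz; ++z) {
        double v = rot[(size_t)z * nx * ny + y * nx + x];
        if (v == 0.0) continue;
        double* t = acc + (size_t)z * nx * ny;
        if (i00) t[y0 * nx + x0] += w00 * v;
        if (i10) t[y0 * nx + x0 + 1] += w10 * v;
        if (i01) t[(y0 + 1) * nx + x0] += w01 * v;
        if (i11) t[(y0 + 1) * nx + x0 + 1] += w11 * v;
      }
    }
  }
}

// Attenuation survival factors in the rotated frame (detector at +y).
// exponent = h * (0.5*mu(self) + sum of mu between voxel and detector).
static void atten_factors(const double* rmu, double* att,
                          int nx, int ny, int nz, double h) {
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      double cum = 0.0;
      for (int y = ny - 1; y >= 0; --y) {
        size_t i = (size_t)z * nx * ny + (size_t)y * nx + x;
        att[i] = std::exp(-h * (cum + 0.5 * rmu[i]));
        cum += rmu[i];
      }
    }
  }
}

// Symmetric normalized Gaussian blur of a (nx, nz) plane, zero padding,
// applied separably in x then z.  Self-adjoint.
static void blur_plane(std::vector<double>& p, std::vector<double>& tmp,
                       int nx, int nz, double sigma) {
  if (sigma < 0.05) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  // along x
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      double a = 0.0;
      int lo = std::max(-r, -x), hi = std::min(r, nx - 1 - x);
      for (int i = lo; i <= hi; ++i) a += k[i + r] * p[(size_t)z * nx + x + i];
      tmp[(size_t)z * nx + x] = a;
    }
  }
  // along z
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      double a = 0.0;
      int lo = std::max(-r, -z), hi = std::min(r, nz - 1 - z);
      for (int i = lo; i <= hi; ++i) a += k[i + r] * tmp[(size_t)(z + i) * nx + x];
      p[(size_t)z * nx + x] = a;
    }
  }
}

// Precompute per-view attenuation factor volumes (rotated frame) so OSEM
// does not redo the rotations and exponentials at every subiteration.
// Layout: [nvol x nviews].
// [[Rcpp::export]]
NumericVector cpp_att_cache(NumericVector mu, IntegerVector dims, double h,
                            NumericVector angles) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nv = angles.size();
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector out(nvol * nv);
  std::vector<double> rm(nvol);
  for (int v = 0; v < nv; ++v) {
    rotate_gather(REAL(mu), rm.data(), nx, ny, nz, -angles[v]);
    atten_factors(rm.data(), REAL(out) + (size_t)v * nvol, nx, ny, nz, h);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector activity, Nullable<NumericVector> mu,
                          IntegerVector dims, double h, NumericVector angles,
                          double r0, double fwhmIntercept, double fwhmSlope,
                          bool useCdr,
                          Nullable<NumericVector> attCache = R_NilValue,
                          Nullable<IntegerVector> attIdx = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nv = angles.size();
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector sino((size_t)nx * nz * nv);
  std::vector<double> rv(nvol), rm(nvol), att(nvol), plane(nx * nz), tmp(nx * nz);
  const bool hasMu = mu.isNotNull();
  const bool hasCache = attCache.isNotNull();
  NumericVector muv, cachev;
  IntegerVector idxv;
  if (hasMu) muv = mu.get();
  if (hasCache) { cachev = attCache.get(); idxv = attIdx.get(); }
  const double cy = 0.5 * (ny - 1);
  for (int v = 0; v < nv; ++v) {
    // activity enters the rotated frame by splatting (adjoint of bilinear
    // gather): exactly count-conserving, so a source of a counts projects
    // to a counts per view (up to attenuation)
    std::fill(rv.begin(), rv.end(), 0.0);
    rotate_scatter(REAL(activity), rv.data(), nx, ny, nz, angles[v]);
    if (hasCache) {
      const double* av = REAL(cachev) + (size_t)(idxv[v] - 1) * nvol;
      for (size_t i = 0; i < nvol; ++i) rv[i] *= av[i];
    } else if (hasMu) {
      // mu is a value field, not a density: interpolate (gather by -theta
      // places mu in the same rotated frame as the splatted activity)
      rotate_gather(REAL(muv), rm.data(), nx, ny, nz, -angles[v]);
      atten_factors(rm.data(), att.data(), nx, ny, nz, h);
      for (size_t i = 0; i < nvol; ++i) rv[i] *= att[i];
    }
    double* out = REAL(sino) + (size_t)v * nx * nz;
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
          plane[(size_t)z * nx + x] = rv[(size_t)z * nx * ny + (size_t)y * nx + x];
      if (useCdr) {
        double d = r0 - (y - cy) * h;  // distance voxel plane -> detector
        double sig = fwhm_at(d, fwhmIntercept, fwhmSlope) / 2.35482 / h;
        blur_plane(plane, tmp, nx, nz, sig);
      }
      for (int i = 0; i < nx * nz; ++i) out[i] += plane[i];
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, Nullable<NumericVector> mu,
                              IntegerVector dims, double h, NumericVector angles,
                              double r0, double fwhmIntercept, double fwhmSlope,
                              bool useCdr,
                              Nullable<NumericVector> attCache = R_NilValue,
                              Nullable<IntegerVector> attIdx = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nv = angles.size();
  const size_t nvol = (size_t)nx * ny * nz;
  NumericVector vol(nvol);
  std::vector<double> rv(nvol), rm(nvol), att(nvol), plane(nx * nz), tmp(nx * nz);
  const bool hasMu = mu.isNotNull();
  const bool hasCache = attCache.isNotNull();
  NumericVector muv, cachev;
  IntegerVector idxv;
  if (hasMu) muv = mu.get();
  if (hasCache) { cachev = attCache.get(); idxv = attIdx.get(); }
  const double cy = 0.5 * (ny - 1);
  for (int v = 0; v < nv; ++v) {
    const double* g = REAL(sino) + (size_t)v * nx * nz;
    for (int y = 0; y < ny; ++y) {
      for (int i = 0; i < nx * nz; ++i) plane[i] = g[i];
      if (useCdr) {
        double d = r0 - (y - cy) * h;
        double sig = fwhm_at(d, fwhmIntercept, fwhmSlope) / 2.35482 / h;
        blur_plane(plane, tmp, nx, nz, sig);
      }
      for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x)
          rv[(size_t)z * nx * ny + (size_t)y * nx + x] = plane[(size_t)z * nx + x];
    }
    if (hasCache) {
      const double* av = REAL(cachev) + (size_t)(idxv[v] - 1) * nvol;
      for (size_t i = 0; i < nvol; ++i) rv[i] *= av[i];
    } else if (hasMu) {
      rotate_gather(REAL(muv), rm.data(), nx, ny, nz, -angles[v]);
      atten_factors(rm.data(), att.data(), nx, ny, nz, h);
      for (size_t i = 0; i < nvol; ++i) rv[i] *= att[i];
    }
    // adjoint of the forward splat is a bilinear gather with the same angle
    rotate_gather(rv.data(), rm.data(), nx, ny, nz, angles[v]);
    double* out = REAL(vol);
    for (size_t i = 0; i < nvol; ++i) out[i] += rm[i];
  }
  return vol;
}

// Separable 3-D Gaussian blur, zero padding (used for the scatter-source
// fluence surrogate and wide sinogram smoothing).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sigma < 0.05) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& v : k) v /= s;
  NumericVector a = clone(vol), b(vol.size());
  // x pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    size_t off = (size_t)z * nx * ny + (size_t)y * nx;
    for (int x = 0; x < nx; ++x) {
      double acc = 0.0; int lo = std::max(-r, -x), hi = std::min(r, nx - 1 - x);
      for (int i = lo; i <= hi; ++i) acc += k[i + r] * a[off + x + i];
      b[off + x] = acc;
    }
  }
  // y pass
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    size_t off = (size_t)z * nx * ny + x;
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0; int lo = std::max(-r, -y), hi = std::min(r, ny - 1 - y);
      for (int i = lo; i <= hi; ++i) acc += k[i + r] * b[off + (size_t)(y + i) * nx];
      a[off + (size_t)y * nx] = acc;
    }
  }
  // z pass
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    size_t off = (size_t)y * nx + x;
    for (int z = 0; z < nz; ++z) {
      double acc = 0.0; int lo = std::max(-r, -z), hi = std::min(r, nz - 1 - z);
      for (int i = lo; i <= hi; ++i) acc += k[i + r] * a[off + (size_t)(z + i) * nx * ny];
      b[off + (size_t)z * nx * ny] = acc;
    }
  }
  return b;
}

// ---------------------------------------------------------------------------
// im2col / col2im for 3-D convolution (cubic kernel, isotropic stride/pad).
// Feature maps are stored as [Nvox x C] matrices, voxel index x-fastest.
// Column layout: c * k^3 + (kz * k + ky) * k + kx.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix x, IntegerVector dims, int k, int stride, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = x.ncol();
  const int o1 = (d1 + 2 * pad - k) / stride + 1;
  const int o2 = (d2 + 2 * pad - k) / stride + 1;
  const int o3 = (d3 + 2 * pad - k) / stride + 1;
  const size_t Nout = (size_t)o1 * o2 * o3;
  NumericMatrix cols(Nout, C * k * k * k);
  const double* xp = REAL(x);
  double* cp = REAL(cols);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int kz = 0; kz < k; ++kz) for (int ky = 0; ky < k; ++ky) for (int kx = 0; kx < k; ++kx) {
      size_t col = (size_t)c * k * k * k + ((size_t)kz * k + ky) * k + kx;
      double* dst = cp + col * Nout;
      for (int z = 0; z < o3; ++z) {
        int iz = z * stride + kz - pad;
        bool okz = iz >= 0 && iz < d3;
        for (int y = 0; y < o2; ++y) {
          int iy = y * stride + ky - pad;
          bool oky = okz && iy >= 0 && iy < d2;
          size_t orow = ((size_t)z * o2 + y) * o1;
          if (!oky) {
            for (int xo = 0; xo < o1; ++xo) dst[orow + xo] = 0.0;
            continue;
          }
          size_t irow = ((size_t)iz * d2 + iy) * d1;
          for (int xo = 0; xo < o1; ++xo) {
            int ix = xo * stride + kx - pad;
            dst[orow + xo] = (ix >= 0 && ix < d1) ? xc[irow + ix] : 0.0;
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: accumulate columns back into a [Nvox x C] map.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix cols, IntegerVector dims, int C, int k,
                         int stride, int pad) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = (d1 + 2 * pad - k) / stride + 1;
  const int o2 = (d2 + 2 * pad - k) / stride + 1;
  const int o3 = (d3 + 2 * pad - k) / stride + 1;
  const size_t Nout = (size_t)o1 * o2 * o3;
  NumericMatrix x((size_t)d1 * d2 * d3, C);
  const double* cp = REAL(cols);
  double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int kz = 0; kz < k; ++kz) for (int ky = 0; ky < k; ++ky) for (int kx = 0; kx < k; ++kx) {
      size_t col = (size_t)c * k * k * k + ((size_t)kz * k + ky) * k + kx;
      const double* src = cp + col * Nout;
      for (int z = 0; z < o3; ++z) {
        int iz = z * stride + kz - pad;
        if (iz < 0 || iz >= d3) continue;
        for (int y = 0; y < o2; ++y) {
          int iy = y * stride + ky - pad;
          if (iy < 0 || iy >= d2) continue;
          size_t orow = ((size_t)z * o2 + y) * o1;
          size_t irow = ((size_t)iz * d2 + iy) * d1;
          for (int xo = 0; xo < o1; ++xo) {
            int ix = xo * stride + kx - pad;
            if (ix >= 0 && ix < d1) xc[irow + ix] += src[orow + xo];
          }
        }
      }
    }
  }
  return x;
}

// ---------------------------------------------------------------------------
// Fused 3-D convolution / transposed convolution: im2col restricted to a
// chunk of output slices into a persistent buffer, then BLAS GEMM.  Feature
// maps are [Nvox x C] column-major matrices (voxel index x-fastest).
// A float32 fast path (fp32 = true) halves memory traffic and uses sgemm;
// the float64 path is bit-stable and serves as the reference in tests.
// ---------------------------------------------------------------------------

static std::vector<double> g_buf1, g_buf2;
static std::vector<float> g_fbuf1, g_fbuf2, g_fx, g_fw, g_fy;

struct ConvGeom {
  int d1, d2, d3, C, k, stride, pad, o1, o2, o3;
  ConvGeom(const IntegerVector& dims, int C_, int k_, int s_, int p_)
    : d1(dims[0]), d2(dims[1]), d3(dims[2]), C(C_), k(k_), stride(s_), pad(p_) {
    o1 = (d1 + 2 * pad - k) / stride + 1;
    o2 = (d2 + 2 * pad - k) / stride + 1;
    o3 = (d3 + 2 * pad - k) / stride + 1;
  }
};

// im2col columns for output slices [z0, z1); buf is column-major with
// leading dimension rows = (z1-z0)*o1*o2, column index c*k^3 + tap
template <typename TS, typename TD>
static void fill_cols(const TS* x, const ConvGeom& G, int z0, int z1, TD* buf) {
  const size_t rows = (size_t)(z1 - z0) * G.o1 * G.o2;
  for (int c = 0; c < G.C; ++c) {
    const TS* xc = x + (size_t)c * G.d1 * G.d2 * G.d3;
    for (int kz = 0; kz < G.k; ++kz) for (int ky = 0; ky < G.k; ++ky)
    for (int kx = 0; kx < G.k; ++kx) {
      size_t col = (size_t)c * G.k * G.k * G.k +
                   ((size_t)kz * G.k + ky) * G.k + kx;
      TD* dst = buf + col * rows;
      for (int z = z0; z < z1; ++z) {
        int iz = z * G.stride + kz - G.pad;
        bool okz = iz >= 0 && iz < G.d3;
        for (int y = 0; y < G.o2; ++y) {
          int iy = y * G.stride + ky - G.pad;
          TD* drow = dst + ((size_t)(z - z0) * G.o2 + y) * G.o1;
          if (!okz || iy < 0 || iy >= G.d2) {
            std::fill(drow, drow + G.o1, (TD)0);
            continue;
          }
          const TS* srow = xc + ((size_t)iz * G.d2 + iy) * G.d1;
          int xlo = 0, xhi = G.o1;
          while (xlo < G.o1 && xlo * G.stride + kx - G.pad < 0) ++xlo;
          while (xhi > xlo && (xhi - 1) * G.stride + kx - G.pad >= G.d1) --xhi;
          for (int xo = 0; xo < xlo; ++xo) drow[xo] = (TD)0;
          if (G.stride == 1) {
            const TS* s0 = srow + kx - G.pad;
            for (int xo = xlo; xo < xhi; ++xo) drow[xo] = (TD)s0[xo];
          } else {
            for (int xo = xlo; xo < xhi; ++xo)
              drow[xo] = (TD)srow[xo * G.stride + kx - G.pad];
          }
          for (int xo = xhi; xo < G.o1; ++xo) drow[xo] = (TD)0;
        }
      }
    }
  }
}

// adjoint of fill_cols: accumulate columns back into x
template <typename TS, typename TD>
static void scatter_cols(const TS* buf, const ConvGeom& G, int z0, int z1, TD* x) {
  const size_t rows = (size_t)(z1 - z0) * G.o1 * G.o2;
  for (int c = 0; c < G.C; ++c) {
    TD* xc = x + (size_t)c * G.d1 * G.d2 * G.d3;
    for (int kz = 0; kz < G.k; ++kz) for (int ky = 0; ky < G.k; ++ky)
    for (int kx = 0; kx < G.k; ++kx) {
      size_t col = (size_t)c * G.k * G.k * G.k +
                   ((size_t)kz * G.k + ky) * G.k + kx;
      const TS* src = buf + col * rows;
      for (int z = z0; z < z1; ++z) {
        int iz = z * G.stride + kz - G.pad;
        if (iz < 0 || iz >= G.d3) continue;
        for (int y = 0; y < G.o2; ++y) {
          int iy = y * G.stride + ky - G.pad;
          if (iy < 0 || iy >= G.d2) continue;
          const TS* srow = src + ((size_t)(z - z0) * G.o2 + y) * G.o1;
          TD* drow = xc + ((size_t)iz * G.d2 + iy) * G.d1;
          int xlo = 0, xhi = G.o1;
          while (xlo < G.o1 && xlo * G.stride + kx - G.pad < 0) ++xlo;
          while (xhi > xlo && (xhi - 1) * G.stride + kx - G.pad >= G.d1) --xhi;
          if (G.stride == 1) {
            TD* d0 = drow + kx - G.pad;
            for (int xo = xlo; xo < xhi; ++xo) d0[xo] += (TD)srow[xo];
          } else {
            for (int xo = xlo; xo < xhi; ++xo)
              drow[xo * G.stride + kx - G.pad] += (TD)srow[xo];
          }
        }
      }
    }
  }
}

// chunk as many output slices as fit a ~128 MB column buffer
static int chunk_slices(const ConvGeom& G, int CK) {
  double maxElems = 16.0e6;
  int t = (int)(maxElems / ((double)G.o1 * G.o2 * CK));
  if (t < 1) t = 1;
  if (t > G.o3) t = G.o3;
  return t;
}

static void dgemm_(const char* ta, const char* tb, int m, int n, int k,
                   double alpha, const double* A, int lda, const double* B,
                   int ldb, double beta, double* Cm, int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  Cm, &ldc FCONE FCONE);
}

// single-precision GEMM: present in the linked BLAS but not declared by
// the R headers (which cover double precision only)
extern "C" void F77_NAME(sgemm)(const char* transa, const char* transb,
                                const int* m, const int* n, const int* k,
                                const float* alpha, const float* a,
                                const int* lda, const float* b,
                                const int* ldb, const float* beta, float* c,
                                const int* ldc FCLEN FCLEN);

static void sgemm_wrap(const char* ta, const char* tb, int m, int n, int k,
                       float alpha, const float* A, int lda, const float* B,
                       int ldb, float beta, float* Cm, int ldc) {
  F77_CALL(sgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  Cm, &ldc FCONE FCONE);
}

static void to_float(const double* src, size_t n, std::vector<float>& dst) {
  dst.resize(n);
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3d_fwd(NumericMatrix x, IntegerVector dims,
                             NumericMatrix W, NumericVector b, int k,
                             int stride, int pad, bool fp32 = true) {
  ConvGeom G(dims, x.ncol(), k, stride, pad);
  const int CK = G.C * k * k * k, Cout = W.ncol();
  const size_t Nout = (size_t)G.o1 * G.o2 * G.o3;
  NumericMatrix Y(Nout, Cout);
  const int T = chunk_slices(G, CK);
  if (fp32) {
    to_float(REAL(x), (size_t)x.nrow() * G.C, g_fx);
    to_float(REAL(W), (size_t)CK * Cout, g_fw);
    g_fbuf1.resize((size_t)T * G.o1 * G.o2 * CK);
    g_fy.resize(Nout * Cout);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      fill_cols(g_fx.data(), G, z0, z1, g_fbuf1.data());
      sgemm_wrap("N", "N", rows, Cout, CK, 1.0f, g_fbuf1.data(), rows,
             g_fw.data(), CK, 0.0f, g_fy.data() + (size_t)z0 * G.o1 * G.o2,
             (int)Nout);
    }
    double* yp = REAL(Y);
    for (int co = 0; co < Cout; ++co) {
      const float* fc = g_fy.data() + (size_t)co * Nout;
      double* yc = yp + (size_t)co * Nout;
      for (size_t i = 0; i < Nout; ++i) yc[i] = (double)fc[i] + b[co];
    }
    return Y;
  }
  g_buf1.resize((size_t)T * G.o1 * G.o2 * CK);
  for (int z0 = 0; z0 < G.o3; z0 += T) {
    int z1 = std::min(z0 + T, G.o3);
    int rows = (z1 - z0) * G.o1 * G.o2;
    fill_cols(REAL(x), G, z0, z1, g_buf1.data());
    dgemm_("N", "N", rows, Cout, CK, 1.0, g_buf1.data(), rows, REAL(W), CK,
           0.0, REAL(Y) + (size_t)z0 * G.o1 * G.o2, (int)Nout);
  }
  for (int co = 0; co < Cout; ++co) {
    double* yc = REAL(Y) + (size_t)co * Nout;
    for (size_t i = 0; i < Nout; ++i) yc[i] += b[co];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericMatrix x, IntegerVector dims, NumericMatrix W,
                    int k, int stride, int pad, NumericMatrix dY,
                    bool fp32 = true) {
  ConvGeom G(dims, x.ncol(), k, stride, pad);
  const int CK = G.C * k * k * k, Cout = W.ncol();
  const size_t Nout = (size_t)G.o1 * G.o2 * G.o3;
  NumericMatrix dW(CK, Cout), dX(x.nrow(), G.C);
  NumericVector db(Cout);
  const int T = chunk_slices(G, CK);
  if (fp32) {
    to_float(REAL(x), (size_t)x.nrow() * G.C, g_fx);
    to_float(REAL(W), (size_t)CK * Cout, g_fw);
    std::vector<float> fdY; to_float(REAL(dY), Nout * Cout, fdY);
    std::vector<float> fdW((size_t)CK * Cout, 0.0f);
    std::vector<float> fdX((size_t)x.nrow() * G.C, 0.0f);
    g_fbuf1.resize((size_t)T * G.o1 * G.o2 * CK);
    g_fbuf2.resize((size_t)T * G.o1 * G.o2 * CK);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      const float* dYc = fdY.data() + (size_t)z0 * G.o1 * G.o2;
      fill_cols(g_fx.data(), G, z0, z1, g_fbuf1.data());
      sgemm_wrap("T", "N", CK, Cout, rows, 1.0f, g_fbuf1.data(), rows, dYc,
             (int)Nout, 1.0f, fdW.data(), CK);
      sgemm_wrap("N", "T", rows, CK, Cout, 1.0f, dYc, (int)Nout, g_fw.data(),
             CK, 0.0f, g_fbuf2.data(), rows);
      scatter_cols(g_fbuf2.data(), G, z0, z1, fdX.data());
    }
    std::copy(fdW.begin(), fdW.end(), REAL(dW));
    std::copy(fdX.begin(), fdX.end(), REAL(dX));
  } else {
    g_buf1.resize((size_t)T * G.o1 * G.o2 * CK);
    g_buf2.resize((size_t)T * G.o1 * G.o2 * CK);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      const double* dYc = REAL(dY) + (size_t)z0 * G.o1 * G.o2;
      fill_cols(REAL(x), G, z0, z1, g_buf1.data());
      dgemm_("T", "N", CK, Cout, rows, 1.0, g_buf1.data(), rows, dYc,
             (int)Nout, 1.0, REAL(dW), CK);
      dgemm_("N", "T", rows, CK, Cout, 1.0, dYc, (int)Nout, REAL(W), CK, 0.0,
             g_buf2.data(), rows);
      scatter_cols(g_buf2.data(), G, z0, z1, REAL(dX));
    }
  }
  for (int co = 0; co < Cout; ++co) {
    const double* yc = REAL(dY) + (size_t)co * Nout;
    double s = 0.0;
    for (size_t i = 0; i < Nout; ++i) s += yc[i];
    db[co] = s;
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// transposed convolution: W is [Cup*k^3 x Cdown]; the output (up) grid has
// dims od = (dims-1)*stride + k - 2*pad and the conv geometry maps od -> dims
// [[Rcpp::export]]
NumericMatrix cpp_tconv3d_fwd(NumericMatrix x, IntegerVector dims,
                              NumericMatrix W, NumericVector b, int k,
                              int stride, int pad, bool fp32 = true) {
  const int Cd = x.ncol(), CuK = W.nrow(), Cu = CuK / (k * k * k);
  IntegerVector od(3);
  for (int i = 0; i < 3; ++i) od[i] = (dims[i] - 1) * stride + k - 2 * pad;
  ConvGeom G(od, Cu, k, stride, pad);  // output grid of G == input dims
  const size_t Nbig = (size_t)od[0] * od[1] * od[2];
  const size_t Nsmall = (size_t)dims[0] * dims[1] * dims[2];
  NumericMatrix Y(Nbig, Cu);
  const int T = chunk_slices(G, CuK);
  if (fp32) {
    to_float(REAL(x), Nsmall * Cd, g_fx);
    to_float(REAL(W), (size_t)CuK * Cd, g_fw);
    std::vector<float> fY(Nbig * Cu, 0.0f);
    g_fbuf1.resize((size_t)T * G.o1 * G.o2 * CuK);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      sgemm_wrap("N", "T", rows, CuK, Cd, 1.0f,
             g_fx.data() + (size_t)z0 * G.o1 * G.o2, (int)Nsmall,
             g_fw.data(), CuK, 0.0f, g_fbuf1.data(), rows);
      scatter_cols(g_fbuf1.data(), G, z0, z1, fY.data());
    }
    double* yp = REAL(Y);
    for (int co = 0; co < Cu; ++co) {
      const float* fc = fY.data() + (size_t)co * Nbig;
      double* yc = yp + (size_t)co * Nbig;
      for (size_t i = 0; i < Nbig; ++i) yc[i] = (double)fc[i] + b[co];
    }
    return Y;
  }
  g_buf1.resize((size_t)T * G.o1 * G.o2 * CuK);
  for (int z0 = 0; z0 < G.o3; z0 += T) {
    int z1 = std::min(z0 + T, G.o3);
    int rows = (z1 - z0) * G.o1 * G.o2;
    dgemm_("N", "T", rows, CuK, Cd, 1.0,
           REAL(x) + (size_t)z0 * G.o1 * G.o2, (int)Nsmall, REAL(W), CuK,
           0.0, g_buf1.data(), rows);
    scatter_cols(g_buf1.data(), G, z0, z1, REAL(Y));
  }
  for (int co = 0; co < Cu; ++co) {
    double* yc = REAL(Y) + (size_t)co * Nbig;
    for (size_t i = 0; i < Nbig; ++i) yc[i] += b[co];
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_tconv3d_bwd(NumericMatrix x, IntegerVector dims, NumericMatrix W,
                     int k, int stride, int pad, NumericMatrix dOut,
                     bool fp32 = true) {
  const int Cd = x.ncol(), CuK = W.nrow(), Cu = CuK / (k * k * k);
  IntegerVector od(3);
  for (int i = 0; i < 3; ++i) od[i] = (dims[i] - 1) * stride + k - 2 * pad;
  ConvGeom G(od, Cu, k, stride, pad);
  const size_t Nbig = (size_t)od[0] * od[1] * od[2];
  const size_t Nsmall = (size_t)dims[0] * dims[1] * dims[2];
  NumericMatrix dW(CuK, Cd), dX(Nsmall, Cd);
  NumericVector db(Cu);
  const int T = chunk_slices(G, CuK);
  if (fp32) {
    to_float(REAL(x), Nsmall * Cd, g_fx);
    to_float(REAL(W), (size_t)CuK * Cd, g_fw);
    std::vector<float> fdOut; to_float(REAL(dOut), Nbig * Cu, fdOut);
    std::vector<float> fdW((size_t)CuK * Cd, 0.0f);
    std::vector<float> fdX(Nsmall * Cd, 0.0f);
    g_fbuf1.resize((size_t)T * G.o1 * G.o2 * CuK);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      fill_cols(fdOut.data(), G, z0, z1, g_fbuf1.data());
      sgemm_wrap("N", "N", rows, Cd, CuK, 1.0f, g_fbuf1.data(), rows,
             g_fw.data(), CuK, 0.0f, fdX.data() + (size_t)z0 * G.o1 * G.o2,
             (int)Nsmall);
      sgemm_wrap("T", "N", CuK, Cd, rows, 1.0f, g_fbuf1.data(), rows,
             g_fx.data() + (size_t)z0 * G.o1 * G.o2, (int)Nsmall, 1.0f,
             fdW.data(), CuK);
    }
    std::copy(fdW.begin(), fdW.end(), REAL(dW));
    std::copy(fdX.begin(), fdX.end(), REAL(dX));
  } else {
    g_buf1.resize((size_t)T * G.o1 * G.o2 * CuK);
    for (int z0 = 0; z0 < G.o3; z0 += T) {
      int z1 = std::min(z0 + T, G.o3);
      int rows = (z1 - z0) * G.o1 * G.o2;
      fill_cols(REAL(dOut), G, z0, z1, g_buf1.data());
      dgemm_("N", "N", rows, Cd, CuK, 1.0, g_buf1.data(), rows, REAL(W), CuK,
             0.0, REAL(dX) + (size_t)z0 * G.o1 * G.o2, (int)Nsmall);
      dgemm_("T", "N", CuK, Cd, rows, 1.0, g_buf1.data(), rows,
             REAL(x) + (size_t)z0 * G.o1 * G.o2, (int)Nsmall, 1.0,
             REAL(dW), CuK);
    }
  }
  for (int co = 0; co < Cu; ++co) {
    const double* yc = REAL(dOut) + (size_t)co * Nbig;
    double s = 0.0;
    for (size_t i = 0; i < Nbig; ++i) s += yc[i];
    db[co] = s;
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// leaky ReLU forward and fused backward (grad * derivative), single pass
// [[Rcpp::export]]
NumericMatrix cpp_lrelu(NumericMatrix x, double a) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = REAL(x); double* yp = REAL(y);
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : a * xp[i];
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_lrelu_bwd(NumericMatrix pre, NumericMatrix g, double a) {
  NumericMatrix y(g.nrow(), g.ncol());
  const double* pp = REAL(pre); const double* gp = REAL(g);
  double* yp = REAL(y);
  const size_t n = (size_t)g.nrow() * g.ncol();
  for (size_t i = 0; i < n; ++i) yp[i] = pp[i] > 0 ? gp[i] : a * gp[i];
  return y;
}

// ---------------------------------------------------------------------------
// Iterated conditional modes with a Potts smoothing prior (6-neighbourhood)
// for attenuation-map region segmentation.  Data term: squared deviation
// from fixed class means scaled by 2*noiseSd^2; prior: beta per disagreeing
// neighbour.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_icm(NumericVector mu, IntegerVector dims, NumericVector means,
                      double noiseSd, double beta, int nsweeps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], K = means.size();
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  const double inv2s2 = 1.0 / (2.0 * noiseSd * noiseSd);
  // init: nearest mean
  for (size_t i = 0; i < n; ++i) {
    int best = 0; double bd = std::abs(mu[i] - means[0]);
    for (int q = 1; q < K; ++q) {
      double d = std::abs(mu[i] - means[q]);
      if (d < bd) { bd = d; best = q; }
    }
    lab[i] = best;
  }
  std::vector<int> nb(6);
  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    bool changed = false;
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      size_t i = ((size_t)z * ny + y) * nx + x;
      int nn = 0;
      if (x > 0) nb[nn++] = lab[i - 1];
      if (x < nx - 1) nb[nn++] = lab[i + 1];
      if (y > 0) nb[nn++] = lab[i - nx];
      if (y < ny - 1) nb[nn++] = lab[i + nx];
      if (z > 0) nb[nn++] = lab[i - (size_t)nx * ny];
      if (z < nz - 1) nb[nn++] = lab[i + (size_t)nx * ny];
      int best = lab[i]; double bestE = R_PosInf;
      for (int q = 0; q < K; ++q) {
        double e = (mu[i] - means[q]) * (mu[i] - means[q]) * inv2s2;
        for (int j = 0; j < nn; ++j) if (nb[j] != q) e += beta;
        if (e < bestE) { bestE = e; best = q; }
      }
      if (best != lab[i]) { lab[i] = best; changed = true; }
    }
    if (!changed) break;
  }
  return lab;
}
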