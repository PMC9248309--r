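// Sampling engine shared by volume resampling, surface projection and the
// Gaussian-smoothing calibration. All coordinates are 0-based voxel indices;
// out-of-field support samples contribute the fill value, so every kernel
// keeps its partition of unity against a constant background.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int M_NEAREST = 0, M_LINEAR = 1, M_CUBIC = 2, M_QUINTIC = 3, M_SINC = 4;
static const double SINC_HALFWIDTH = 7.0; // voxels, Hann window
static const int MAXSUP = 14;

static inline double b3(double t) {
  double u = std::fabs(t);
  if (u < 1.0) return (4.0 - 6.0 * u * u + 3.0 * u * u * u) / 6.0;
  if (u < 2.0) { double v = 2.0 - u; return v * v * v / 6.0; }
  return 0.0;
}

static inline double b5(double t) {
  double u = std::fabs(t);
  if (u >= 3.0) return 0.0;
  double s = 0.0, v;
  v = 3.0 - u; s += v * v * v * v * v;
  if (u < 2.0) { v = 2.0 - u; s -= 6.0 * v * v * v * v * v; }
  if (u < 1.0) { v = 1.0 - u; s += 15.0 * v * v * v * v * v; }
  return s / 120.0;
}

static inline double hann_sinc(double t) {
  double u = std::fabs(t);
  if (u >= SINC_HALFWIDTH) return 0.0;
  double s = (u < 1e-9) ? 1.0 : std::sin(M_PI * u) / (M_PI * u);
  return s * 0.5 * (1.0 + std::cos(M_PI * u / SINC_HALFWIDTH));
}

// 1D kernel weights at coordinate x; returns support size, writes first index
// and weights. Weights sum to 1 for every method.
static inline int axis_weights(int method, double x, int *i0, double *w) {
  switch (method) {
  case M_NEAREST:
    // ties (x exactly half-way) break toward the lower index
    *i0 = (int)std::ceil(x - 0.5);
    w[0] = 1.0;
    return 1;
  case M_LINEAR: {
    int f = (int)std::floor(x);
    *i0 = f;
    double d = x - f;
    w[0] = 1.0 - d; w[1] = d;
    return 2;
  }
  case M_CUBIC: {
    int f = (int)std::floor(x);
    *i0 = f - 1;
    for (int k = 0; k < 4; k++) w[k] = b3(x - (*i0 + k));
    return 4;
  }
  case M_QUINTIC: {
    int f = (int)std::floor(x);
    *i0 = f - 2;
    for (int k = 0; k < 6; k++) w[k] = b5(x - (*i0 + k));
    return 6;
  }
  default: { // windowed sinc; renormalised so weights sum to exactly 1
    int f = (int)std::floor(x);
    *i0 = f - 6;
    double s = 0.0;
    for (int k = 0; k < 14; k++) { w[k] = hann_sinc(x - (*i0 + k)); s += w[k]; }
    for (int k = 0; k < 14; k++) w[k] /= s;
    return 14;
  }
  }
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Core sample of one 3D frame at one point. Spline coefficients were
// prefiltered under mirror boundaries, so in-FOV points index coefficients
// with mirroring; points outside the voxel-centre hull (and non-spline
// border support) take the fill value.
static inline double sample_point(const double *v, int nx, int ny, int nz,
                                  double cx, double cy, double cz,
                                  int method, double fill) {
  double wx[MAXSUP], wy[MAXSUP], wz[MAXSUP];
  int ix0, iy0, iz0;
  const int sx = axis_weights(method, cx, &ix0, wx);
  const int sy = axis_weights(method, cy, &iy0, wy);
  const int sz = axis_weights(method, cz, &iz0, wz);
  const bool spline = (method == M_CUBIC || method == M_QUINTIC);
  const bool inb = cx >= 0 && cx <= nx - 1 && cy >= 0 && cy <= ny - 1 &&
    cz >= 0 && cz <= nz - 1;
  double acc = 0.0;
  if (spline && inb) {
    for (int c = 0; c < sz; c++) {
      const int z = mirror_idx(iz0 + c, nz);
      double accz = 0.0;
      for (int b = 0; b < sy; b++) {
        const int y = mirror_idx(iy0 + b, ny);
        const double *row = v + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double accy = 0.0;
        for (int a = 0; a < sx; a++)
          accy += wx[a] * row[mirror_idx(ix0 + a, nx)];
        accz += wy[b] * accy;
      }
      acc += wz[c] * accz;
    }
    return acc;
  }
  for (int c = 0; c < sz; c++) {
    const int z = iz0 + c;
    const bool zin = (z >= 0 && z < nz);
    double accz = 0.0;
    for (int b = 0; b < sy; b++) {
      const int y = iy0 + b;
      const bool yin = zin && (y >= 0 && y < ny);
      double accy = 0.0;
      if (yin) {
        const double *row = v + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int a = 0; a < sx; a++) {
          const int x = ix0 + a;
          accy += wx[a] * ((x >= 0 && x < nx) ? row[x] : fill);
        }
      } else {
        for (int a = 0; a < sx; a++) accy += wx[a] * fill;
      }
      accz += wy[b] * accy;
    }
    acc += wz[c] * accz;
  }
  return acc;
}

// [[Rcpp::export(name = ".bk_sample3d")]]
NumericVector bk_sample3d(NumericVector vol, IntegerVector dims,
                          NumericMatrix coords, int method, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = coords.nrow();
  const double *v = REAL(vol);
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; p++)
    out[p] = sample_point(v, nx, ny, nz, coords(p, 0), coords(p, 1),
                          coords(p, 2), method, fill);
  return out;
}

// Sample every frame of a 4D series at the same coordinates (volume-to-surface
// projection of a time series). vol must already be prefiltered per frame for
// spline methods.
// [[Rcpp::export(name = ".bk_sample_frames")]]
NumericMatrix bk_sample_frames(NumericVector vol, IntegerVector dims,
                               NumericMatrix coords, int method, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const R_xlen_t n = coords.nrow();
  const double *v = REAL(vol);
  NumericMatrix out(n, nt);
  for (R_xlen_t p = 0; p < n; p++) {
    const double cx = coords(p, 0), cy = coords(p, 1), cz = coords(p, 2);
    for (int t = 0; t < nt; t++)
      out(p, t) = sample_point(v + nvox * t, nx, ny, nz, cx, cy, cz,
                               method, fill);
  }
  return out;
}

// Recursive B-spline prefilter (causal/anticausal IIR, mirror boundaries) so
// that spline sampling reproduces on-grid values.
static void filt_line(double *c, int n, const double *z, int nz) {
  if (n < 2) return;
  const double tol = 1e-12;
  double lambda = 1.0;
  for (int k = 0; k < nz; k++) lambda *= (1.0 - z[k]) * (1.0 - 1.0 / z[k]);
  for (int i = 0; i < n; i++) c[i] *= lambda;
  for (int k = 0; k < nz; k++) {
    const double zk = z[k];
    int horizon = (int)std::ceil(std::log(tol) / std::log(std::fabs(zk)));
    double sum;
    if (horizon < n) {
      double zn = zk;
      sum = c[0];
      for (int i = 1; i < horizon; i++) { sum += zn * c[i]; zn *= zk; }
    } else {
      double zn = zk, iz = 1.0 / zk, z2n = std::pow(zk, (double)(n - 1));
      sum = c[0] + z2n * c[n - 1];
      z2n = z2n * z2n * iz;
      for (int i = 1; i < n - 1; i++) { sum += (zn + z2n) * c[i]; zn *= zk; z2n *= iz; }
      sum /= (1.0 - std::pow(zk, (double)(2 * n - 2)));
    }
    c[0] = sum;
    for (int i = 1; i < n; i++) c[i] += zk * c[i - 1];
    c[n - 1] = (zk / (zk * zk - 1.0)) * (zk * c[n - 2] + c[n - 1]);
    for (int i = n - 2; i >= 0; i--) c[i] = zk * (c[i + 1] - c[i]);
  }
}

// [[Rcpp::export(name = ".bk_bspline_prefilter")]]
NumericVector bk_bspline_prefilter(NumericVector vol, IntegerVector dims, int order) {
  NumericVector out = clone(vol);
  double *v = REAL(out);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double poles[2];
  int npoles;
  if (order == 3) {
    poles[0] = std::sqrt(3.0) - 2.0;
    npoles = 1;
  } else if (order == 5) {
    poles[0] = -0.43057534709997114;
    poles[1] = -0.04309628820326465;
    npoles = 2;
  } else {
    stop("unsupported spline order");
  }
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  // along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      filt_line(v + (R_xlen_t)nx * (y + (R_xlen_t)ny * z), nx, poles, npoles);
  // along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      double *base = v + x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; y++) line[y] = base[(R_xlen_t)nx * y];
      filt_line(line.data(), ny, poles, npoles);
      for (int y = 0; y < ny; y++) base[(R_xlen_t)nx * y] = line[y];
    }
  // along z
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      double *base = v + x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; z++) line[z] = base[sz * z];
      filt_line(line.data(), nz, poles, npoles);
      for (int z = 0; z < nz; z++) base[sz * z] = line[z];
    }
  return out;
}

// Separable 1D convolution along one axis of a 3D array. The kernel is
// renormalised over in-bounds taps at the borders, so constants are preserved
// everywhere.
// [[Rcpp::export(name = ".bk_conv_axis")]]
NumericVector bk_conv_axis(NumericVector vol, IntegerVector dims,
                           NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size(), r = (klen - 1) / 2;
  const double *kw = REAL(kernel);
  const double *v = REAL(vol);
  NumericVector outv(vol.size());
  double *o = REAL(outv);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t s[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = s[axis];
  const int b = (axis == 0) ? 1 : 0;
  const int c = (axis == 2) ? 1 : 2;
  std::vector<double> line(na), res(na);
  for (int jc = 0; jc < n[c]; jc++) {
    for (int jb = 0; jb < n[b]; jb++) {
      const R_xlen_t off = s[b] * jb + s[c] * jc;
      for (int i = 0; i < na; i++) line[i] = v[off + sa * i];
      for (int i = 0; i < na; i++) {
        const int lo = std::max(-r, -i), hi = std::min(r, na - 1 - i);
        double acc = 0.0, wsum = 0.0;
        for (int k = lo; k <= hi; k++) {
          const double w = kw[k + r];
          acc += w * line[i + k];
          wsum += w;
        }
        res[i] = acc / wsum;
      }
      for (int i = 0; i < na; i++) o[off + sa * i] = res[i];
    }
  }
  return outv;
}

// Mark voxels whose centre lies within radius_mm of any of the given points
// (points in 0-based voxel coordinates of the same grid).
// [[Rcpp::export(name = ".bk_mark_near")]]
LogicalVector bk_mark_near(NumericMatrix points, IntegerVector dims,
                           NumericVector spacing, double radius_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  int *o = LOGICAL(out);
  const double r2 = radius_mm * radius_mm;
  for (R_xlen_t p = 0; p < points.nrow(); p++) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    const int x0 = std::max(0, (int)std::ceil(px - radius_mm / spacing[0]));
    const int x1 = std::min(nx - 1, (int)std::floor(px + radius_mm / spacing[0]));
    const int y0 = std::max(0, (int)std::ceil(py - radius_mm / spacing[1]));
    const int y1 = std::min(ny - 1, (int)std::floor(py + radius_mm / spacing[1]));
    const int z0 = std::max(0, (int)std::ceil(pz - radius_mm / spacing[2]));
    const int z1 = std::min(nz - 1, (int)std::floor(pz + radius_mm / spacing[2]));
    for (int z = z0; z <= z1; z++) {
      const double dz = (z - pz) * spacing[2];
      for (int y = y0; y <= y1; y++) {
        const double dy = (y - py) * spacing[1];
        const double dzy = dz * dz + dy * dy;
        if (dzy > r2) continue;
        for (int x = x0; x <= x1; x++) {
          const double dx = (x - px) * spacing[0];
          if (dzy + dx * dx <= r2)
            o[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = 1;
        }
      }
    }
  }
  return out;
}
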