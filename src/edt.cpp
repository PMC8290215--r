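#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, 2012)
// on a regular 3D grid with anisotropic spacing.  Distances are measured
// between voxel centers in physical mm.  Works in the squared domain; the
// 1D lower-envelope pass is applied separably along each axis.
//
// "No site yet" is encoded as a large finite squared distance (far above
// any realisable grid distance) so the envelope arithmetic never meets an
// infinity; callers guarantee a non-empty site set.

// One 1D pass: f holds squared distances, step is the physical spacing
// along this axis.  d receives the transformed squared distances.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n,
                 double step) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double qq = q * step;
    double s;
    for (;;) {
      double vv = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * step;
    while (z[k + 1] < qq) k++;
    double vv = v[k] * step;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // squared diagonal of the whole grid bounds every real distance
  double ext = nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  const double FAR = 1e3 * ext * ext + 1e6;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : FAR;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zi = 0; zi < nz; zi++)
    for (int yi = 0; yi < ny; yi++) {
      R_xlen_t base = (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
      for (int xi = 0; xi < nx; xi++) f[xi] = out[base + xi];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int xi = 0; xi < nx; xi++) out[base + xi] = d[xi];
    }
  // pass along y
  for (int zi = 0; zi < nz; zi++)
    for (int xi = 0; xi < nx; xi++) {
      R_xlen_t base = xi + (R_xlen_t)nx * ny * zi;
      for (int yi = 0; yi < ny; yi++) f[yi] = out[base + (R_xlen_t)nx * yi];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int yi = 0; yi < ny; yi++) out[base + (R_xlen_t)nx * yi] = d[yi];
    }
  // pass along z
  {
    R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int yi = 0; yi < ny; yi++)
      for (int xi = 0; xi < nx; xi++) {
        R_xlen_t base = xi + (R_xlen_t)nx * yi;
        for (int zi = 0; zi < nz; zi++) f[zi] = out[base + stride * zi];
        dt1d(f, d, v, z, nz, spacing[2]);
        for (int zi = 0; zi < nz; zi++) out[base + stride * zi] = d[zi];
      }
  }

  double realmax = ext * ext;  // any true squared distance is below this
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (out[i] > realmax) ? R_PosInf : std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling by iterative flood fill.
// Returns an integer array: 0 for background, components numbered from 1
// in order of first (column-major) encounter.
// [[Rcpp::export(name = ".cpp_label26")]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  for (R_xlen_t i = 0; i < n; i++) lab[i] = 0;
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int xi = cur % nx;
      int yi = (cur / nx) % ny;
      int zi = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = xi + dx, y2 = yi + dy, z2 = zi + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            R_xlen_t j = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Separable Gaussian smoothing with a truncated, boundary-renormalized
// kernel (radius 3.5 sigma per axis, in voxels of that axis).
static void blur_axis(std::vector<double> &buf, std::vector<double> &tmp,
                      int n, const std::vector<double> &kern, int r) {
  for (int i = 0; i < n; i++) {
    double acc = 0.0, wsum = 0.0;
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    for (int j = lo; j <= hi; j++) {
      double w = kern[j - i + r];
      acc += w * buf[j];
      wsum += w;
    }
    tmp[i] = acc / wsum;
  }
  for (int i = 0; i < n; i++) buf[i] = tmp[i];
}

// [[Rcpp::export(name = ".cpp_gauss_blur")]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dims,
                             NumericVector spacing, double fwhm_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = img[i];
  if (fwhm_mm <= 0) {
    out.attr("dim") = dims;
    return out;
  }
  double sigma = fwhm_mm / 2.354820045030949;  // FWHM -> sigma
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> buf(nmax), tmp(nmax);

  for (int ax = 0; ax < 3; ax++) {
    double step = spacing[ax];
    int r = (int)std::ceil(3.5 * sigma / step);
    if (r < 1) r = 1;
    std::vector<double> kern(2 * r + 1);
    for (int j = -r; j <= r; j++)
      kern[j + r] = std::exp(-0.5 * (j * step) * (j * step) / (sigma * sigma));
    if (ax == 0) {
      for (int zi = 0; zi < nz; zi++)
        for (int yi = 0; yi < ny; yi++) {
          R_xlen_t base = (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
          for (int xi = 0; xi < nx; xi++) buf[xi] = out[base + xi];
          blur_axis(buf, tmp, nx, kern, r);
          for (int xi = 0; xi < nx; xi++) out[base + xi] = buf[xi];
        }
    } else if (ax == 1) {
      for (int zi = 0; zi < nz; zi++)
        for (int xi = 0; xi < nx; xi++) {
          R_xlen_t base = xi + (R_xlen_t)nx * ny * zi;
          for (int yi = 0; yi < ny; yi++) buf[yi] = out[base + (R_xlen_t)nx * yi];
          blur_axis(buf, tmp, ny, kern, r);
          for (int yi = 0; yi < ny; yi++) out[base + (R_xlen_t)nx * yi] = buf[yi];
        }
    } else {
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int yi = 0; yi < ny; yi++)
        for (int xi = 0; xi < nx; xi++) {
          R_xlen_t base = xi + (R_xlen_t)nx * yi;
          for (int zi = 0; zi < nz; zi++) buf[zi] = out[base + stride * zi];
          blur_axis(buf, tmp, nz, kern, r);
          for (int zi = 0; zi < nz; zi++) out[base + stride * zi] = buf[zi];
        }
    }
  }
  out.attr("dim") = dims;
  return out;
}
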