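#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Geometry conventions shared with the R layer:
//  - volumes are cubic arrays v[ix, iy, iz], 0-based voxel i at coordinate i
//    (grid corner at 0), rotation centre at n/2 in every axis;
//  - tilt axis is y (second axis), beam axis is z (third axis);
//  - rotation about y is right-handed, angle in radians;
//  - interpolation is bilinear in the (x, z) plane (y is untouched by a tilt).

// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int n, double theta) {
  NumericMatrix img(n, n);
  const double c = n / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int iz = 0; iz < n; ++iz) {
    const double Z = iz - c;
    for (int ix = 0; ix < n; ++ix) {
      const double X = ix - c;
      // source position in the unrotated volume: R_y(-theta) * (X, Z)
      const double xs = ct * X - st * Z + c;
      const double zs = st * X + ct * Z + c;
      const int x0 = (int)std::floor(xs), z0 = (int)std::floor(zs);
      if (x0 < -1 || x0 > n - 1 || z0 < -1 || z0 > n - 1) continue;
      const double fx = xs - x0, fz = zs - z0;
      const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
      const double w01 = (1 - fx) * fz, w11 = fx * fz;
      const bool x0ok = x0 >= 0 && x0 < n, x1ok = x0 + 1 >= 0 && x0 + 1 < n;
      const bool z0ok = z0 >= 0 && z0 < n, z1ok = z0 + 1 >= 0 && z0 + 1 < n;
      for (int iy = 0; iy < n; ++iy) {
        double acc = 0.0;
        if (x0ok && z0ok) acc += w00 * vol[x0     + (size_t)n * (iy + (size_t)n * z0)];
        if (x1ok && z0ok) acc += w10 * vol[x0 + 1 + (size_t)n * (iy + (size_t)n * z0)];
        if (x0ok && z1ok) acc += w01 * vol[x0     + (size_t)n * (iy + (size_t)n * (z0 + 1))];
        if (x1ok && z1ok) acc += w11 * vol[x0 + 1 + (size_t)n * (iy + (size_t)n * (z0 + 1))];
        img(ix, iy) += acc;
      }
    }
  }
  return img;
}

// Exact adjoint of cpp_project: scatter each ray sample back with the same
// bilinear weights, so <project(V), I> == <V, backproject(I)> to rounding.
// [[Rcpp::export]]
void cpp_backproject_add(NumericVector vol, NumericMatrix img, int n, double theta) {
  const double c = n / 2.0;
  const double ct = std::cos(theta), st = std::sin(theta);
  for (int iz = 0; iz < n; ++iz) {
    const double Z = iz - c;
    for (int ix = 0; ix < n; ++ix) {
      const double X = ix - c;
      const double xs = ct * X - st * Z + c;
      const double zs = st * X + ct * Z + c;
      const int x0 = (int)std::floor(xs), z0 = (int)std::floor(zs);
      if (x0 < -1 || x0 > n - 1 || z0 < -1 || z0 > n - 1) continue;
      const double fx = xs - x0, fz = zs - z0;
      const double w00 = (1 - fx) * (1 - fz), w10 = fx * (1 - fz);
      const double w01 = (1 - fx) * fz, w11 = fx * fz;
      const bool x0ok = x0 >= 0 && x0 < n, x1ok = x0 + 1 >= 0 && x0 + 1 < n;
      const bool z0ok = z0 >= 0 && z0 < n, z1ok = z0 + 1 >= 0 && z0 + 1 < n;
      for (int iy = 0; iy < n; ++iy) {
        const double v = img(ix, iy);
        if (v == 0.0) continue;
        if (x0ok && z0ok) vol[x0     + (size_t)n * (iy + (size_t)n * z0)]       += w00 * v;
        if (x1ok && z0ok) vol[x0 + 1 + (size_t)n * (iy + (size_t)n * z0)]       += w10 * v;
        if (x0ok && z1ok) vol[x0     + (size_t)n * (iy + (size_t)n * (z0 + 1))] += w01 * v;
        if (x1ok && z1ok) vol[x0 + 1 + (size_t)n * (iy + (size_t)n * (z0 + 1))] += w11 * v;
      }
    }
  }
}

// Gaussian rasterization of point masses onto a cubic grid.
// coords are voxel-space positions (Angstrom already divided by pixel size),
// sigma is in voxels; each atom deposits ~mass in total (normalised kernel,
// truncated at 4 sigma).
// [[Rcpp::export]]
NumericVector cpp_rasterize(NumericMatrix coords, NumericVector mass, int n,
                            double sigma) {
  NumericVector vol((size_t)n * n * n);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const int cut = (int)std::ceil(4.0 * sigma);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double gx = coords(a, 0), gy = coords(a, 1), gz = coords(a, 2);
    const double m = mass[a] * norm;
    const int x0 = std::max(0, (int)std::floor(gx) - cut);
    const int x1 = std::min(n - 1, (int)std::ceil(gx) + cut);
    const int y0 = std::max(0, (int)std::floor(gy) - cut);
    const int y1 = std::min(n - 1, (int)std::ceil(gy) + cut);
    const int z0 = std::max(0, (int)std::floor(gz) - cut);
    const int z1 = std::min(n - 1, (int)std::ceil(gz) + cut);
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = iz - gz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = iy - gy;
        const double ryz = dy * dy + dz * dz;
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = ix - gx;
          vol[ix + (size_t)n * (iy + (size_t)n * iz)] +=
            m * std::exp(-(dx * dx + ryz) * inv2s2);
        }
      }
    }
  }
  return vol;
}

// Pearson correlation between two equal-length vectors, ignoring nothing.
// [[Rcpp::export]]
double cpp_pearson(NumericVector a, NumericVector b) {
  const size_t n = a.size();
  double sa = 0, sb = 0;
  for (size_t i = 0; i < n; ++i) { sa += a[i]; sb += b[i]; }
  const double ma = sa / n, mb = sb / n;
  double sab = 0, saa = 0, sbb = 0;
  for (size_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Pearson correlation between a and b restricted to voxels where a exceeds
// thr_frac of its maximum (the body's own support) -- the locally
// normalised score used for fitting a small body into a larger map.
// [[Rcpp::export]]
double cpp_masked_pearson(NumericVector a, NumericVector b, double thr_frac) {
  const size_t n = a.size();
  double amax = 0;
  for (size_t i = 0; i < n; ++i) if (a[i] > amax) amax = a[i];
  const double thr = thr_frac * amax;
  double sa = 0, sb = 0; size_t m = 0;
  for (size_t i = 0; i < n; ++i) if (a[i] > thr) { sa += a[i]; sb += b[i]; ++m; }
  if (m < 8) return NA_REAL;
  const double ma = sa / m, mb = sb / m;
  double sab = 0, saa = 0, sbb = 0;
  for (size_t i = 0; i < n; ++i) if (a[i] > thr) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}
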