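// Dense-field and affine resampling primitives used by the demons
// registration and the augmentation pipeline. Displacement fields are
// (nx, ny, nz, 3) arrays in voxel units with pull-back convention:
// warped(v) = image(v + d(v)). Voxel coordinates are 0-based in C++.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline long id3(int x, int y, int z, int nx, int ny, int nz) {
  return x + (long)nx * (y + (long)ny * z);
}

static double sample_tri(const double* img, int nx, int ny, int nz,
                         double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = img[id3(x0,y0,z0,nx,ny,nz)] * (1-fx) + img[id3(x1,y0,z0,nx,ny,nz)] * fx;
  double c10 = img[id3(x0,y1,z0,nx,ny,nz)] * (1-fx) + img[id3(x1,y1,z0,nx,ny,nz)] * fx;
  double c01 = img[id3(x0,y0,z1,nx,ny,nz)] * (1-fx) + img[id3(x1,y0,z1,nx,ny,nz)] * fx;
  double c11 = img[id3(x0,y1,z1,nx,ny,nz)] * (1-fx) + img[id3(x1,y1,z1,nx,ny,nz)] * fx;
  double c0 = c00 * (1-fy) + c10 * fy, c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

static double sample_nn(const double* img, int nx, int ny, int nz,
                        double x, double y, double z) {
  int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) return 0.0;
  return img[id3(xi, yi, zi, nx, ny, nz)];
}

// [[Rcpp::export(name = ".warp_disp")]]
NumericVector warp_disp(NumericVector img, NumericVector disp,
                        IntegerVector dims, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* ip = REAL(img);
  const double* dp = REAL(disp);
  double* op = REAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long v = id3(x, y, z, nx, ny, nz);
      double sx = x + dp[v], sy = y + dp[v + nvox], sz = z + dp[v + 2 * nvox];
      op[v] = nearest ? sample_nn(ip, nx, ny, nz, sx, sy, sz)
                      : sample_tri(ip, nx, ny, nz, sx, sy, sz);
    }
  return out;
}

// out(v) = img(M %*% (v,1)): pull-back affine resampling onto an output
// grid of dimensions `dims`; the source grid has dimensions `in_dims`.
// M is 3x4 in 0-based voxel coordinates.
// [[Rcpp::export(name = ".affine_resample")]]
NumericVector affine_resample(NumericVector img, NumericMatrix M,
                              IntegerVector dims, bool nearest,
                              Nullable<IntegerVector> in_dims = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int ix = nx, iy = ny, iz = nz;
  if (in_dims.isNotNull()) {
    IntegerVector id(in_dims);
    ix = id[0]; iy = id[1]; iz = id[2];
  }
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double* ip = REAL(img);
  double* op = REAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double sx = M(0,0)*x + M(0,1)*y + M(0,2)*z + M(0,3);
      double sy = M(1,0)*x + M(1,1)*y + M(1,2)*z + M(1,3);
      double sz = M(2,0)*x + M(2,1)*y + M(2,2)*z + M(2,3);
      op[id3(x,y,z,nx,ny,nz)] = nearest ? sample_nn(ip, ix, iy, iz, sx, sy, sz)
                                        : sample_tri(ip, ix, iy, iz, sx, sy, sz);
    }
  return out;
}

// compose(d1, d2)(v) = d2(v) + d1(v + d2(v)); applying the composed field
// equals warping first by d1 then by d2.
// [[Rcpp::export(name = ".compose_disp")]]
NumericVector compose_disp(NumericVector d1, NumericVector d2,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* p1 = REAL(d1);
  const double* p2 = REAL(d2);
  double* op = REAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long v = id3(x, y, z, nx, ny, nz);
      double sx = x + p2[v], sy = y + p2[v + nvox], sz = z + p2[v + 2*nvox];
      for (int k = 0; k < 3; ++k) {
        // clamp sampling of d1 to the grid edge so composition near the
        // boundary extends rather than zero-fills
        double cx = std::min(std::max(sx, 0.0), (double)nx - 1);
        double cy = std::min(std::max(sy, 0.0), (double)ny - 1);
        double cz = std::min(std::max(sz, 0.0), (double)nz - 1);
        op[v + k * nvox] = p2[v + k * nvox] +
          sample_tri(p1 + k * nvox, nx, ny, nz, cx, cy, cz);
      }
    }
  return out;
}

// Fixed-point inversion: v_{k+1}(x) = -d(x + v_k(x)).
// [[Rcpp::export(name = ".invert_disp")]]
NumericVector invert_disp(NumericVector d, IntegerVector dims, int iters) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector inv(nvox * 3);
  inv.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* dp = REAL(d);
  double* vp = REAL(inv);
  std::vector<double> tmp(nvox * 3, 0.0);
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long v = id3(x, y, z, nx, ny, nz);
        double sx = x + vp[v], sy = y + vp[v + nvox], sz = z + vp[v + 2*nvox];
        double cx = std::min(std::max(sx, 0.0), (double)nx - 1);
        double cy = std::min(std::max(sy, 0.0), (double)ny - 1);
        double cz = std::min(std::max(sz, 0.0), (double)nz - 1);
        for (int k = 0; k < 3; ++k)
          tmp[v + k * nvox] = -sample_tri(dp + k * nvox, nx, ny, nz, cx, cy, cz);
      }
    std::copy(tmp.begin(), tmp.end(), vp);
  }
  return inv;
}

// Separable Gaussian smoothing of a 3D array (reflect boundary).
// [[Rcpp::export(name = ".gauss3")]]
NumericVector gauss3(NumericVector img, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(clone(img));
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  if (sigma <= 0) return out;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double& w : k) w /= s;
  std::vector<double> buf(nvox);
  double* a = REAL(out);
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i;
  };
  // x pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i)
        acc += k[i + r] * a[id3(reflect(x + i, nx), y, z, nx, ny, nz)];
      buf[id3(x, y, z, nx, ny, nz)] = acc;
    }
  std::copy(buf.begin(), buf.end(), a);
  // y pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i)
        acc += k[i + r] * a[id3(x, reflect(y + i, ny), z, nx, ny, nz)];
      buf[id3(x, y, z, nx, ny, nz)] = acc;
    }
  std::copy(buf.begin(), buf.end(), a);
  // z pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double acc = 0;
      for (int i = -r; i <= r; ++i)
        acc += k[i + r] * a[id3(x, y, reflect(z + i, nz), nx, ny, nz)];
      buf[id3(x, y, z, nx, ny, nz)] = acc;
    }
  std::copy(buf.begin(), buf.end(), a);
  return out;
}

// Central-difference spatial gradient, one (nx,ny,nz) array per axis.
// [[Rcpp::export(name = ".grad3")]]
NumericVector grad3(NumericVector img, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* ip = REAL(img);
  double* op = REAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long v = id3(x, y, z, nx, ny, nz);
      int xm = std::max(x-1,0), xp_ = std::min(x+1,nx-1);
      int ym = std::max(y-1,0), yp = std::min(y+1,ny-1);
      int zm = std::max(z-1,0), zp = std::min(z+1,nz-1);
      op[v] = 0.5 * (ip[id3(xp_,y,z,nx,ny,nz)] - ip[id3(xm,y,z,nx,ny,nz)]);
      op[v + nvox] = 0.5 * (ip[id3(x,yp,z,nx,ny,nz)] - ip[id3(x,ym,z,nx,ny,nz)]);
      op[v + 2*nvox] = 0.5 * (ip[id3(x,y,zp,nx,ny,nz)] - ip[id3(x,y,zm,nx,ny,nz)]);
    }
  return out;
}

// One demons force field: u = (m - f) * grad(f) / (|grad f|^2 + (m - f)^2).
// f is the fixed image, m the moving image already warped by the current
// field. Voxels with tiny denominator get zero update.
// [[Rcpp::export(name = ".demons_force")]]
NumericVector demons_force(NumericVector fixed, NumericVector moving_warped,
                           NumericVector gradf, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  NumericVector out(nvox * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  const double* fp = REAL(fixed);
  const double* mp = REAL(moving_warped);
  const double* gp = REAL(gradf);
  double* op = REAL(out);
  for (long v = 0; v < nvox; ++v) {
    double diff = mp[v] - fp[v];
    double g2 = gp[v]*gp[v] + gp[v+nvox]*gp[v+nvox] + gp[v+2*nvox]*gp[v+2*nvox];
    double den = g2 + diff * diff;
    double s = (den > 1e-9) ? diff / den : 0.0;
    op[v] = s * gp[v];
    op[v + nvox] = s * gp[v + nvox];
    op[v + 2*nvox] = s * gp[v + 2*nvox];
  }
  return out;
}
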