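// Low-level kernels for the 3D U-Net: im2col-based 3x3x3 convolution
// (forward and backward) in single precision, 2x max-pooling with argmax,
// and nearest-neighbour upsampling with its adjoint. Arrays are R arrays in
// column-major order with dimensions (nx, ny, nz, channels).
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline long idx4(int x, int y, int z, int c, int nx, int ny, int nz) {
  return x + nx * (y + ny * (z + (long)nz * c));
}

static inline long id3vox(int x, int y, int z, int nx, int ny) {
  return x + (long)nx * (y + (long)ny * z);
}

// Fill the per-channel im2col block (Nvox x 27) for a 3x3x3 kernel, zero
// padding 1. Voxel-major layout keeps reads and writes contiguous; working
// per input channel keeps the block small enough to stay cache-friendly.
static void im2col_chan(const double* xc, int nx, int ny, int nz,
                        arma::fmat& M) {
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      const int colidx = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
      float* mcol = M.colptr(colidx);
      const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
      for (int z = 0; z < nz; ++z) {
        const int zz = z + dz;
        for (int y = 0; y < ny; ++y) {
          const int yy = y + dy;
          float* out = mcol + id3vox(0, y, z, nx, ny);
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny) {
            std::fill(out, out + nx, 0.0f);
            continue;
          }
          const double* src = xc + id3vox(dx, yy, zz, nx, ny);
          for (int x = 0; x < x0; ++x) out[x] = 0.0f;
          for (int x = x0; x < x1; ++x) out[x] = (float)src[x];
          for (int x = x1; x < nx; ++x) out[x] = 0.0f;
        }
      }
    }
}

// Adjoint: scatter-add a (Nvox x 27) block into one input-channel array.
static void col2im_chan(const arma::fmat& M, double* gc, int nx, int ny,
                        int nz) {
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      const int colidx = (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
      const float* mcol = M.colptr(colidx);
      const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
      for (int z = 0; z < nz; ++z) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int y = 0; y < ny; ++y) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          const float* src = mcol + id3vox(0, y, z, nx, ny);
          double* dst = gc + id3vox(dx, yy, zz, nx, ny);
          for (int x = x0; x < x1; ++x) dst[x] += (double)src[x];
        }
      }
    }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
NumericVector conv3d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                         IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const long nvox = (long)nx * ny * nz;
  arma::fmat K(w.nrow(), cout);
  for (int j = 0; j < cout; ++j) for (int i = 0; i < w.nrow(); ++i)
    K(i, j) = (float)w(i, j);
  arma::fmat Mc(nvox, 27);
  arma::fmat Y(nvox, cout, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    im2col_chan(REAL(x) + nvox * (long)c, nx, ny, nz, Mc);
    Y += Mc * K.rows(27 * c, 27 * c + 26);
  }
  NumericVector out((R_xlen_t)nvox * cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  double* op = REAL(out);
  for (int c = 0; c < cout; ++c) {
    const float bc = (float)b[c];
    const float* yc = Y.colptr(c);
    for (long v = 0; v < nvox; ++v) op[v + nvox * (long)c] = yc[v] + bc;
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
List conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const long nvox = (long)nx * ny * nz;
  arma::fmat G(nvox, cout);
  const double* dp = REAL(dy);
  for (int c = 0; c < cout; ++c) {
    float* gc = G.colptr(c);
    for (long v = 0; v < nvox; ++v) gc[v] = (float)dp[v + nvox * (long)c];
  }
  arma::fmat K(w.nrow(), cout);
  for (int j = 0; j < cout; ++j) for (int i = 0; i < w.nrow(); ++i)
    K(i, j) = (float)w(i, j);
  arma::fmat dW(w.nrow(), cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)nvox * cin);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  std::fill(REAL(dx), REAL(dx) + nvox * cin, 0.0);
  arma::fmat Mc(nvox, 27);
  for (int c = 0; c < cin; ++c) {
    im2col_chan(REAL(x) + nvox * (long)c, nx, ny, nz, Mc);
    dW.rows(27 * c, 27 * c + 26) = Mc.t() * G;
    arma::fmat dMc = G * K.rows(27 * c, 27 * c + 26).t();  // nvox x 27
    col2im_chan(dMc, REAL(dx) + nvox * (long)c, nx, ny, nz);
  }
  arma::frowvec db = arma::sum(G, 0);
  NumericMatrix dWout(w.nrow(), cout);
  for (int j = 0; j < cout; ++j) for (int i = 0; i < w.nrow(); ++i)
    dWout(i, j) = dW(i, j);
  NumericVector dbout(cout);
  for (int c = 0; c < cout; ++c) dbout[c] = db[c];
  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = dbout);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const long onvox = (long)ox * oy * oz;
  NumericVector out(onvox * nc);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  IntegerVector arg(onvox * nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z) for (int y = 0; y < oy; ++y)
      for (int x0 = 0; x0 < ox; ++x0) {
        double best = -1e300; int bi = 0;
        for (int dz = 0; dz < 2; ++dz) for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            int i = idx4(2 * x0 + dx, 2 * y + dy, 2 * z + dz, c, nx, ny, nz);
            if (xp[i] > best) { best = xp[i]; bi = i; }
          }
        long o = x0 + ox * (y + oy * (z + (long)oz * c));
        op[o] = best; arg[o] = bi;
      }
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector arg,
                           IntegerVector in_dims) {
  const long n = (long)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector dx(n);
  dx.attr("dim") = in_dims;
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[arg[i]] += gp[i];
  return dx;
}

// [[Rcpp::export(name = ".upsample2_fwd")]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = nx * 2, oy = ny * 2, oz = nz * 2;
  NumericVector out((R_xlen_t)ox * oy * oz * nc);
  out.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < oz; ++z) for (int y = 0; y < oy; ++y)
      for (int x0 = 0; x0 < ox; ++x0)
        op[idx4(x0, y, z, c, ox, oy, oz)] =
          xp[idx4(x0 / 2, y / 2, z / 2, c, nx, ny, nz)];
  return out;
}

// [[Rcpp::export(name = ".upsample2_bwd")]]
NumericVector upsample2_bwd(NumericVector dy, IntegerVector out_dims) {
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2],
            nc = out_dims[3];
  const int nx = ox * 2, ny = oy * 2, nz = oz * 2;
  NumericVector dx((R_xlen_t)ox * oy * oz * nc);
  dx.attr("dim") = out_dims;
  const double* gp = REAL(dy);
  double* dp = REAL(dx);
  for (int c = 0; c < nc; ++c)
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
      for (int x0 = 0; x0 < nx; ++x0)
        dp[idx4(x0 / 2, y / 2, z / 2, c, ox, oy, oz)] +=
          gp[idx4(x0, y, z, c, nx, ny, nz)];
  return dx;
}
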