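// Single-precision end-to-end U-Net training step: forward pass, combined
// Dice/cross-entropy loss and full backpropagation in one call, so that
// activations never round-trip through R. The parameter tree and the
// returned gradient tree mirror the R-side structures (see R/unet.R); the
// R implementation of the same network is the reference in the tests.
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Dim3 { int nx, ny, nz; long nvox() const { return (long)nx * ny * nz; } };

// Fill the im2col block for voxels of z-slab [z0, z1) across all input
// channels: rows are slab voxels, columns are c*27 + offset.
static void im2col_slab_f(const fmat& X, const Dim3& d, int z0, int z1,
                          fmat& M) {
  const int nx = d.nx, ny = d.ny, nz = d.nz;
  const long slab = (long)nx * ny;
  for (int c = 0; c < (int)X.n_cols; ++c) {
    const float* xc = X.colptr(c);
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        float* mcol = M.colptr(c * 27 + (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1)));
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        for (int z = z0; z < z1; ++z) {
          const int zz = z + dz;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + dy;
            float* out = mcol + (long)nx * y + slab * (z - z0);
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny) {
              std::fill(out, out + nx, 0.0f);
              continue;
            }
            const float* src = xc + dx + (long)nx * yy + slab * zz;
            for (int x = 0; x < x0; ++x) out[x] = 0.0f;
            for (int x = x0; x < x1; ++x) out[x] = src[x];
            for (int x = x1; x < nx; ++x) out[x] = 0.0f;
          }
        }
      }
  }
}

// Adjoint of the slab im2col: scatter-add into the full gradient array.
static void col2im_slab_f(const fmat& M, fmat& dX, const Dim3& d, int z0,
                          int z1) {
  const int nx = d.nx, ny = d.ny, nz = d.nz;
  const long slab = (long)nx * ny;
  for (int c = 0; c < (int)dX.n_cols; ++c) {
    float* gc = dX.colptr(c);
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const float* mcol =
          M.colptr(c * 27 + (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1)));
        const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
        for (int z = z0; z < z1; ++z) {
          const int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            const float* src = mcol + (long)nx * y + slab * (z - z0);
            float* dst = gc + dx + (long)nx * yy + slab * zz;
            for (int x = x0; x < x1; ++x) dst[x] += src[x];
          }
        }
      }
  }
}

// choose a slab height that keeps the im2col block around ~4 MB
static int slab_height(const Dim3& d, int cin) {
  long per_slice = (long)d.nx * d.ny * 27 * cin * 4;
  int h = (int)std::max(1L, (long)(4L * 1024 * 1024 / std::max(1L, per_slice)));
  return std::min(h, d.nz);
}

static fmat conv_fwd_f(const fmat& X, const Dim3& d, const fmat& K,
                       const fvec& b) {
  const int cin = X.n_cols, cout = K.n_cols;
  const long slab = (long)d.nx * d.ny;
  fmat Y(X.n_rows, cout);
  const int h = slab_height(d, cin);
  fmat M(slab * h, 27 * cin);
  for (int z0 = 0; z0 < d.nz; z0 += h) {
    const int z1 = std::min(d.nz, z0 + h);
    if ((z1 - z0) != h) M.set_size(slab * (z1 - z0), 27 * cin);
    im2col_slab_f(X, d, z0, z1, M);
    Y.rows(slab * z0, slab * z1 - 1) = M * K;
  }
  Y.each_row() += b.t();
  return Y;
}

static void conv_bwd_f(const fmat& X, const Dim3& d, const fmat& K,
                       const fmat& G, fmat& dW, fvec& db, fmat& dX,
                       bool need_dx) {
  const int cin = X.n_cols;
  const long slab = (long)d.nx * d.ny;
  dW.zeros(K.n_rows, K.n_cols);
  if (need_dx) dX.zeros(X.n_rows, cin);
  const int h = slab_height(d, cin);
  fmat M(slab * h, 27 * cin);
  for (int z0 = 0; z0 < d.nz; z0 += h) {
    const int z1 = std::min(d.nz, z0 + h);
    if ((z1 - z0) != h) M.set_size(slab * (z1 - z0), 27 * cin);
    im2col_slab_f(X, d, z0, z1, M);
    fmat Gs = G.rows(slab * z0, slab * z1 - 1);
    dW += M.t() * Gs;
    if (need_dx) {
      M = Gs * K.t();  // reuse the buffer: (slab voxels) x (27*cin)
      col2im_slab_f(M, dX, d, z0, z1);
      if (z1 < d.nz) M.set_size(slab * std::min(h, d.nz - z1), 27 * cin);
    }
  }
  db = arma::sum(G, 0).t();
}

struct BnCache { fvec mu, v, istd; fmat xhat; };

// conv + batch-norm + ReLU block; in training mode uses batch statistics
static fmat cbr_fwd_f(const fmat& X, const Dim3& d, const fmat& K,
                      const fvec& b, const fvec& gamma, const fvec& beta,
                      bool train, const fvec& rm, const fvec& rv,
                      fmat& conv_in, BnCache& bc, arma::umat* maskp) {
  conv_in = X;
  fmat Y = conv_fwd_f(X, d, K, b);
  const int C = Y.n_cols;
  const float eps = 1e-5f;
  if (train) {
    bc.mu = arma::mean(Y, 0).t();
    bc.v = arma::mean(arma::square(Y), 0).t() - arma::square(bc.mu);
  } else { bc.mu = rm; bc.v = rv; }
  bc.istd = 1.0f / arma::sqrt(bc.v + eps);
  bc.xhat = Y;
  for (int c = 0; c < C; ++c)
    bc.xhat.col(c) = (Y.col(c) - bc.mu[c]) * bc.istd[c];
  fmat out = bc.xhat;
  for (int c = 0; c < C; ++c)
    out.col(c) = bc.xhat.col(c) * gamma[c] + beta[c];
  if (maskp) *maskp = (out > 0);
  out.transform([](float x) { return x > 0 ? x : 0.0f; });
  return out;
}

static fmat cbr_bwd_f(fmat dY, const arma::umat& mask, const fmat& conv_in,
                      const Dim3& d, const fmat& K, const fvec& gamma,
                      const BnCache& bc, fmat& dW, fvec& db, fvec& dgamma,
                      fvec& dbeta, bool need_dx) {
  dY %= arma::conv_to<fmat>::from(mask);
  const int C = dY.n_cols;
  dgamma.set_size(C); dbeta.set_size(C);
  fmat dconv(dY.n_rows, C);
  for (int c = 0; c < C; ++c) {
    dgamma[c] = arma::dot(dY.col(c), bc.xhat.col(c));
    dbeta[c] = arma::accu(dY.col(c));
    fvec dxh = dY.col(c) * gamma[c];
    float m1 = arma::mean(dxh);
    float m2 = arma::mean(dxh % bc.xhat.col(c));
    dconv.col(c) = (dxh - m1 - bc.xhat.col(c) * m2) * bc.istd[c];
  }
  fmat dX;
  conv_bwd_f(conv_in, d, K, dconv, dW, db, dX, need_dx);
  return dX;
}

static fmat maxpool_fwd_f(const fmat& X, const Dim3& d, Dim3& od,
                          arma::umat& arg) {
  od = {d.nx / 2, d.ny / 2, d.nz / 2};
  const int C = X.n_cols;
  fmat Y(od.nvox(), C);
  arg.set_size(od.nvox(), C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    arma::uword* ap = arg.colptr(c);
    for (int z = 0; z < od.nz; ++z) for (int y = 0; y < od.ny; ++y)
      for (int x = 0; x < od.nx; ++x) {
        float best = -1e30f; long bi = 0;
        for (int dz = 0; dz < 2; ++dz) for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            long i = (2 * x + dx) +
              (long)d.nx * ((2 * y + dy) + (long)d.ny * (2 * z + dz));
            if (xp[i] > best) { best = xp[i]; bi = i; }
          }
        long o = x + (long)od.nx * (y + (long)od.ny * z);
        yp[o] = best; ap[o] = bi;
      }
  }
  return Y;
}

static fmat maxpool_bwd_f(const fmat& dY, const arma::umat& arg, long nvox_in) {
  fmat dX(nvox_in, dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const float* gp = dY.colptr(c);
    const arma::uword* ap = arg.colptr(c);
    float* dp = dX.colptr(c);
    for (arma::uword i = 0; i < dY.n_rows; ++i) dp[ap[i]] += gp[i];
  }
  return dX;
}

static fmat upsample_fwd_f(const fmat& X, const Dim3& d, Dim3& od) {
  od = {d.nx * 2, d.ny * 2, d.nz * 2};
  fmat Y(od.nvox(), X.n_cols);
  for (arma::uword c = 0; c < X.n_cols; ++c) {
    const float* xp = X.colptr(c);
    float* yp = Y.colptr(c);
    for (int z = 0; z < od.nz; ++z) for (int y = 0; y < od.ny; ++y)
      for (int x = 0; x < od.nx; ++x)
        yp[x + (long)od.nx * (y + (long)od.ny * z)] =
          xp[(x / 2) + (long)d.nx * ((y / 2) + (long)d.ny * (z / 2))];
  }
  return Y;
}

static fmat upsample_bwd_f(const fmat& dY, const Dim3& od, const Dim3& d) {
  fmat dX(d.nvox(), dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c) {
    const float* gp = dY.colptr(c);
    float* dp = dX.colptr(c);
    for (int z = 0; z < od.nz; ++z) for (int y = 0; y < od.ny; ++y)
      for (int x = 0; x < od.nx; ++x)
        dp[(x / 2) + (long)d.nx * ((y / 2) + (long)d.ny * (z / 2))] +=
          gp[x + (long)od.nx * (y + (long)od.ny * z)];
  }
  return dX;
}

static fmat as_fmat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (int j = 0; j < nm.ncol(); ++j)
    for (int i = 0; i < nm.nrow(); ++i) out(i, j) = (float)nm(i, j);
  return out;
}
static fvec as_fvec(SEXP v) {
  NumericVector nv(v);
  fvec out(nv.size());
  for (int i = 0; i < nv.size(); ++i) out[i] = (float)nv[i];
  return out;
}
static NumericMatrix wrap_fmat(const fmat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}
static NumericVector wrap_fvec(const fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

struct ConvPar { fmat w; fvec b; };
struct BnPar { fvec gamma, beta, rm, rv; };

static ConvPar get_conv(List l) { return {as_fmat(l["w"]), as_fvec(l["b"])}; }
static BnPar get_bn(List l) {
  return {as_fvec(l["gamma"]), as_fvec(l["beta"]),
          as_fvec(l["rm"]), as_fvec(l["rv"])};
}

// Forward (+ optional loss/backward) through the full network. `labels`
// is an integer vector of voxel classes (0-based) when training.
// [[Rcpp::export(name = ".unet_pass")]]
List unet_pass(List params, NumericVector x, IntegerVector dims,
               Nullable<IntegerVector> labels_, double lambda, bool train,
               bool dice_sq = false, double label_smooth = 0.0) {
  List enc = params["enc"], dec = params["dec"], headL = params["head"];
  const int depth = enc.size();
  Dim3 d0 = {dims[0], dims[1], dims[2]};
  long nvox0 = d0.nvox();

  fmat h(nvox0, 1);
  for (long i = 0; i < nvox0; ++i) h(i, 0) = (float)x[i];

  std::vector<Dim3> ldim(depth);
  std::vector<fmat> skips(depth);
  std::vector<fmat> enc_in1(depth), enc_in2(depth);
  std::vector<BnCache> enc_bn1(depth), enc_bn2(depth);
  std::vector<arma::umat> enc_m1(depth), enc_m2(depth), pool_arg(depth);
  Dim3 d = d0;
  // encoder
  for (int i = 0; i < depth; ++i) {
    ldim[i] = d;
    List bl = enc[i];
    ConvPar c1 = get_conv(bl["conv1"]), c2 = get_conv(bl["conv2"]);
    BnPar b1 = get_bn(bl["bn1"]), b2 = get_bn(bl["bn2"]);
    h = cbr_fwd_f(h, d, c1.w, c1.b, b1.gamma, b1.beta, train, b1.rm, b1.rv,
                  enc_in1[i], enc_bn1[i], train ? &enc_m1[i] : nullptr);
    if (!train) { enc_in1[i].reset(); enc_bn1[i].xhat.reset(); }
    h = cbr_fwd_f(h, d, c2.w, c2.b, b2.gamma, b2.beta, train, b2.rm, b2.rv,
                  enc_in2[i], enc_bn2[i], train ? &enc_m2[i] : nullptr);
    if (!train) { enc_in2[i].reset(); enc_bn2[i].xhat.reset(); }
    if (i < depth - 1) {
      skips[i] = h;
      Dim3 od;
      h = maxpool_fwd_f(h, d, od, pool_arg[i]);
      d = od;
    }
  }
  // decoder
  std::vector<fmat> dec_upin(depth), dec_in1(depth), dec_in2(depth);
  std::vector<BnCache> dec_bnu(depth), dec_bn1(depth), dec_bn2(depth);
  std::vector<arma::umat> dec_mu(depth), dec_m1(depth), dec_m2(depth);
  std::vector<Dim3> updim(depth);
  for (int i = depth - 2; i >= 0; --i) {
    updim[i] = d;
    Dim3 od;
    fmat up = upsample_fwd_f(h, d, od);
    d = od;
    List bl = dec[i];
    ConvPar cu = get_conv(bl["upconv"]), c1 = get_conv(bl["conv1"]),
            c2 = get_conv(bl["conv2"]);
    BnPar bu = get_bn(bl["bnup"]), b1 = get_bn(bl["bn1"]),
          b2 = get_bn(bl["bn2"]);
    fmat u = cbr_fwd_f(up, d, cu.w, cu.b, bu.gamma, bu.beta, train, bu.rm,
                       bu.rv, dec_upin[i], dec_bnu[i],
                       train ? &dec_mu[i] : nullptr);
    fmat cat = arma::join_rows(skips[i], u);
    if (!train) { skips[i].reset(); dec_upin[i].reset(); dec_bnu[i].xhat.reset(); }
    h = cbr_fwd_f(cat, d, c1.w, c1.b, b1.gamma, b1.beta, train, b1.rm, b1.rv,
                  dec_in1[i], dec_bn1[i], train ? &dec_m1[i] : nullptr);
    if (!train) { dec_in1[i].reset(); dec_bn1[i].xhat.reset(); }
    h = cbr_fwd_f(h, d, c2.w, c2.b, b2.gamma, b2.beta, train, b2.rm, b2.rv,
                  dec_in2[i], dec_bn2[i], train ? &dec_m2[i] : nullptr);
    if (!train) { dec_in2[i].reset(); dec_bn2[i].xhat.reset(); }
  }
  // head (1x1x1)
  fmat Wh = as_fmat(headL["w"]);
  fvec bh = as_fvec(headL["b"]);
  fmat logits = h * Wh;
  logits.each_row() += bh.t();
  const int C = logits.n_cols;
  // softmax
  fvec mx = arma::max(logits, 1);
  fmat P = logits;
  P.each_col() -= mx;
  P = arma::exp(P);
  fvec rs = arma::sum(P, 1);
  P.each_col() /= rs;

  if (labels_.isNull()) {
    NumericVector probs((R_xlen_t)nvox0 * C);
    probs.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2], C);
    double* pp = REAL(probs);
    for (int c = 0; c < C; ++c) {
      const float* pc = P.colptr(c);
      for (long v = 0; v < nvox0; ++v) pp[v + nvox0 * (long)c] = pc[v];
    }
    return List::create(_["probs"] = probs);
  }

  // loss and gradient w.r.t. logits
  IntegerVector labels(labels_);
  const float epsd = 1e-5f;
  fmat T(nvox0, C, arma::fill::zeros);
  for (long v = 0; v < nvox0; ++v) T(v, labels[v]) = 1.0f;
  fvec inter = arma::sum(P % T, 0).t();
  fvec sums = dice_sq
    ? fvec((arma::sum(arma::square(P), 0) + arma::sum(T, 0)).t())
    : fvec((arma::sum(P, 0) + arma::sum(T, 0)).t());
  double l_md = 0;
  for (int c = 1; c < C; ++c)
    l_md += (2.0 * inter[c] + epsd) / (sums[c] + epsd);
  l_md = 1.0 - l_md / (C - 1);
  // cross-entropy against (optionally label-smoothed) targets; smoothing
  // keeps the logits away from saturation so the Dice gradient, which
  // scales with the predicted probability, stays informative
  const float ls = (float)label_smooth;
  double l_ce = 0;
  if (ls > 0) {
    const float off = ls / C, on = 1.0f - ls + ls / C;
    for (long v = 0; v < nvox0; ++v) {
      for (int c = 0; c < C; ++c) {
        float t = (c == labels[v]) ? on : off;
        l_ce += -t * std::log(std::max(P(v, c), 1e-12f));
      }
    }
  } else {
    for (long v = 0; v < nvox0; ++v)
      l_ce += -std::log(std::max(P(v, labels[v]), 1e-12f));
  }
  l_ce /= nvox0;

  fmat gp(nvox0, C, arma::fill::zeros);
  for (int c = 1; c < C; ++c) {
    float num = 2.0f * inter[c] + epsd;
    float den = sums[c] + epsd;
    if (dice_sq)
      gp.col(c) = -(2.0f * T.col(c) * den - num * 2.0f * P.col(c)) /
        (den * den) / (C - 1);
    else
      gp.col(c) = -(2.0f * T.col(c) * den - num) / (den * den) / (C - 1);
  }
  // dL/dz = P % (gp - dot) + lambda*(P - T_smoothed)/n
  fvec dot = arma::sum(gp % P, 1);
  fmat dlog(nvox0, C);
  for (int c = 0; c < C; ++c) {
    fvec tsm = (ls > 0) ? fvec(T.col(c) * (1.0f - ls) + ls / C)
                        : fvec(T.col(c));
    dlog.col(c) = P.col(c) % (gp.col(c) - dot) +
      (float)lambda * (P.col(c) - tsm) / (float)nvox0;
  }

  // backward
  List genc(depth), gdec(depth), stats_enc(depth), stats_dec(depth);
  fmat dh = dlog * Wh.t();
  fmat ghw = h.t() * dlog;
  fvec ghb = arma::sum(dlog, 0).t();
  dlog.reset(); P.reset(); T.reset(); h.reset();

  std::vector<fmat> dskip(depth);
  for (int i = 0; i < depth - 1; ++i) {
    List bl = dec[i];
    ConvPar cu = get_conv(bl["upconv"]), c1 = get_conv(bl["conv1"]),
            c2 = get_conv(bl["conv2"]);
    BnPar bu = get_bn(bl["bnup"]), b1 = get_bn(bl["bn1"]),
          b2 = get_bn(bl["bn2"]);
    fmat dW2, dW1, dWu; fvec db2, db1, dbu, dg2, dbe2, dg1, dbe1, dgu, dbeu;
    Dim3 dd = ldim[i];
    fmat dcat = cbr_bwd_f(dh, dec_m2[i], dec_in2[i], dd, c2.w, b2.gamma,
                          dec_bn2[i], dW2, db2, dg2, dbe2, true);
    dec_in2[i].reset(); dec_bn2[i].xhat.reset();
    dcat = cbr_bwd_f(dcat, dec_m1[i], dec_in1[i], dd, c1.w, b1.gamma,
                     dec_bn1[i], dW1, db1, dg1, dbe1, true);
    dec_in1[i].reset(); dec_bn1[i].xhat.reset();
    const int nsk = skips[i].n_cols;
    dskip[i] = dcat.cols(0, nsk - 1);
    fmat dup_out = dcat.cols(nsk, dcat.n_cols - 1);
    dcat.reset();
    fmat dup = cbr_bwd_f(dup_out, dec_mu[i], dec_upin[i], dd, cu.w, bu.gamma,
                         dec_bnu[i], dWu, dbu, dgu, dbeu, true);
    dec_upin[i].reset(); dec_bnu[i].xhat.reset();
    dh = upsample_bwd_f(dup, dd, updim[i]);
    gdec[i] = List::create(
      _["conv1"] = List::create(_["w"] = wrap_fmat(dW1), _["b"] = wrap_fvec(db1)),
      _["bn1"] = List::create(_["gamma"] = wrap_fvec(dg1), _["beta"] = wrap_fvec(dbe1)),
      _["conv2"] = List::create(_["w"] = wrap_fmat(dW2), _["b"] = wrap_fvec(db2)),
      _["bn2"] = List::create(_["gamma"] = wrap_fvec(dg2), _["beta"] = wrap_fvec(dbe2)),
      _["upconv"] = List::create(_["w"] = wrap_fmat(dWu), _["b"] = wrap_fvec(dbu)),
      _["bnup"] = List::create(_["gamma"] = wrap_fvec(dgu), _["beta"] = wrap_fvec(dbeu)));
    stats_dec[i] = List::create(
      _["up"] = List::create(_["bn"] = List::create(
          _["mu"] = wrap_fvec(dec_bnu[i].mu), _["v"] = wrap_fvec(dec_bnu[i].v))),
      _["blk"] = List::create(
        _["a"] = List::create(_["bn"] = List::create(
            _["mu"] = wrap_fvec(dec_bn1[i].mu), _["v"] = wrap_fvec(dec_bn1[i].v))),
        _["b"] = List::create(_["bn"] = List::create(
            _["mu"] = wrap_fvec(dec_bn2[i].mu), _["v"] = wrap_fvec(dec_bn2[i].v)))));
  }
  for (int i = depth - 1; i >= 0; --i) {
    if (i < depth - 1) {
      dh = maxpool_bwd_f(dh, pool_arg[i], ldim[i].nvox());
      dh += dskip[i];
      dskip[i].reset();
    }
    List bl = enc[i];
    ConvPar c1 = get_conv(bl["conv1"]), c2 = get_conv(bl["conv2"]);
    BnPar b1 = get_bn(bl["bn1"]), b2 = get_bn(bl["bn2"]);
    fmat dW2, dW1; fvec db2, db1, dg2, dbe2, dg1, dbe1;
    Dim3 dd = ldim[i];
    dh = cbr_bwd_f(dh, enc_m2[i], enc_in2[i], dd, c2.w, b2.gamma, enc_bn2[i],
                   dW2, db2, dg2, dbe2, true);
    enc_in2[i].reset(); enc_bn2[i].xhat.reset();
    dh = cbr_bwd_f(dh, enc_m1[i], enc_in1[i], dd, c1.w, b1.gamma, enc_bn1[i],
                   dW1, db1, dg1, dbe1, i > 0);
    enc_in1[i].reset(); enc_bn1[i].xhat.reset();
    genc[i] = List::create(
      _["conv1"] = List::create(_["w"] = wrap_fmat(dW1), _["b"] = wrap_fvec(db1)),
      _["bn1"] = List::create(_["gamma"] = wrap_fvec(dg1), _["beta"] = wrap_fvec(dbe1)),
      _["conv2"] = List::create(_["w"] = wrap_fmat(dW2), _["b"] = wrap_fvec(db2)),
      _["bn2"] = List::create(_["gamma"] = wrap_fvec(dg2), _["beta"] = wrap_fvec(dbe2)));
    stats_enc[i] = List::create(
      _["a"] = List::create(_["bn"] = List::create(
          _["mu"] = wrap_fvec(enc_bn1[i].mu), _["v"] = wrap_fvec(enc_bn1[i].v))),
      _["b"] = List::create(_["bn"] = List::create(
          _["mu"] = wrap_fvec(enc_bn2[i].mu), _["v"] = wrap_fvec(enc_bn2[i].v))));
  }
  List grads = List::create(
    _["enc"] = genc, _["dec"] = gdec,
    _["head"] = List::create(_["w"] = wrap_fmat(ghw), _["b"] = wrap_fvec(ghb)));
  List stats = List::create(_["enc"] = stats_enc, _["dec"] = stats_dec);
  return List::create(_["loss"] = l_md + lambda * l_ce, _["l_md"] = l_md,
                      _["l_ce"] = l_ce, _["grads"] = grads,
                      _["stats"] = stats);
}
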