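// 3D convolution primitives for the segmentation network.
//
// Activations are stored as R matrices of shape [nvox * nb, channels] where
// rows are volume-major (all voxels of volume 1, then volume 2, ...) and
// voxels are linearized column-major over the (nx, ny, nz) grid, matching R's
// array layout.  Convolutions are lowered to GEMM via im2col/col2im; the
// transposed convolution reuses the same machinery with the roles of input
// and output grids swapped.  Internals run in single precision: the lowering
// is memory-bound and float halves the traffic; weights and activations are
// well inside float range for a batch-normalized network.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct ConvGeom {
  int nx, ny, nz;       // input grid
  int kx, ky, kz;       // kernel
  int sx, sy, sz;       // stride
  int px, py, pz;       // zero padding
  int ox, oy, oz;       // output grid

  ConvGeom(const IntegerVector& dims, const IntegerVector& kernel,
           const IntegerVector& stride, const IntegerVector& pad) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    kx = kernel[0]; ky = kernel[1]; kz = kernel[2];
    sx = stride[0]; sy = stride[1]; sz = stride[2];
    px = pad[0]; py = pad[1]; pz = pad[2];
    ox = (nx + 2 * px - kx) / sx + 1;
    oy = (ny + 2 * py - ky) / sy + 1;
    oz = (nz + 2 * pz - kz) / sz + 1;
    if (ox < 1 || oy < 1 || oz < 1)
      stop("convolution output would be empty for input %dx%dx%d", nx, ny, nz);
  }
  std::size_t n_in() const { return (std::size_t)nx * ny * nz; }
  std::size_t n_out() const { return (std::size_t)ox * oy * oz; }
  int kprod() const { return kx * ky * kz; }
};

// Gather one volume (cin channel planes at x + c*ch_stride) into C
// [n_out, cin * kprod]; column index = ((c*kz + dz)*ky + dy)*kx + dx.
// Rows outside the padded input are written as zeros (no pre-zeroing), with
// a memcpy fast path for unit stride.
static void im2col(const float* x, std::size_t ch_stride, int cin,
                   const ConvGeom& g, arma::fmat& C) {
  for (int c = 0; c < cin; ++c) {
    const float* xp = x + (std::size_t)c * ch_stride;
    for (int dz = 0; dz < g.kz; ++dz)
      for (int dy = 0; dy < g.ky; ++dy)
        for (int dx = 0; dx < g.kx; ++dx) {
          float* Cc = C.colptr(((c * g.kz + dz) * g.ky + dy) * g.kx + dx);
          for (int oz = 0; oz < g.oz; ++oz) {
            const int iz = oz * g.sz - g.pz + dz;
            if (iz < 0 || iz >= g.nz) {
              std::memset(Cc + (std::size_t)oz * g.oy * g.ox, 0,
                          sizeof(float) * g.oy * g.ox);
              continue;
            }
            for (int oy = 0; oy < g.oy; ++oy) {
              const int iy = oy * g.sy - g.py + dy;
              float* Crow = Cc + ((std::size_t)oz * g.oy + oy) * g.ox;
              if (iy < 0 || iy >= g.ny) {
                std::memset(Crow, 0, sizeof(float) * g.ox);
                continue;
              }
              const float* xrow = xp + ((std::size_t)iz * g.ny + iy) * g.nx;
              const int ix0 = -g.px + dx;
              if (g.sx == 1) {
                const int o_lo = std::max(0, -ix0);
                const int o_hi = std::min(g.ox, g.nx - ix0);
                for (int ox = 0; ox < o_lo; ++ox) Crow[ox] = 0.0f;
                if (o_hi > o_lo)
                  std::memcpy(Crow + o_lo, xrow + ix0 + o_lo,
                              sizeof(float) * (o_hi - o_lo));
                for (int ox = std::max(o_lo, o_hi); ox < g.ox; ++ox)
                  Crow[ox] = 0.0f;
              } else {
                for (int ox = 0; ox < g.ox; ++ox) {
                  const int ix = ox * g.sx + ix0;
                  Crow[ox] = (ix >= 0 && ix < g.nx) ? xrow[ix] : 0.0f;
                }
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col: x[plane] += C.
static void col2im(const arma::fmat& C, float* x, std::size_t ch_stride,
                   int cin, const ConvGeom& g) {
  for (int c = 0; c < cin; ++c) {
    float* xp = x + (std::size_t)c * ch_stride;
    for (int dz = 0; dz < g.kz; ++dz)
      for (int dy = 0; dy < g.ky; ++dy)
        for (int dx = 0; dx < g.kx; ++dx) {
          const float* Cc = C.colptr(((c * g.kz + dz) * g.ky + dy) * g.kx + dx);
          for (int oz = 0; oz < g.oz; ++oz) {
            const int iz = oz * g.sz - g.pz + dz;
            if (iz < 0 || iz >= g.nz) continue;
            for (int oy = 0; oy < g.oy; ++oy) {
              const int iy = oy * g.sy - g.py + dy;
              if (iy < 0 || iy >= g.ny) continue;
              const float* Crow = Cc + ((std::size_t)oz * g.oy + oy) * g.ox;
              float* xrow = xp + ((std::size_t)iz * g.ny + iy) * g.nx;
              const int ix0 = -g.px + dx;
              if (g.sx == 1) {
                const int o_lo = std::max(0, -ix0);
                const int o_hi = std::min(g.ox, g.nx - ix0);
                for (int ox = o_lo; ox < o_hi; ++ox) xrow[ix0 + ox] += Crow[ox];
              } else {
                for (int ox = 0; ox < g.ox; ++ox) {
                  const int ix = ox * g.sx + ix0;
                  if (ix >= 0 && ix < g.nx) xrow[ix] += Crow[ox];
                }
              }
            }
          }
        }
  }
}

static arma::fmat to_f(const arma::mat& X) {
  return arma::conv_to<arma::fmat>::from(X);
}
static arma::mat to_d(const arma::fmat& X) {
  return arma::conv_to<arma::mat>::from(X);
}

// [[Rcpp::export]]
IntegerVector cpp_conv_out_dims(IntegerVector dims, IntegerVector kernel,
                                IntegerVector stride, IntegerVector pad) {
  ConvGeom g(dims, kernel, stride, pad);
  return IntegerVector::create(g.ox, g.oy, g.oz);
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat& X, int nb, IntegerVector dims,
                        const arma::mat& W, const arma::vec& b,
                        IntegerVector kernel, IntegerVector stride,
                        IntegerVector pad) {
  ConvGeom g(dims, kernel, stride, pad);
  const int cin = X.n_cols, cout = W.n_cols;
  if ((int)W.n_rows != cin * g.kprod()) stop("weight/kernel shape mismatch");
  if (X.n_rows != (std::size_t)nb * g.n_in()) stop("input row count mismatch");
  arma::fmat Xf = to_f(X), Wf = to_f(W);
  arma::fmat Y(g.n_out() * nb, cout);
  arma::fmat C(g.n_out(), cin * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(Xf.memptr() + (std::size_t)v * g.n_in(), Xf.n_rows, cin, g, C);
    Y.rows(v * g.n_out(), (v + 1) * g.n_out() - 1) = C * Wf;
  }
  arma::mat Yd = to_d(Y);
  Yd.each_row() += b.t();
  return Yd;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat& X, int nb, IntegerVector dims,
                   const arma::mat& W, const arma::mat& dY,
                   IntegerVector kernel, IntegerVector stride,
                   IntegerVector pad) {
  ConvGeom g(dims, kernel, stride, pad);
  const int cin = X.n_cols;
  arma::fmat Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  arma::fmat dX(X.n_rows, cin, arma::fill::zeros);
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::fmat C(g.n_out(), cin * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(Xf.memptr() + (std::size_t)v * g.n_in(), Xf.n_rows, cin, g, C);
    arma::fmat dYv = dYf.rows(v * g.n_out(), (v + 1) * g.n_out() - 1);
    dW += C.t() * dYv;
    arma::fmat dC = dYv * Wf.t();
    col2im(dC, dX.memptr() + (std::size_t)v * g.n_in(), dX.n_rows, cin, g);
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = to_d(dX), _["dW"] = to_d(dW),
                      _["db"] = db.t());
}

// Transposed convolution, kernel 4, stride 2, pad 1: doubles each grid axis.
// W has shape [cin, cout * 64]; column index within a cout block follows the
// same ((c*kz+dz)*ky+dy)*kx+dx order as im2col with c over cout.
static ConvGeom deconv_geom(IntegerVector dims_small) {
  IntegerVector dims_large = IntegerVector::create(
      dims_small[0] * 2, dims_small[1] * 2, dims_small[2] * 2);
  IntegerVector k = IntegerVector::create(4, 4, 4);
  IntegerVector s = IntegerVector::create(2, 2, 2);
  IntegerVector p = IntegerVector::create(1, 1, 1);
  return ConvGeom(dims_large, k, s, p);  // maps large -> small
}

// [[Rcpp::export]]
arma::mat cpp_convt3_fwd(const arma::mat& X, int nb, IntegerVector dims_small,
                         const arma::mat& W, const arma::vec& b) {
  ConvGeom g = deconv_geom(dims_small);
  const int cin = X.n_cols;
  const int cout = W.n_cols / g.kprod();
  if ((int)W.n_rows != cin) stop("deconv weight rows must equal cin");
  if (X.n_rows != (std::size_t)nb * g.n_out()) stop("deconv input rows mismatch");
  arma::fmat Xf = to_f(X), Wf = to_f(W);
  arma::fmat Y(g.n_in() * nb, cout, arma::fill::zeros);
  for (int v = 0; v < nb; ++v) {
    arma::fmat C = Xf.rows(v * g.n_out(), (v + 1) * g.n_out() - 1) * Wf;
    col2im(C, Y.memptr() + (std::size_t)v * g.n_in(), Y.n_rows, cout, g);
  }
  arma::mat Yd = to_d(Y);
  Yd.each_row() += b.t();
  return Yd;
}

// [[Rcpp::export]]
List cpp_convt3_bwd(const arma::mat& X, int nb, IntegerVector dims_small,
                    const arma::mat& W, const arma::mat& dY) {
  ConvGeom g = deconv_geom(dims_small);
  const int cout = W.n_cols / g.kprod();
  arma::fmat Xf = to_f(X), Wf = to_f(W), dYf = to_f(dY);
  arma::fmat dX(X.n_rows, X.n_cols);
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::fmat C(g.n_out(), cout * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(dYf.memptr() + (std::size_t)v * g.n_in(), dYf.n_rows, cout, g, C);
    arma::fmat Xv = Xf.rows(v * g.n_out(), (v + 1) * g.n_out() - 1);
    dX.rows(v * g.n_out(), (v + 1) * g.n_out() - 1) = C * Wf.t();
    dW += Xv.t() * C;
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = to_d(dX), _["dW"] = to_d(dW),
                      _["db"] = db.t());
}

// ---------------------------------------------------------------------------
// Float-buffer (XPtr) variants: activations stay in single-precision C++
// buffers across the layer calls of one forward/backward pass, avoiding
// double<->float conversion and R copies of multi-megabyte activation
// matrices at every block boundary.  Weights remain R doubles (small).

typedef Rcpp::XPtr<arma::fmat> FPtr;

static arma::fmat& deref(SEXP p) { return *FPtr(p); }

// [[Rcpp::export]]
SEXP cpp_fm_new(const arma::mat& X) {
  return FPtr(new arma::fmat(arma::conv_to<arma::fmat>::from(X)), true);
}

// [[Rcpp::export]]
arma::mat cpp_fm_mat(SEXP p) { return to_d(deref(p)); }

// [[Rcpp::export]]
SEXP cpp_add_f(SEXP a, SEXP b) {
  return FPtr(new arma::fmat(deref(a) + deref(b)), true);
}

// [[Rcpp::export]]
SEXP cpp_conv3_fwd_f(SEXP xp, int nb, IntegerVector dims, const arma::mat& W,
                     const arma::vec& b, IntegerVector kernel,
                     IntegerVector stride, IntegerVector pad) {
  ConvGeom g(dims, kernel, stride, pad);
  arma::fmat& X = deref(xp);
  const int cin = X.n_cols, cout = W.n_cols;
  if ((int)W.n_rows != cin * g.kprod()) stop("weight/kernel shape mismatch");
  if (X.n_rows != (std::size_t)nb * g.n_in()) stop("input row count mismatch");
  arma::fmat Wf = to_f(W);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b);
  arma::fmat* Y = new arma::fmat(g.n_out() * nb, cout);
  arma::fmat C(g.n_out(), cin * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(X.memptr() + (std::size_t)v * g.n_in(), X.n_rows, cin, g, C);
    Y->rows(v * g.n_out(), (v + 1) * g.n_out() - 1) = C * Wf;
  }
  Y->each_row() += bf;
  return FPtr(Y, true);
}

// [[Rcpp::export]]
List cpp_conv3_bwd_f(SEXP xp, int nb, IntegerVector dims, const arma::mat& W,
                     SEXP dyp, IntegerVector kernel, IntegerVector stride,
                     IntegerVector pad, bool need_dx) {
  ConvGeom g(dims, kernel, stride, pad);
  arma::fmat& X = deref(xp);
  arma::fmat& dY = deref(dyp);
  const int cin = X.n_cols;
  arma::fmat Wf = to_f(W);
  arma::fmat* dX = need_dx ?
    new arma::fmat(X.n_rows, cin, arma::fill::zeros) : nullptr;
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::fmat C(g.n_out(), cin * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(X.memptr() + (std::size_t)v * g.n_in(), X.n_rows, cin, g, C);
    arma::fmat dYv = dY.rows(v * g.n_out(), (v + 1) * g.n_out() - 1);
    dW += C.t() * dYv;
    if (need_dx) {
      arma::fmat dC = dYv * Wf.t();
      col2im(dC, dX->memptr() + (std::size_t)v * g.n_in(), dX->n_rows, cin, g);
    }
  }
  arma::frowvec db = arma::sum(dY, 0);
  return List::create(
      _["dX"] = need_dx ? (SEXP)FPtr(dX, true) : R_NilValue,
      _["dW"] = to_d(dW),
      _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
SEXP cpp_convt3_fwd_f(SEXP xp, int nb, IntegerVector dims_small,
                      const arma::mat& W) {
  ConvGeom g = deconv_geom(dims_small);
  arma::fmat& X = deref(xp);
  const int cin = X.n_cols;
  const int cout = W.n_cols / g.kprod();
  if ((int)W.n_rows != cin) stop("deconv weight rows must equal cin");
  arma::fmat Wf = to_f(W);
  arma::fmat* Y = new arma::fmat(g.n_in() * nb, cout, arma::fill::zeros);
  for (int v = 0; v < nb; ++v) {
    arma::fmat C = X.rows(v * g.n_out(), (v + 1) * g.n_out() - 1) * Wf;
    col2im(C, Y->memptr() + (std::size_t)v * g.n_in(), Y->n_rows, cout, g);
  }
  return FPtr(Y, true);
}

// [[Rcpp::export]]
List cpp_convt3_bwd_f(SEXP xp, int nb, IntegerVector dims_small,
                      const arma::mat& W, SEXP dyp) {
  ConvGeom g = deconv_geom(dims_small);
  arma::fmat& X = deref(xp);
  arma::fmat& dY = deref(dyp);
  const int cout = W.n_cols / g.kprod();
  arma::fmat Wf = to_f(W);
  arma::fmat* dX = new arma::fmat(X.n_rows, X.n_cols);
  arma::fmat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::fmat C(g.n_out(), cout * g.kprod());
  for (int v = 0; v < nb; ++v) {
    im2col(dY.memptr() + (std::size_t)v * g.n_in(), dY.n_rows, cout, g, C);
    arma::fmat Xv = X.rows(v * g.n_out(), (v + 1) * g.n_out() - 1);
    dX->rows(v * g.n_out(), (v + 1) * g.n_out() - 1) = C * Wf.t();
    dW += Xv.t() * C;
  }
  arma::frowvec db = arma::sum(dY, 0);
  return List::create(_["dX"] = FPtr(dX, true), _["dW"] = to_d(dW),
                      _["db"] = arma::conv_to<arma::vec>::from(db));
}

// [[Rcpp::export]]
List cpp_bn_stats_f(SEXP yp) {
  arma::fmat& Y = deref(yp);
  const arma::uword n = Y.n_rows, c = Y.n_cols;
  arma::vec mu(c), v(c);
  for (arma::uword j = 0; j < c; ++j) {
    const float* y = Y.colptr(j);
    double s = 0, s2 = 0;
    for (arma::uword i = 0; i < n; ++i) { s += y[i]; s2 += (double)y[i] * y[i]; }
    mu[j] = s / n;
    double var = s2 / n - mu[j] * mu[j];
    v[j] = var > 0 ? var : 0;
  }
  return List::create(_["mu"] = mu, _["var"] = v);
}

// [[Rcpp::export]]
SEXP cpp_bn_relu_fwd_f(SEXP yp, const arma::vec& mu, const arma::vec& invstd,
                       const arma::vec& gamma, const arma::vec& beta,
                       bool relu) {
  arma::fmat& Y = deref(yp);
  const arma::uword n = Y.n_rows, c = Y.n_cols;
  arma::fmat* out = new arma::fmat(n, c);
  for (arma::uword j = 0; j < c; ++j) {
    const float a = (float)(gamma[j] * invstd[j]);
    const float b = (float)(beta[j] - gamma[j] * invstd[j] * mu[j]);
    const float* y = Y.colptr(j);
    float* o = out->colptr(j);
    if (relu)
      for (arma::uword i = 0; i < n; ++i) {
        const float t = a * y[i] + b;
        o[i] = t > 0 ? t : 0;
      }
    else
      for (arma::uword i = 0; i < n; ++i) o[i] = a * y[i] + b;
  }
  return FPtr(out, true);
}

// [[Rcpp::export]]
List cpp_bn_relu_bwd_f(SEXP ycp, SEXP doutp, const arma::vec& mu,
                       const arma::vec& invstd, const arma::vec& gamma,
                       const arma::vec& beta, bool relu, bool batch_stats) {
  arma::fmat& Yc = deref(ycp);
  arma::fmat& dOut = deref(doutp);
  const arma::uword n = Yc.n_rows, c = Yc.n_cols;
  arma::fmat* dY = new arma::fmat(n, c);
  arma::vec dgamma(c), dbeta(c);
  for (arma::uword j = 0; j < c; ++j) {
    const float is = (float)invstd[j], m = (float)mu[j];
    const float gm = (float)gamma[j], bt = (float)beta[j];
    const float* y = Yc.colptr(j);
    const float* do_ = dOut.colptr(j);
    float* dy = dY->colptr(j);
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    for (arma::uword i = 0; i < n; ++i) {
      const float xhat = (y[i] - m) * is;
      float gr = do_[i];
      if (relu && (gm * xhat + bt) <= 0) gr = 0;
      const float dxhat = gr * gm;
      dy[i] = dxhat;
      dg += (double)gr * xhat;
      db += gr;
      s1 += dxhat;
      s2 += (double)dxhat * xhat;
    }
    dgamma[j] = dg;
    dbeta[j] = db;
    if (batch_stats) {
      const float inv_n = 1.0f / (float)n;
      const float fs1 = (float)s1, fs2 = (float)s2;
      for (arma::uword i = 0; i < n; ++i) {
        const float xhat = (y[i] - m) * is;
        dy[i] = is * (dy[i] - inv_n * fs1 - xhat * inv_n * fs2);
      }
    } else {
      for (arma::uword i = 0; i < n; ++i) dy[i] *= is;
    }
  }
  return List::create(_["dY"] = FPtr(dY, true), _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
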