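// Affine volume resampler (trilinear / nearest-neighbor) in physical
// millimeter coordinates with a voxel-center convention: voxel (i,j,k)
// (0-based) sits at origin + (i,j,k) * spacing.  For each output voxel the
// source location is q = A %*% p + t in the input volume's physical frame;
// samples outside the input grid take the pad value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_resample(const NumericVector& values, IntegerVector dims_in,
                           NumericVector spacing_in, NumericVector origin_in,
                           IntegerVector dims_out, NumericVector spacing_out,
                           NumericVector origin_out, const arma::mat& A,
                           const arma::vec& tr, std::string method,
                           double pad) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  const bool nearest = (method == "nearest");
  if (!nearest && method != "linear") stop("unknown interpolation method");
  if ((std::size_t)values.size() != (std::size_t)nx * ny * nz)
    stop("values length does not match dims_in");
  NumericVector out((std::size_t)ox * oy * oz);
  const double* v = values.begin();
  double* o = out.begin();

  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return pad;
    return v[((std::size_t)k * ny + j) * nx + i];
  };

  std::size_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    const double pz = origin_out[2] + k * spacing_out[2];
    for (int j = 0; j < oy; ++j) {
      const double py = origin_out[1] + j * spacing_out[1];
      for (int i = 0; i < ox; ++i, ++idx) {
        const double px = origin_out[0] + i * spacing_out[0];
        const double qx = A(0, 0) * px + A(0, 1) * py + A(0, 2) * pz + tr[0];
        const double qy = A(1, 0) * px + A(1, 1) * py + A(1, 2) * pz + tr[1];
        const double qz = A(2, 0) * px + A(2, 1) * py + A(2, 2) * pz + tr[2];
        const double ux = (qx - origin_in[0]) / spacing_in[0];
        const double uy = (qy - origin_in[1]) / spacing_in[1];
        const double uz = (qz - origin_in[2]) / spacing_in[2];
        if (nearest) {
          o[idx] = at((int)std::lround(ux), (int)std::lround(uy),
                      (int)std::lround(uz));
        } else {
          const int fx = (int)std::floor(ux), fy = (int)std::floor(uy),
                    fz = (int)std::floor(uz);
          const double wx = ux - fx, wy = uy - fy, wz = uz - fz;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const double w = (dx ? wx : 1 - wx) * (dy ? wy : 1 - wy) *
                                 (dz ? wz : 1 - wz);
                if (w > 0) acc += w * at(fx + dx, fy + dy, fz + dz);
              }
          o[idx] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
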