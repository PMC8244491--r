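// Atomic-property-field kernels: Gaussian accumulation onto a regular grid
// and trilinear pseudo-energy evaluation.  Grids are stored as flattened
// column-major arrays of shape (nx, ny, nz, nchan), matching R's array().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline long idx4(int ix, int iy, int iz, int ch,
                        int nx, int ny, int nz) {
  return (long)ix + (long)nx * ((long)iy + (long)ny * ((long)iz + (long)nz * ch));
}

// Accumulate sum_atoms phi[atom, ch] * exp(-d^2 / (2 sigma^2)) at every grid
// node within cutoff_sd standard deviations of an atom.  G(0) = 1.
// [[Rcpp::export]]
NumericVector cpp_accumulate_field(IntegerVector dims, NumericVector origin,
                                   double spacing, NumericMatrix coords,
                                   NumericMatrix phi, double sigma,
                                   double cutoff_sd) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nchan = dims[3];
  NumericVector field((long)nx * ny * nz * nchan);
  const double cut = cutoff_sd * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int ix0 = std::max(0, (int)std::ceil((ax - cut - origin[0]) / spacing));
    int ix1 = std::min(nx - 1, (int)std::floor((ax + cut - origin[0]) / spacing));
    int iy0 = std::max(0, (int)std::ceil((ay - cut - origin[1]) / spacing));
    int iy1 = std::min(ny - 1, (int)std::floor((ay + cut - origin[1]) / spacing));
    int iz0 = std::max(0, (int)std::ceil((az - cut - origin[2]) / spacing));
    int iz1 = std::min(nz - 1, (int)std::floor((az + cut - origin[2]) / spacing));
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - az;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - ay;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - ax;
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > cut * cut) continue;
          const double g = std::exp(-d2 * inv2s2);
          for (int ch = 0; ch < nchan; ++ch) {
            const double p = phi(a, ch);
            if (p != 0.0) field[idx4(ix, iy, iz, ch, nx, ny, nz)] += p * g;
          }
        }
      }
    }
  }
  return field;
}

// Pseudo-energy E = -sum_atoms sum_ch phi[atom, ch] * P_ch(r_atom), with
// trilinear interpolation of P; atoms outside the grid contribute 0 and are
// counted.  Returns per-channel overlap sums (so E = -sum(overlap)).
// [[Rcpp::export]]
List cpp_apf_energy(NumericVector field, IntegerVector dims,
                    NumericVector origin, double spacing,
                    NumericMatrix coords, NumericMatrix phi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nchan = dims[3];
  NumericVector overlap(nchan);
  int n_outside = 0;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double fx = (coords(a, 0) - origin[0]) / spacing;
    const double fy = (coords(a, 1) - origin[1]) / spacing;
    const double fz = (coords(a, 2) - origin[2]) / spacing;
    if (fx < 0 || fy < 0 || fz < 0 ||
        fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
      ++n_outside;
      continue;
    }
    int ix = std::min((int)std::floor(fx), nx - 2 >= 0 ? nx - 2 : 0);
    int iy = std::min((int)std::floor(fy), ny - 2 >= 0 ? ny - 2 : 0);
    int iz = std::min((int)std::floor(fz), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) ix = 0;
    if (ny == 1) iy = 0;
    if (nz == 1) iz = 0;
    const double tx = fx - ix, ty = fy - iy, tz = fz - iz;
    const double w[8] = {
      (1 - tx) * (1 - ty) * (1 - tz), tx * (1 - ty) * (1 - tz),
      (1 - tx) * ty * (1 - tz),       tx * ty * (1 - tz),
      (1 - tx) * (1 - ty) * tz,       tx * (1 - ty) * tz,
      (1 - tx) * ty * tz,             tx * ty * tz};
    const int ox[8] = {0, 1, 0, 1, 0, 1, 0, 1};
    const int oy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
    const int oz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
    for (int ch = 0; ch < nchan; ++ch) {
      const double p = phi(a, ch);
      if (p == 0.0) continue;
      double val = 0.0;
      for (int k = 0; k < 8; ++k) {
        if (w[k] == 0.0) continue;
        int jx = ix + ox[k], jy = iy + oy[k], jz = iz + oz[k];
        if (jx >= nx) jx = nx - 1;
        if (jy >= ny) jy = ny - 1;
        if (jz >= nz) jz = nz - 1;
        val += w[k] * field[idx4(jx, jy, jz, ch, nx, ny, nz)];
      }
      overlap[ch] += p * val;
    }
  }
  return List::create(_["overlap"] = overlap, _["n_outside"] = n_outside);
}
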