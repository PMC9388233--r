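// Multi-channel, stride-1, zero-padded 3D cross-correlation and its two
// backward passes.  Arrays are column-major with layout (X, Y, Z, C);
// weights are (kx, ky, kz, Cin, Cout).
//
// All three kernels walk the output (or input) volume row by row along
// the contiguous x axis, accumulating into a local row buffer, so every
// memory row is written once and the 3^3 x Cin input rows touched per
// output row stay cache-resident across neighboring (y, z) positions.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int imax(int a, int b) { return a > b ? a : b; }
static inline int imin(int a, int b) { return a < b ? a : b; }

// [[Rcpp::export(name = ".cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                                 NumericVector w, IntegerVector wdim,
                                 NumericVector bias, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int KX = wdim[0], KY = wdim[1], KZ = wdim[2], Cout = wdim[4];
  if (wdim[3] != Cin) stop("weight input-channel count mismatch");
  const int OX = X + 2 * pad - KX + 1;
  const int OY = Y + 2 * pad - KY + 1;
  const int OZ = Z + 2 * pad - KZ + 1;
  if (OX < 1 || OY < 1 || OZ < 1) stop("kernel larger than padded input");
  NumericVector out((R_xlen_t)OX * OY * OZ * Cout);
  double *po = out.begin();
  const double *px = x.begin();
  const double *pw = w.begin();
  std::vector<double> acc(OX);
  for (int oc = 0; oc < Cout; ++oc) {
    const double b0 = bias[oc % bias.size()];
    for (int oz = 0; oz < OZ; ++oz) {
      for (int oy = 0; oy < OY; ++oy) {
        for (int ox = 0; ox < OX; ++ox) acc[ox] = b0;
        for (int ic = 0; ic < Cin; ++ic) {
          const double *xBase = px + (R_xlen_t)ic * X * Y * Z;
          for (int kz = 0; kz < KZ; ++kz) {
            const int iz = oz + kz - pad;
            if (iz < 0 || iz >= Z) continue;
            for (int ky = 0; ky < KY; ++ky) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= Y) continue;
              const double *xrow =
                xBase + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              const double *wcol =
                pw + (R_xlen_t)KX * (ky + KY * (kz + KZ * (ic + Cin * oc)));
              for (int kx = 0; kx < KX; ++kx) {
                const double wv = wcol[kx];
                const int ox0 = imax(0, pad - kx);
                const int ox1 = imin(OX - 1, X - 1 - kx + pad);
                const double *xr = xrow + (kx - pad);
                for (int ox = ox0; ox <= ox1; ++ox)
                  acc[ox] += wv * xr[ox];
              }
            }
          }
        }
        double *orow = po +
          (R_xlen_t)OX * (oy + (R_xlen_t)OY * (oz + (R_xlen_t)OZ * oc));
        for (int ox = 0; ox < OX; ++ox) orow[ox] = acc[ox];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, Cout);
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd_input")]]
NumericVector cpp_conv3d_bwd_input(NumericVector gy, IntegerVector gydim,
                                   NumericVector w, IntegerVector wdim,
                                   IntegerVector xdim, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int KX = wdim[0], KY = wdim[1], KZ = wdim[2], Cout = wdim[4];
  const int OX = gydim[0], OY = gydim[1], OZ = gydim[2];
  if (gydim[3] != Cout) stop("gradient channel count mismatch");
  NumericVector gx((R_xlen_t)X * Y * Z * Cin);
  double *pgx = gx.begin();
  const double *pgy = gy.begin();
  const double *pw = w.begin();
  std::vector<double> acc(X);
  // gx[ix, iy, iz, ic] = sum_{oc, k} w[k, ic, oc] * gy[i - k + pad, oc]
  for (int ic = 0; ic < Cin; ++ic) {
    for (int iz = 0; iz < Z; ++iz) {
      for (int iy = 0; iy < Y; ++iy) {
        for (int ix = 0; ix < X; ++ix) acc[ix] = 0.0;
        for (int oc = 0; oc < Cout; ++oc) {
          const double *gyBase = pgy + (R_xlen_t)oc * OX * OY * OZ;
          for (int kz = 0; kz < KZ; ++kz) {
            const int oz = iz - kz + pad;
            if (oz < 0 || oz >= OZ) continue;
            for (int ky = 0; ky < KY; ++ky) {
              const int oy = iy - ky + pad;
              if (oy < 0 || oy >= OY) continue;
              const double *gyrow =
                gyBase + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
              const double *wcol =
                pw + (R_xlen_t)KX * (ky + KY * (kz + KZ * (ic + Cin * oc)));
              for (int kx = 0; kx < KX; ++kx) {
                const double wv = wcol[kx];
                // ox = ix - kx + pad must lie in [0, OX-1]
                const int ix0 = imax(0, kx - pad);
                const int ix1 = imin(X - 1, OX - 1 + kx - pad);
                const double *gr = gyrow - (kx - pad);
                for (int ix = ix0; ix <= ix1; ++ix)
                  acc[ix] += wv * gr[ix];
              }
            }
          }
        }
        double *gxrow = pgx +
          (R_xlen_t)X * (iy + (R_xlen_t)Y * (iz + (R_xlen_t)Z * ic));
        for (int ix = 0; ix < X; ++ix) gxrow[ix] = acc[ix];
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  return gx;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd_weights")]]
NumericVector cpp_conv3d_bwd_weights(NumericVector gy, IntegerVector gydim,
                                     NumericVector x, IntegerVector xdim,
                                     IntegerVector wdim, int pad) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], Cin = xdim[3];
  const int KX = wdim[0], KY = wdim[1], KZ = wdim[2], Cout = wdim[4];
  const int OX = gydim[0], OY = gydim[1], OZ = gydim[2];
  NumericVector gw((R_xlen_t)KX * KY * KZ * Cin * Cout);
  double *pgw = gw.begin();
  const double *pgy = gy.begin();
  const double *px = x.begin();
  for (int oc = 0; oc < Cout; ++oc) {
    const double *gyBase = pgy + (R_xlen_t)oc * OX * OY * OZ;
    for (int oz = 0; oz < OZ; ++oz) {
      for (int oy = 0; oy < OY; ++oy) {
        const double *gyrow =
          gyBase + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
        for (int ic = 0; ic < Cin; ++ic) {
          const double *xBase = px + (R_xlen_t)ic * X * Y * Z;
          for (int kz = 0; kz < KZ; ++kz) {
            const int iz = oz + kz - pad;
            if (iz < 0 || iz >= Z) continue;
            for (int ky = 0; ky < KY; ++ky) {
              const int iy = oy + ky - pad;
              if (iy < 0 || iy >= Y) continue;
              const double *xrow =
                xBase + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
              double *gwcol =
                pgw + (R_xlen_t)KX * (ky + KY * (kz + KZ * (ic + Cin * oc)));
              for (int kx = 0; kx < KX; ++kx) {
                const int ox0 = imax(0, pad - kx);
                const int ox1 = imin(OX - 1, X - 1 - kx + pad);
                const double *xr = xrow + (kx - pad);
                double acc = 0.0;
                for (int ox = ox0; ox <= ox1; ++ox)
                  acc += gyrow[ox] * xr[ox];
                gwcol[kx] += acc;
              }
            }
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(KX, KY, KZ, Cin, Cout);
  return gw;
}
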