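// Low-level numerical kernels: im2col-based 3D convolution (forward and
// backward), trilinear resampling, and an exact anisotropic Euclidean
// distance transform. Array layout follows R: column-major, dims (X,Y,Z[,C]).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx4(int x, int y, int z, int c, int X, int Y, int Z) {
  return x + (long)X * (y + (long)Y * (z + (long)Z * c));
}

// Build the im2col matrix A (Nvox x k^3*Cin) for a cubic kernel with "same"
// zero padding. Row v corresponds to output voxel v (column-major order);
// column r = kidx + k^3*ci with kidx = kx + k*(ky + k*kz).
static arma::mat im2col3(const double* in, int X, int Y, int Z, int Cin, int k) {
  const int k3 = k * k * k, pad = (k - 1) / 2;
  const long N = (long)X * Y * Z;
  arma::mat A(N, (long)k3 * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int r = kx + k * (ky + k * kz) + k3 * ci;
          double* col = A.colptr(r);
          const int dx = kx - pad, dy = ky - pad, dz = kz - pad;
          for (int z = 0; z < Z; ++z) {
            const int zz = z + dz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yy = y + dy;
              if (yy < 0 || yy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              const double* src = in + idx4(x0 + dx, yy, zz, ci, X, Y, Z);
              double* dst = col + idx4(x0, y, z, 0, X, Y, Z);
              std::copy(src, src + (x1 - x0), dst);
            }
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector input, IntegerVector dims,
                             NumericMatrix W, NumericVector bias, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Cout = W.ncol();
  arma::mat A = im2col3(input.begin(), X, Y, Z, Cin, k);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat O = A * Wm;
  O.each_row() += arma::rowvec(bias.begin(), Cout, false);
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector input, IntegerVector dims, NumericMatrix W,
                    NumericVector gout, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], Cin = dims[3];
  const int Cout = W.ncol(), k3 = k * k * k, pad = (k - 1) / 2;
  const long N = (long)X * Y * Z;
  arma::mat A = im2col3(input.begin(), X, Y, Z, Cin, k);
  arma::mat G(gout.begin(), N, Cout, false);
  arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat gW = A.t() * G;
  arma::rowvec gb = arma::sum(G, 0);
  arma::mat B = G * Wm.t();  // N x k3*Cin
  NumericVector gin((long)N * Cin);
  double* gi = gin.begin();
  for (int ci = 0; ci < Cin; ++ci) {
    for (int kz = 0; kz < k; ++kz) {
      for (int ky = 0; ky < k; ++ky) {
        for (int kx = 0; kx < k; ++kx) {
          const int r = kx + k * (ky + k * kz) + k3 * ci;
          const double* col = B.colptr(r);
          const int dx = kx - pad, dy = ky - pad, dz = kz - pad;
          for (int z = 0; z < Z; ++z) {
            const int zz = z + dz;
            if (zz < 0 || zz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int yy = y + dy;
              if (yy < 0 || yy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              const double* src = col + idx4(x0, y, z, 0, X, Y, Z);
              double* dst = gi + idx4(x0 + dx, yy, zz, ci, X, Y, Z);
              for (int x = 0; x < x1 - x0; ++x) dst[x] += src[x];
            }
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(X, Y, Z, Cin);
  NumericMatrix gWr(gW.n_rows, gW.n_cols);
  std::copy(gW.begin(), gW.end(), gWr.begin());
  return List::create(_["gin"] = gin, _["gW"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Trilinear interpolation of a 3D volume at arbitrary continuous coordinates
// given in 0-based voxel index space; samples outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix coords, double fill = 0.0) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int n = coords.nrow();
  const double* v = vol.begin();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double cx = coords(i, 0), cy = coords(i, 1), cz = coords(i, 2);
    if (cx < -1 || cx > X || cy < -1 || cy > Y || cz < -1 || cz > Z) {
      out[i] = fill;
      continue;
    }
    const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
    const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int z = z0 + dz;
      const double wz = dz ? fz : 1 - fz;
      if (wz == 0) continue;
      for (int dy = 0; dy <= 1; ++dy) {
        const int y = y0 + dy;
        const double wy = dy ? fy : 1 - fy;
        if (wy == 0) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          const int x = x0 + dx;
          const double wx = dx ? fx : 1 - fx;
          if (wx == 0) continue;
          double val = fill;
          if (x >= 0 && x < X && y >= 0 && y < Y && z >= 0 && z < Z)
            val = v[idx4(x, y, z, 0, X, Y, Z)];
          acc += wx * wy * wz * val;
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing w; f holds squared distances on input, overwritten on output.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[kk];
      s = ((f[q] + q * w * q * w) - (f[p] + p * w * p * w)) /
          (2.0 * q * w - 2.0 * p * w);
      if (s <= z[kk]) {
        --kk;
      } else {
        break;
      }
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q * w) ++kk;
    const double dx = q * w - v[kk] * w;
    d[q] = dx * dx + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel center to the nearest
// foreground voxel center, honoring anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector fg, IntegerVector dims,
                         NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  // Large finite stand-in for "no seed on this scanline"; keeps the envelope
  // arithmetic NaN-free. Any real squared distance on a grid is far smaller.
  const double BIG = 1e20;
  NumericVector D((long)X * Y * Z);
  for (long i = 0; i < (long)X * Y * Z; ++i) D[i] = fg[i] > 0.5 ? 0.0 : BIG;
  const int nmax = std::max(X, std::max(Y, Z));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int zz = 0; zz < Z; ++zz)
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x) f[x] = D[idx4(x, y, zz, 0, X, Y, Z)];
      dt1d(f, d, v, z, X, spacing[0]);
      for (int x = 0; x < X; ++x) D[idx4(x, y, zz, 0, X, Y, Z)] = f[x];
    }
  // y pass
  for (int zz = 0; zz < Z; ++zz)
    for (int x = 0; x < X; ++x) {
      for (int y = 0; y < Y; ++y) f[y] = D[idx4(x, y, zz, 0, X, Y, Z)];
      dt1d(f, d, v, z, Y, spacing[1]);
      for (int y = 0; y < Y; ++y) D[idx4(x, y, zz, 0, X, Y, Z)] = f[y];
    }
  // z pass
  for (int y = 0; y < Y; ++y)
    for (int x = 0; x < X; ++x) {
      for (int zz = 0; zz < Z; ++zz) f[zz] = D[idx4(x, y, zz, 0, X, Y, Z)];
      dt1d(f, d, v, z, Z, spacing[2]);
      for (int zz = 0; zz < Z; ++zz) D[idx4(x, y, zz, 0, X, Y, Z)] = f[zz];
    }
  D.attr("dim") = IntegerVector::create(X, Y, Z);
  return D;
}
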