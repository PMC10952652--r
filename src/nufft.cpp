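// Kaiser-Bessel gridding kernels for the non-uniform FFT.
//
// Convention: sample coordinates arrive as fractional 0-based indices on the
// oversampled Cartesian grid (already shifted so DC sits at G/2); kernel
// support wraps periodically, which is exact for the spectrum of a discrete
// image. spread() is the algebraic transpose of interp() by construction, so
// operator adjoint tests hold to machine precision.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <complex>
using namespace Rcpp;

// modified Bessel I0, Abramowitz & Stegun 9.8.1/9.8.2
static double bessel_i0(double x) {
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75, t2 = t * t;
    return 1.0 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
           t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))));
  }
  double t = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
          t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
          t * (-0.01647633 + t * 0.00392377))))))));
}

static inline double kb_kernel(double u, double half_w, double beta) {
  double r = u / half_w;
  double arg = 1.0 - r * r;
  if (arg < 0) return 0.0;
  return bessel_i0(beta * std::sqrt(arg));
}

// per-sample 1D kernel weights and wrapped grid indices
static inline int kernel_line(double u, int G, double half_w, double beta,
                              int *idx, double *w, int maxpts) {
  int lo = (int)std::ceil(u - half_w);
  int hi = (int)std::floor(u + half_w);
  int n = 0;
  for (int j = lo; j <= hi && n < maxpts; ++j) {
    double val = kb_kernel(u - j, half_w, beta);
    if (val <= 0) continue;
    int jj = j % G; if (jj < 0) jj += G;
    idx[n] = jj; w[n] = val; ++n;
  }
  return n;
}

// [[Rcpp::export]]
ComplexVector nufft_spread3(NumericMatrix coords, ComplexVector vals,
                            IntegerVector dims, double width, double beta) {
  const int G1 = dims[0], G2 = dims[1], G3 = dims[2];
  const double half_w = width / 2.0;
  const int maxpts = (int)width + 2;
  const R_xlen_t n = coords.nrow();
  std::vector<std::complex<double> > grid((size_t)G1 * G2 * G3,
                                          std::complex<double>(0, 0));
  std::vector<int> ix(maxpts), iy(maxpts), iz(maxpts);
  std::vector<double> wx(maxpts), wy(maxpts), wz(maxpts);
  for (R_xlen_t s = 0; s < n; ++s) {
    int nx = kernel_line(coords(s, 0), G1, half_w, beta, ix.data(), wx.data(), maxpts);
    int ny = kernel_line(coords(s, 1), G2, half_w, beta, iy.data(), wy.data(), maxpts);
    int nz = kernel_line(coords(s, 2), G3, half_w, beta, iz.data(), wz.data(), maxpts);
    std::complex<double> v(vals[s].r, vals[s].i);
    for (int c = 0; c < nz; ++c) {
      size_t offz = (size_t)iz[c] * G1 * G2;
      for (int b = 0; b < ny; ++b) {
        size_t offyz = offz + (size_t)iy[b] * G1;
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < nx; ++a)
          grid[offyz + ix[a]] += (wx[a] * wyz) * v;
      }
    }
  }
  ComplexVector out((R_xlen_t)G1 * G2 * G3);
  for (size_t k = 0; k < grid.size(); ++k) {
    out[k].r = grid[k].real(); out[k].i = grid[k].imag();
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
ComplexVector nufft_interp3(ComplexVector grid, NumericMatrix coords,
                            IntegerVector dims, double width, double beta) {
  const int G1 = dims[0], G2 = dims[1], G3 = dims[2];
  const double half_w = width / 2.0;
  const int maxpts = (int)width + 2;
  const R_xlen_t n = coords.nrow();
  ComplexVector out(n);
  std::vector<int> ix(maxpts), iy(maxpts), iz(maxpts);
  std::vector<double> wx(maxpts), wy(maxpts), wz(maxpts);
  for (R_xlen_t s = 0; s < n; ++s) {
    int nx = kernel_line(coords(s, 0), G1, half_w, beta, ix.data(), wx.data(), maxpts);
    int ny = kernel_line(coords(s, 1), G2, half_w, beta, iy.data(), wy.data(), maxpts);
    int nz = kernel_line(coords(s, 2), G3, half_w, beta, iz.data(), wz.data(), maxpts);
    std::complex<double> acc(0, 0);
    for (int c = 0; c < nz; ++c) {
      size_t offz = (size_t)iz[c] * G1 * G2;
      for (int b = 0; b < ny; ++b) {
        size_t offyz = offz + (size_t)iy[b] * G1;
        double wyz = wy[b] * wz[c];
        for (int a = 0; a < nx; ++a) {
          const Rcomplex &g = grid[offyz + ix[a]];
          acc += (wx[a] * wyz) * std::complex<double>(g.r, g.i);
        }
      }
    }
    out[s].r = acc.real(); out[s].i = acc.imag();
  }
  return out;
}
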