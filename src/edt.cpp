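#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform to a seed set, separable
// lower-envelope algorithm (Felzenszwalb & Huttenlocher), generalised to
// anisotropic sample spacing: parabolas sit at physical positions i * s.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 const double s, const int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    const double qs = q * s;
    double sep;
    while (true) {
      const double vs = v[k] * s;
      sep = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (sep <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    const double qs = q * s;
    while (z[k + 1] < qs) k++;
    const double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector seed, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seed.size() != n) stop("seed length does not match dims");
  const double BIG = 1e30;

  NumericVector g(n);
  double* gp = REAL(g);
  const int* sp = LOGICAL(seed);
  for (R_xlen_t i = 0; i < n; i++) gp[i] = sp[i] ? 0.0 : BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int kz = 0; kz < nz; kz++) {
    for (int ky = 0; ky < ny; ky++) {
      double* base = gp + (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = base[i];
      dt1d(f, d, v, z, spacing[0], nx);
      for (int i = 0; i < nx; i++) base[i] = d[i];
    }
  }
  // pass along y
  for (int kz = 0; kz < nz; kz++) {
    for (int kx = 0; kx < nx; kx++) {
      double* base = gp + (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; j++) f[j] = base[(R_xlen_t)j * nx];
      dt1d(f, d, v, z, spacing[1], ny);
      for (int j = 0; j < ny; j++) base[(R_xlen_t)j * nx] = d[j];
    }
  }
  // pass along z
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ky++) {
    for (int kx = 0; kx < nx; kx++) {
      double* base = gp + (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; k++) f[k] = base[(R_xlen_t)k * plane];
      dt1d(f, d, v, z, spacing[2], nz);
      for (int k = 0; k < nz; k++) base[(R_xlen_t)k * plane] = d[k];
    }
  }
  return g;
}
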