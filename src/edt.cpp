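#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm of Felzenszwalb & Huttenlocher applied per axis with a per-axis
// physical step size. Exact for voxel-center distances under anisotropic
// spacing because the squared distance decomposes additively over axes.

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   double step) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no finite source along this line yet
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = step * step;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue; // only finite parabolas enter the envelope
    int p = v[k];
    double s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
               (2.0 * s2 * (q - p));
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
          (2.0 * s2 * (q - p));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    double dq = (double)(q - p) * step;
    d[q] = dq * dq + f[p];
  }
}

// mask: logical vector of length nx*ny*nz in column-major order with
// dimensions (n1, n2, n3); spacing: physical step per axis, length 3.
// Returns squared distances in spacing units^2.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  bool any_fg = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = mask[i] ? 0.0 : INF;
    if (mask[i]) any_fg = true;
  }
  if (!any_fg) stop("mask has no foreground voxels");

  std::vector<double> f, d;

  // axis 1 (fastest-varying)
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      edt_1d(f, d, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }

  // axis 2
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      edt_1d(f, d, spacing[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }

  // axis 3
  if (n3 > 1) {
    f.resize(n3); d.resize(n3);
    const R_xlen_t plane = (R_xlen_t)n1 * n2;
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        R_xlen_t base = (R_xlen_t)j * n1 + i;
        for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * plane];
        edt_1d(f, d, spacing[2]);
        for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * plane] = d[k];
      }
  }
  return out;
}
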