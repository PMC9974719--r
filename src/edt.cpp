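#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform of a
// sampled function, generalised to a physical sample step.  f holds squared
// distances on input; d receives the transformed values.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double step) {
  const double INF = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = q * step;
    double s;
    for (;;) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double vs = v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

//' @title Exact squared Euclidean distance transform (internal)
//' @description For every voxel, the squared physical distance (mm^2) from
//'   its centre to the nearest centre of a foreground voxel, computed exactly
//'   by separable lower-envelope passes with anisotropic spacing.
//' @param mask logical 3-D array (foreground = TRUE)
//' @param spacing numeric length-3 voxel spacing in mm
//' @return double 3-D array of squared distances (0 inside the mask)
//' @keywords internal
// [[Rcpp::export(.edt3d)]]
NumericVector edt3d(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-D array");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double INF = 1e30;
  NumericVector out(mask.size());
  out.attr("dim") = dims;

  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;

  // pass along axis 1 (fastest-varying)
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }

  // axis 2
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = d[j];
    }

  // axis 3
  f.resize(n3); d.resize(n3);
  R_xlen_t plane = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = out[base + (R_xlen_t)k * plane];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) out[base + (R_xlen_t)k * plane] = d[k];
    }

  return out;
}
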