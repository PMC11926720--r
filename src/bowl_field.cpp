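#include <Rcpp.h>
#include <cmath>

// Rayleigh-type diffraction sum for a spherically focused bowl source.
//
// The bowl (radius of curvature F, apex at z = 0, focus at z = F) is
// discretized into rings at polar angle theta_j with area dS_j; each ring
// is sampled at nphi equispaced azimuths (periodic trapezoid rule, which
// converges spectrally for the smooth periodic integrand). For a field
// point (r, z) the kernel accumulates sum over source points of
// exp(i k R) / R * dS. The caller multiplies |sum| by k p0 / (2 pi) to
// obtain the pressure amplitude (p0 = rho c u0, the source surface
// pressure).
//
// [[Rcpp::export]]
Rcpp::NumericVector bowl_field_cpp(Rcpp::NumericVector zf,
                                   Rcpp::NumericVector rf,
                                   Rcpp::NumericVector zs,
                                   Rcpp::NumericVector rs,
                                   Rcpp::NumericVector dS,
                                   double k, int nphi) {
  const int nf = zf.size();
  const int ns = zs.size();
  Rcpp::NumericVector out(nf);

  std::vector<double> cphi(nphi);
  for (int m = 0; m < nphi; ++m)
    cphi[m] = std::cos(2.0 * M_PI * (m + 0.5) / nphi);

  for (int i = 0; i < nf; ++i) {
    const double z = zf[i], r = rf[i];
    double acc_re = 0.0, acc_im = 0.0;
    for (int j = 0; j < ns; ++j) {
      const double dz2 = (z - zs[j]) * (z - zs[j]);
      const double rr2 = r * r + rs[j] * rs[j];
      const double cross = 2.0 * r * rs[j];
      const double w = dS[j] / nphi;
      if (r == 0.0) {
        // on axis the azimuthal integrand is constant
        const double R = std::sqrt(rr2 + dz2);
        acc_re += std::cos(k * R) / R * dS[j];
        acc_im += std::sin(k * R) / R * dS[j];
        continue;
      }
      for (int m = 0; m < nphi; ++m) {
        const double R = std::sqrt(rr2 - cross * cphi[m] + dz2);
        acc_re += std::cos(k * R) / R * w;
        acc_im += std::sin(k * R) / R * w;
      }
    }
    out[i] = std::sqrt(acc_re * acc_re + acc_im * acc_im);
  }
  return out;
}
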