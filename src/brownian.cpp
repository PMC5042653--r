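#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Brownian-dynamics photon-trace simulation.
//
// Molecules of each species random-walk in a periodic cubic box centred on
// a 3D Gaussian detection profile exp(-2 r^2/w0^2 - 2 z^2/z0^2). The
// instantaneous detection factor is averaged over `substeps` inner steps
// per sampling bin (inner step dt/substeps resolves focal transits), the
// per-bin emission rate is brightness * detection + background, optionally
// damped by an exponential bleaching envelope, and counts are drawn
// Poisson per bin. Uses R's RNG so results are reproducible via set.seed().
//
// Species s contributes brightness bg_[s] to the green channel and br_[s]
// to the red one; a crosstalk coefficient adds that fraction of the
// molecular green rate into the red channel.
// [[Rcpp::export(name = ".sim_trace_cpp")]]
List sim_trace_cpp(int n_bins, double dt, int substeps, double box,
                   double w0, double z0,
                   IntegerVector n_mol, NumericVector D,
                   NumericVector brightness_g, NumericVector brightness_r,
                   double background_g, double background_r,
                   double bleach_time, double crosstalk, bool two_channel) {
  const int n_species = n_mol.size();
  const double half = box / 2.0;
  const double cw = 2.0 / (w0 * w0);
  const double cz = 2.0 / (z0 * z0);
  const double dt_sub = dt / substeps;

  std::vector<double> rate_g(n_bins, 0.0);
  std::vector<double> rate_r;
  bool any_red = two_channel;
  if (any_red) rate_r.assign(n_bins, 0.0);

  for (int s = 0; s < n_species; ++s) {
    const double step_sd = std::sqrt(2.0 * D[s] * dt_sub);
    const double bg_s = brightness_g[s];
    const double br_s = brightness_r[s];
    if (bg_s <= 0.0 && br_s <= 0.0) continue;
    for (int m = 0; m < n_mol[s]; ++m) {
      double x = unif_rand() * box - half;
      double y = unif_rand() * box - half;
      double z = unif_rand() * box - half;
      for (int b = 0; b < n_bins; ++b) {
        double det = 0.0;
        for (int k = 0; k < substeps; ++k) {
          x += norm_rand() * step_sd;
          y += norm_rand() * step_sd;
          z += norm_rand() * step_sd;
          // periodic wrap
          if (x > half) x -= box; else if (x < -half) x += box;
          if (y > half) y -= box; else if (y < -half) y += box;
          if (z > half) z -= box; else if (z < -half) z += box;
          det += std::exp(-cw * (x * x + y * y) - cz * z * z);
        }
        det /= substeps;
        rate_g[b] += bg_s * det;
        if (any_red && br_s > 0.0) rate_r[b] += br_s * det;
      }
      if (m % 8 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericVector counts_g(n_bins);
  NumericVector counts_r(any_red ? n_bins : 0);
  for (int b = 0; b < n_bins; ++b) {
    double env = 1.0;
    if (bleach_time > 0.0) env = std::exp(-((b + 0.5) * dt) / bleach_time);
    double lam_g = dt * (env * rate_g[b] + background_g);
    counts_g[b] = R::rpois(lam_g);
    if (any_red) {
      double lam_r = dt * (env * (rate_r[b] + crosstalk * rate_g[b]) +
                           background_r);
      counts_r[b] = R::rpois(lam_r);
    }
  }
  return List::create(_["counts_g"] = counts_g,
                      _["counts_r"] = counts_r);
}
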