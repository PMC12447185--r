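#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isotropic random walk through a two-layer slab: a finite top layer
// (0 <= z < t_mm) over a semi-infinite bottom layer (z >= t_mm). Scattering
// step optical depths are exponential(1) and converted to geometric length
// with the reduced scattering coefficient of the layer the photon is in;
// absorption attenuates the photon weight continuously along the path.
// A photon is detected when it re-crosses the z = 0 surface; its lateral
// exit distance |x| along the scan axis is binned on the offset grid.
// One Raman conversion site per photon is drawn uniformly over its
// scattering events (reservoir sampling); the detected weight is counted
// as "bottom" when that site lies below the interlayer interface.
//
// All lengths in mm, all coefficients in mm^-1. Uses R's RNG: results are
// reproducible under set.seed() on the calling side.

// [[Rcpp::export]]
List cpp_photon_walk(double t_mm,
                     double mua_top, double mus_top,
                     double mua_bot, double mus_bot,
                     NumericVector bin_edges,
                     int n_photons,
                     int max_steps,
                     double roulette_threshold,
                     double roulette_survival) {
  const int n_bins = bin_edges.size() - 1;
  NumericVector w_total(n_bins), w_bottom(n_bins);
  IntegerVector n_det(n_bins);
  double detected_weight = 0.0;
  int detected_count = 0;

  const double eps = 1e-12;

  for (int p = 0; p < n_photons; ++p) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;  // launched straight down
    double w = 1.0;
    int n_scat = 0;
    double site_z = -1.0;  // reservoir-sampled Raman conversion depth
    bool alive = true;
    bool detected = false;

    for (int step = 0; step < max_steps && alive; ++step) {
      double tau = -std::log(unif_rand());  // optical depth to next event

      // propagate, possibly across the layer interface or out the surface
      while (tau > eps) {
        bool in_top = (t_mm > 0.0) &&
          (z < t_mm - eps || (std::fabs(z - t_mm) <= eps && uz < 0.0));
        double mus = in_top ? mus_top : mus_bot;
        double mua = in_top ? mua_top : mua_bot;
        if (mus <= 0.0) { alive = false; break; }  // non-scattering layer
        double s_full = tau / mus;

        // distance to the nearest bounding plane along the direction;
        // the plane at z = 0 is the detection surface
        double d_plane = R_PosInf;
        bool plane_is_surface = false;
        if (uz < -eps) {
          if (in_top) {
            d_plane = (0.0 - z) / uz;
            plane_is_surface = true;
          } else {
            d_plane = (t_mm - z) / uz;
            plane_is_surface = (t_mm <= 0.0);
          }
        } else if (uz > eps) {
          d_plane = in_top ? (t_mm - z) / uz : R_PosInf;
        }

        if (s_full < d_plane) {
          x += ux * s_full; y += uy * s_full; z += uz * s_full;
          w *= std::exp(-mua * s_full);
          tau = 0.0;  // scattering event here
        } else {
          x += ux * d_plane; y += uy * d_plane; z += uz * d_plane;
          w *= std::exp(-mua * d_plane);
          tau -= d_plane * mus;
          if (plane_is_surface) {
            // crossed z = 0: photon escapes and is detected
            double r = std::fabs(x);
            if (n_scat > 0) {
              int bin = -1;
              for (int b = 0; b < n_bins; ++b) {
                if (r >= bin_edges[b] && r < bin_edges[b + 1]) { bin = b; break; }
              }
              if (bin >= 0) {
                w_total[bin] += w;
                if (site_z > t_mm) w_bottom[bin] += w;
                n_det[bin] += 1;
              }
              detected_weight += w;
              detected_count += 1;
            }
            alive = false;
            detected = true;
            break;
          }
          // crossed the interface: snap onto it and keep propagating
          z = t_mm;
        }
      }
      if (!alive) break;

      // scattering event: reservoir-sample the Raman conversion site
      n_scat += 1;
      if (unif_rand() < 1.0 / n_scat) site_z = z;

      // new isotropic direction
      double cost = 2.0 * unif_rand() - 1.0;
      double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      double phi = 2.0 * M_PI * unif_rand();
      ux = sint * std::cos(phi);
      uy = sint * std::sin(phi);
      uz = cost;

      // Russian roulette on low-weight photons
      if (w < roulette_threshold) {
        if (unif_rand() < roulette_survival) w /= roulette_survival;
        else alive = false;
      }
    }
    (void)detected;
  }

  return List::create(_["w_total"] = w_total,
                      _["w_bottom"] = w_bottom,
                      _["n_detected"] = n_det,
                      _["detected_weight"] = detected_weight,
                      _["detected_count"] = detected_count,
                      _["launch_weight"] = (double)n_photons);
}
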