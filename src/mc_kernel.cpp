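// Voxel Monte Carlo photon transport for a slab phantom.
//
// Weighted-photon random walk on a regular voxel grid: exponential
// free paths at the local mu_t, partial absorption (w *= mu_a/mu_t per
// interaction), Henyey-Greenstein scattering, Fresnel reflection at
// the refractive-index-mismatched outer boundary, Russian roulette for
// low weights. Detector tally: weight exiting the x = Lx face within a
// circular aperture around a detector position. Uses R's RNG so runs
// are reproducible via set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double runi() { return unif_rand(); }

struct Grid {
  int nx, ny, nz;
  double vx; // voxel edge (mm), cubic
  const int* region;
  int at(double x, double y, double z) const {
    int i = (int)std::floor(x / vx), j = (int)std::floor(y / vx),
        k = (int)std::floor(z / vx);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    if (k < 0) k = 0; if (k >= nz) k = nz - 1;
    return region[i + nx * (j + (long)ny * k)];
  }
};

static inline void hg_scatter(double g, double& ux, double& uy, double& uz) {
  double ct;
  if (std::fabs(g) < 1e-6) {
    ct = 2.0 * runi() - 1.0;
  } else {
    double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * runi());
    ct = (1.0 + g * g - f * f) / (2.0 * g);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * runi();
  double cp = std::cos(phi), sp = std::sin(phi);
  double nux, nuy, nuz;
  if (std::fabs(uz) > 0.99999) {
    nux = st * cp; nuy = st * sp; nuz = ct * (uz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nuz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
  ux = nux / nrm; uy = nuy / nrm; uz = nuz / nrm;
}

// Fresnel reflectance, unpolarized, from medium n_in into n_out
static inline double fresnel(double n_in, double n_out, double cos_i) {
  if (cos_i < 0) cos_i = -cos_i;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n_in / n_out * sin_i;
  if (sin_t >= 1.0) return 1.0; // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_in * cos_i - n_out * cos_t) / (n_in * cos_i + n_out * cos_t);
  double rp = (n_in * cos_t - n_out * cos_i) / (n_in * cos_t + n_out * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export(name = ".mc_slab")]]
List mc_slab(IntegerVector region, IntegerVector grid_dims, double voxel_mm,
             NumericVector mu_a, NumericVector mu_s, NumericVector g_hg,
             double n_medium,
             NumericMatrix src_pos, NumericMatrix det_pos,
             double cone_half_deg, double aperture_radius,
             int n_photons,
             double roulette_threshold = 1e-4,
             double roulette_p = 0.1) {
  Grid gr{grid_dims[0], grid_dims[1], grid_dims[2], voxel_mm,
          INTEGER(region)};
  const double Lx = gr.nx * voxel_mm, Ly = gr.ny * voxel_mm,
               Lz = gr.nz * voxel_mm;
  const int ns = src_pos.nrow(), nd = det_pos.nrow();
  NumericMatrix tally_w(ns, nd), tally_w2(ns, nd);
  IntegerMatrix tally_n(ns, nd);
  double absorbed = 0, transmitted = 0, reflected = 0, side_exit = 0,
         roulette_net = 0;
  const double cos_half = std::cos(cone_half_deg * M_PI / 180.0);
  const double eps = 1e-9;

  for (int s = 0; s < ns; ++s) {
    for (int ph = 0; ph < n_photons; ++ph) {
      // launch: uniform solid angle inside the cone about +x
      double ct = 1.0 - runi() * (1.0 - cos_half);
      double st = std::sqrt(1.0 - ct * ct);
      double phi = 2.0 * M_PI * runi();
      double ux = ct, uy = st * std::cos(phi), uz = st * std::sin(phi);
      double x = eps, y = src_pos(s, 1), z = src_pos(s, 2);
      double w = 1.0;
      int reg = gr.at(x, y, z);
      double tau = -std::log(runi());
      for (;;) {
        double mt = mu_a[reg] + mu_s[reg];
        // distance to the next voxel face along the direction
        double tb = 1e30;
        {
          double t;
          if (ux > eps)      { t = ((std::floor(x / voxel_mm) + 1) * voxel_mm - x) / ux; if (t < tb) tb = t; }
          else if (ux < -eps){ t = (std::floor(x / voxel_mm) * voxel_mm - x) / ux; if (t < tb) tb = t; }
          if (uy > eps)      { t = ((std::floor(y / voxel_mm) + 1) * voxel_mm - y) / uy; if (t < tb) tb = t; }
          else if (uy < -eps){ t = (std::floor(y / voxel_mm) * voxel_mm - y) / uy; if (t < tb) tb = t; }
          if (uz > eps)      { t = ((std::floor(z / voxel_mm) + 1) * voxel_mm - z) / uz; if (t < tb) tb = t; }
          else if (uz < -eps){ t = (std::floor(z / voxel_mm) * voxel_mm - z) / uz; if (t < tb) tb = t; }
          if (tb < 0) tb = 0;
        }
        double t_int = (mt > 0) ? tau / mt : 1e30;
        if (t_int <= tb) {
          // interaction inside the current voxel
          x += ux * t_int; y += uy * t_int; z += uz * t_int;
          double da = w * mu_a[reg] / mt;
          absorbed += da; w -= da;
          hg_scatter(g_hg[reg], ux, uy, uz);
          tau = -std::log(runi());
          if (w < roulette_threshold) {
            if (runi() < roulette_p) {
              roulette_net -= w * (1.0 / roulette_p - 1.0);
              w /= roulette_p;
            } else { roulette_net += w; break; }
          }
          continue;
        }
        // advance to the voxel face
        x += ux * (tb + eps); y += uy * (tb + eps); z += uz * (tb + eps);
        tau -= mt * (tb + eps);
        if (tau < 0) tau = 0;
        if (x < 0 || x >= Lx || y < 0 || y >= Ly || z < 0 || z >= Lz) {
          // outer boundary: Fresnel
          double cos_i = (x < 0 || x >= Lx) ? std::fabs(ux)
                        : (y < 0 || y >= Ly) ? std::fabs(uy) : std::fabs(uz);
          double R = fresnel(n_medium, 1.0, cos_i);
          if (runi() < R) { // specular reflection back inside
            if (x < 0)      { x = -x + eps; ux = -ux; }
            else if (x >= Lx) { x = 2 * Lx - x - eps; ux = -ux; }
            else if (y < 0) { y = -y + eps; uy = -uy; }
            else if (y >= Ly) { y = 2 * Ly - y - eps; uy = -uy; }
            else if (z < 0) { z = -z + eps; uz = -uz; }
            else            { z = 2 * Lz - z - eps; uz = -uz; }
          } else {
            if (x >= Lx) {
              transmitted += w;
              for (int d = 0; d < nd; ++d) {
                double dy = y - det_pos(d, 1), dz = z - det_pos(d, 2);
                if (dy * dy + dz * dz <= aperture_radius * aperture_radius) {
                  tally_w(s, d) += w; tally_w2(s, d) += w * w;
                  tally_n(s, d) += 1;
                  break;
                }
              }
            } else if (x < 0) reflected += w;
            else side_exit += w;
            break;
          }
        }
        reg = gr.at(x, y, z);
      }
    }
  }
  double launched = (double)ns * n_photons;
  return List::create(
    _["tally_w"] = tally_w, _["tally_w2"] = tally_w2, _["tally_n"] = tally_n,
    _["launched"] = launched, _["absorbed"] = absorbed,
    _["transmitted"] = transmitted, _["reflected"] = reflected,
    _["side_exit"] = side_exit, _["roulette_net"] = roulette_net);
}
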