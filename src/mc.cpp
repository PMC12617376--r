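#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Correlation Monte Carlo in a layered slab.
//
// Photons random-walk through a stack of horizontal layers (z measured from
// the surface downwards).  Step lengths are sampled on the per-layer
// scattering coefficient passed in `mus` (callers pass mus for
// Henyey-Greenstein mode or musp with g = 0 for the isotropic similarity
// mode).  Absorption is NOT applied in flight: per-layer pathlengths L_i and
// momentum transfers Y_i = sum(1 - cos(theta)) are tallied per detected
// photon, so one transport run serves every Brownian-coefficient setting.
// The surface (z = 0) applies Fresnel reflection / total internal reflection
// for the tissue->air index step; photons escaping within a detector ring
// (or disc) are recorded, all other escapes and far-boundary exits are lost.

// ---- xoshiro256++ (self-seeded, platform-independent determinism) ----
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1]
  inline double runif_oc() { return ((next() >> 11) + 1) * 0x1.0p-53; }
  // uniform on [0, 1)
  inline double runif_co() { return (next() >> 11) * 0x1.0p-53; }
};

static inline double fresnel_R(double cos_i, double n_rel) {
  // n_rel = n_inside / n_outside (> 1); returns unpolarised reflectance
  double sin_i2 = 1.0 - cos_i * cos_i;
  double sin_t2 = n_rel * n_rel * sin_i2;
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t2);
  double rs = (n_rel * cos_i - cos_t) / (n_rel * cos_i + cos_t);
  double rp = (n_rel * cos_t - cos_i) / (n_rel * cos_t + cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

static inline void spin(double& ux, double& uy, double& uz,
                        double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
    double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
    double nuz = -sint * cosp * den + uz * cost;
    ux = nux; uy = nuy; uz = nuz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

// [[Rcpp::export]]
List run_mc_cpp(double n_photons,
                NumericVector mus,        // per-layer sampling coefficient (mm^-1)
                NumericVector g,          // per-layer anisotropy used for sampling
                NumericVector mua,        // per-layer absorption, for the roulette threshold only
                NumericVector z_bounds,   // cumulative lower boundary of each layer (mm), last = bottom of slab
                NumericVector det_rho,    // detector centre radii (mm)
                double det_half_width,    // ring half-width or disc radius (mm)
                bool ring,
                double src_radius,
                double n_rel,             // n_tissue / n_outside
                double box_half,          // lateral half-size (mm)
                double kill_od,           // drop photons once sum(mua_i L_i) exceeds this
                double max_path,          // secondary cap on total pathlength (mm)
                int max_events,
                double seed) {
  const int nlay = mus.size();
  const int ndet = det_rho.size();
  Xoshiro rng((uint64_t)seed);

  std::vector<double> rows;  // det_id, Y_1..Y_nlay, L_1..L_nlay
  const int ncol = 1 + 2 * nlay;
  double n_detected = 0, n_lost_top = 0, n_lost_geom = 0, n_killed = 0;

  std::vector<double> Y(nlay), L(nlay);
  const long np = (long)n_photons;
  for (long n = 0; n < np; ++n) {
    // launch: uniform over source disc, pencil beam pointing down
    double rs = src_radius * std::sqrt(rng.runif_co());
    double ps = 2.0 * M_PI * rng.runif_co();
    double x = rs * std::cos(ps), y = rs * std::sin(ps), z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    std::fill(Y.begin(), Y.end(), 0.0);
    std::fill(L.begin(), L.end(), 0.0);
    double path = 0.0, od = 0.0;
    int events = 0;
    bool alive = true;

    while (alive) {
      double xi = -std::log(rng.runif_oc());  // optical depth to next scattering
      // consume xi across layer boundaries
      while (xi > 0.0 && alive) {
        double mu = mus[layer];
        double zlo = (layer == 0) ? 0.0 : z_bounds[layer - 1];
        double zhi = z_bounds[layer];
        double dbound;
        if (uz > 1e-12)       dbound = (zhi - z) / uz;
        else if (uz < -1e-12) dbound = (zlo - z) / uz;
        else                  dbound = 1e30;
        double sfree = (mu > 0.0) ? xi / mu : 1e30;
        if (sfree < dbound) {
          // scatter within this layer
          x += ux * sfree; y += uy * sfree; z += uz * sfree;
          L[layer] += sfree; path += sfree; od += mua[layer] * sfree;
          xi = 0.0;
          if (std::fabs(x) > box_half || std::fabs(y) > box_half) {
            alive = false; n_lost_geom += 1; break;
          }
          double cost, gg = g[layer];
          if (gg == 0.0) {
            cost = 2.0 * rng.runif_co() - 1.0;
          } else {
            double tmp = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * rng.runif_co());
            cost = (1.0 + gg * gg - tmp * tmp) / (2.0 * gg);
            if (cost > 1.0) cost = 1.0;
            if (cost < -1.0) cost = -1.0;
          }
          Y[layer] += 1.0 - cost;
          spin(ux, uy, uz, cost, 2.0 * M_PI * rng.runif_co());
          if (++events > max_events || path > max_path || od > kill_od) {
            alive = false; n_killed += 1;
          }
        } else {
          // advance to the boundary
          x += ux * dbound; y += uy * dbound; z += uz * dbound;
          L[layer] += dbound; path += dbound; od += mua[layer] * dbound;
          xi -= dbound * mu;
          if (std::fabs(x) > box_half || std::fabs(y) > box_half) {
            alive = false; n_lost_geom += 1; break;
          }
          if (uz < 0.0 && layer == 0) {
            // surface interaction
            z = 0.0;
            double cos_i = -uz;
            double R = fresnel_R(cos_i, n_rel);
            if (rng.runif_co() < R) {
              uz = -uz;  // reflected back in
            } else {
              // escapes: detector?
              int hit = -1;
              if (ring) {
                double r = std::sqrt(x * x + y * y);
                for (int k = 0; k < ndet; ++k)
                  if (std::fabs(r - det_rho[k]) <= det_half_width) { hit = k; break; }
              } else {
                for (int k = 0; k < ndet; ++k) {
                  double dx = x - det_rho[k];
                  if (dx * dx + y * y <= det_half_width * det_half_width) { hit = k; break; }
                }
              }
              if (hit >= 0) {
                rows.push_back(hit + 1.0);
                for (int i = 0; i < nlay; ++i) rows.push_back(Y[i]);
                for (int i = 0; i < nlay; ++i) rows.push_back(L[i]);
                n_detected += 1;
              } else {
                n_lost_top += 1;
              }
              alive = false;
            }
          } else if (uz > 0.0) {
            if (layer == nlay - 1) {
              alive = false; n_lost_geom += 1;  // bottom of slab
            } else {
              z = z_bounds[layer]; ++layer;
            }
          } else {
            // moving up across an internal boundary
            z = (layer == 0) ? 0.0 : z_bounds[layer - 1];
            if (layer > 0) --layer;
          }
        }
      }
    }
    if ((n & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  long nr = rows.size() / ncol;
  NumericMatrix tall(nr, ncol);
  for (long r = 0; r < nr; ++r)
    for (int c = 0; c < ncol; ++c) tall(r, c) = rows[r * ncol + c];
  return List::create(_["tallies"] = tall,
                      _["n_launched"] = (double)np,
                      _["n_detected"] = n_detected,
                      _["n_lost_top"] = n_lost_top,
                      _["n_lost_geom"] = n_lost_geom,
                      _["n_killed"] = n_killed);
}

// Evaluate the field-autocorrelation estimator on compressed tallies.
// Each detected photon contributes w_n * exp(-c_n * tau) where
// c_n = 2 k0^2 sum_i alpha_i DB_i Y_{n,i} and w_n = exp(-sum_i mua_i L_{n,i}).
// Returns per-block partial sums so callers can form block-bootstrap errors.
// [[Rcpp::export]]
List tally_accumulate_cpp(NumericVector cdecay, NumericVector w,
                          NumericVector tau, int nblocks) {
  const int n = cdecay.size(), ntau = tau.size();
  NumericMatrix A(nblocks, ntau);
  NumericVector W(nblocks);
  for (int i = 0; i < n; ++i) {
    int b = i % nblocks;
    W[b] += w[i];
    for (int t = 0; t < ntau; ++t)
      A(b, t) += w[i] * std::exp(-cdecay[i] * tau[t]);
  }
  return List::create(_["A"] = A, _["W"] = W);
}
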