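#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

// MCML-style photon random walk in a semi-infinite turbid half-space
// (z >= 0, beam entering at z = 0 along +z). Weight absorption with
// Russian roulette; unpolarized Fresnel with total internal reflection at
// the top boundary. Because the geometry is laterally invariant and
// azimuthally symmetric, only the depth z and direction cosine uz are
// tracked, and the azimuthal factor cos(phi) of the Henyey-Greenstein
// direction update is sampled by Marsaglia rejection (no trigonometry).
// The RNG stream is drawn from std::mt19937_64 raw output (not std::
// distributions, whose mapping is implementation defined), so results are
// bit-reproducible across platforms.

namespace {

inline double uniform(std::mt19937_64 &eng) {
  // 53-bit mantissa uniform in [0, 1)
  return (eng() >> 11) * (1.0 / 9007199254740992.0);
}

// cosine of a uniform azimuth, via a uniform point in the unit disk
inline double rand_cos_azimuth(std::mt19937_64 &eng) {
  double v1, v2, s;
  do {
    v1 = 2.0 * uniform(eng) - 1.0;
    v2 = 2.0 * uniform(eng) - 1.0;
    s = v1 * v1 + v2 * v2;
  } while (s >= 1.0 || s == 0.0);
  return (v1 * v1 - v2 * v2) / s;  // cos(2*phi), phi uniform
}

// Fresnel reflectance for radiance inside medium n hitting the boundary to
// air with incidence cosine ci (> 0).
inline double fresnel_internal(double ci, double n) {
  if (n == 1.0) return 0.0;
  double sin_t2 = n * n * (1.0 - ci * ci);
  if (sin_t2 >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - sin_t2);
  double rs = (n * ci - ct) / (n * ci + ct);
  double rp = (n * ct - ci) / (n * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector mc_reflectance_cpp(double mua, double mus, double g,
                                       double n, double n_photons,
                                       double seed, double max_steps) {
  const double mut = mua + mus;
  const double albedo = (mut > 0.0) ? mus / mut : 0.0;
  const long long N = static_cast<long long>(n_photons);
  const long long cap = static_cast<long long>(max_steps);
  const double w_min = 1e-2, roulette_p = 0.1;

  std::mt19937_64 eng(static_cast<std::uint64_t>(seed));
  double sum = 0.0, sumsq = 0.0, lost = 0.0;

  for (long long i = 0; i < N; ++i) {
    double z = 0.0, uz = 1.0, w = 1.0;
    double escaped = 0.0;
    long long steps = 0;
    for (;;) {
      double s = -std::log(1.0 - uniform(eng)) / mut;
      // propagate, handling (possibly repeated) top-boundary hits
      bool dead = false;
      while (uz < 0.0 && z + s * uz < 0.0) {
        s += z / uz;  // path left after reaching the surface
        z = 0.0;
        if (uniform(eng) < fresnel_internal(-uz, n)) {
          uz = -uz;  // internally reflected, continue with the remainder
        } else {
          escaped = w;
          dead = true;
          break;
        }
      }
      if (dead) break;
      z += s * uz;
      // absorb
      w *= albedo;
      if (w < w_min) {
        if (w <= 0.0 || uniform(eng) >= roulette_p) break;
        w /= roulette_p;
      }
      // scatter: Henyey-Greenstein polar angle, uniform azimuth
      double ct;
      if (g == 0.0) {
        ct = 2.0 * uniform(eng) - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * uniform(eng));
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      }
      double st2 = (1.0 - uz * uz) * (1.0 - ct * ct);
      uz = uz * ct + (st2 > 0.0 ? std::sqrt(st2) * rand_cos_azimuth(eng) : 0.0);
      if (uz > 1.0) uz = 1.0;
      if (uz < -1.0) uz = -1.0;
      if (++steps >= cap) {
        lost += w;
        break;
      }
    }
    sum += escaped;
    sumsq += escaped * escaped;
  }

  double mean = sum / N;
  double var = sumsq / N - mean * mean;
  if (var < 0.0) var = 0.0;
  double se = std::sqrt(var / N);
  return Rcpp::NumericVector::create(mean, se, lost / N);
}
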