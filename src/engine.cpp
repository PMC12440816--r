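#include <Rcpp.h>
#include <cstdint>
#include <cmath>

// Self-contained RNG so engine output depends only on (seed, trajectory index),
// never on the caller's R RNG state. Per-trajectory substreams are derived with
// splitmix64 so any execution order (or future parallelism) reproduces bit-for-bit.

namespace {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ seeded via splitmix64
struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  Rng(uint64_t seed, uint64_t stream) {
    uint64_t st = seed ^ (0xD2B74407B1CE6E93ULL * (stream + 1ULL));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(st);
    has_spare = false;
    spare = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1), never exactly 0 or 1
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal, Box-Muller with spare caching
  inline double norm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double theta = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(theta);
    has_spare = true;
    return r * std::cos(theta);
  }
};

inline void reflect_into(double &x, double lo, double hi) {
  if (!std::isfinite(lo) && !std::isfinite(hi)) return;
  // fold until inside; interval assumed much wider than one step
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
}

} // namespace

using namespace Rcpp;

// Two SHs loaded facing each other: left SH N-terminus at x1, right at x2,
// gap = x2 - x1. Per step both positions take independent Gaussian increments
// sd = sqrt(2 D dt); collision (gap <= 0) is checked at the end of the full
// step, then each surviving SH draws a dissociation Bernoulli.
// fate codes: 1 = collision, 2 = dissociation, 3 = timeout.
// [[Rcpp::export]]
List cpp_simulate_batch(double x1_0, double x2_0, double D, double dt,
                        double half_life, double total_time, int n,
                        double seed, bool memoryless, bool reflect,
                        double lo, double hi) {
  IntegerVector fate(n);
  NumericVector time(n);
  const double step_sd = std::sqrt(2.0 * D * dt);
  const double tau = half_life / std::log(2.0); // mean lifetime
  // memoryless per-step hazard: 1 - 2^(-dt/half_life)
  const double p_const = 1.0 - std::exp2(-dt / half_life);
  const long nsteps = (long)std::ceil(total_time / dt);
  const uint64_t useed = (uint64_t)seed;

  for (int i = 0; i < n; ++i) {
    Rng rng(useed, (uint64_t)i);
    double x1 = x1_0, x2 = x2_0;
    int f = 3;
    double t_event = total_time;

    if (x2 - x1 <= 0.0) { // loaded already touching
      fate[i] = 1;
      time[i] = 0.0;
      continue;
    }

    for (long k = 0; k < nsteps; ++k) {
      double t_now = (double)(k + 1) * dt;
      x1 += step_sd * rng.norm();
      x2 += step_sd * rng.norm();
      if (reflect) {
        reflect_into(x1, lo, hi);
        reflect_into(x2, lo, hi);
      }
      if (x2 - x1 <= 0.0) {
        f = 1;
        t_event = t_now;
        break;
      }
      double p;
      if (memoryless) {
        p = p_const;
      } else {
        // hazard exactly as the printed density (1/tau) exp(-t/tau), clipped
        p = std::exp(-t_now / tau) / tau;
        if (p > 1.0) p = 1.0;
      }
      if (rng.unif() < p || rng.unif() < p) {
        f = 2;
        t_event = t_now;
        break;
      }
    }
    fate[i] = f;
    time[i] = (f == 3) ? total_time : t_event;
  }
  return List::create(_["fate"] = fate, _["time"] = time);
}

// Single-SH lifetimes under the per-step Bernoulli dissociation rule (no
// partner, no collision). Memoryless mode samples the geometric step count
// directly; as_printed iterates the time-dependent clipped hazard.
// Survivors past max_time report Inf.
// [[Rcpp::export]]
NumericVector cpp_sample_lifetimes(int n, double dt, double half_life,
                                   double max_time, double seed,
                                   bool memoryless) {
  NumericVector out(n);
  const double p_const = 1.0 - std::exp2(-dt / half_life);
  const double tau = half_life / std::log(2.0);
  const double log1mp = std::log1p(-p_const);
  const long nsteps = (long)std::ceil(max_time / dt);
  const uint64_t useed = (uint64_t)seed;

  for (int i = 0; i < n; ++i) {
    Rng rng(useed, (uint64_t)i);
    if (memoryless) {
      // geometric number of survived steps; death at end of step k (k >= 1)
      long k = 1 + (long)std::floor(std::log(rng.unif()) / log1mp);
      out[i] = (k > nsteps) ? R_PosInf : (double)k * dt;
    } else {
      double life = R_PosInf;
      for (long k = 0; k < nsteps; ++k) {
        double t_now = (double)(k + 1) * dt;
        double p = std::exp(-t_now / tau) / tau;
        if (p > 1.0) p = 1.0;
        if (rng.unif() < p) {
          life = t_now;
          break;
        }
      }
      out[i] = life;
    }
  }
  return out;
}
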