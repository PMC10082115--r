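#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Truncated-normal mediator draws for the Monte-Carlo g-computation
// expansion.  A self-contained xoshiro256++ stream (seeded via splitmix64
// from the caller's seed) with Marsaglia's polar method generates the
// normals: fast, and bit-reproducible independently of the C++ standard
// library.  The full-matrix and moment-accumulating variants consume the
// identical stream, so estimates computed from either are bit-equal.
//
// Left truncation at 0 is by per-draw rejection; when the acceptance
// probability for a row falls below 0.05 the draw switches to the exact
// inverse-CDF method (same distribution, bounded work).

namespace {

struct Rng {
  std::uint64_t s[4];
  bool have_cached = false;
  double cached = 0.0;

  explicit Rng(double seed) {
    std::uint64_t x = static_cast<std::uint64_t>(seed);
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion of the seed
      x += 0x9E3779B97F4A7C15ULL;
      std::uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    std::uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // uniform on (0, 1), 53-bit
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  inline double norm() {  // Marsaglia polar, one normal per call
    if (have_cached) { have_cached = false; return cached; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    cached = v * f;
    have_cached = true;
    return u * f;
  }
};

inline double draw_one(Rng &rng, double mu, double sigma, bool truncate,
                       double p_neg) {
  if (sigma <= 0.0) {
    double x = mu;
    if (truncate && x < 0.0) x = 0.0;
    return x;
  }
  if (!truncate) return mu + sigma * rng.norm();
  if (p_neg > 0.95) {
    double u = p_neg + (1.0 - p_neg) * rng.unif();
    return mu + sigma * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  double x;
  do {
    x = mu + sigma * rng.norm();
  } while (x < 0.0);
  return x;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_truncnorm_draws(NumericVector mu, double sigma, int K,
                                  double seed, bool truncate) {
  int n = mu.size();
  Rng rng(seed);
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    double p_neg = (truncate && sigma > 0.0)
      ? R::pnorm(0.0, mu[i], sigma, 1, 0) : 0.0;
    for (int k = 0; k < K; ++k)
      out(i, k) = draw_one(rng, mu[i], sigma, truncate, p_neg);
  }
  return out;
}

// Per-row draw moments (mean of M, mean of M^2, ...) over the same stream.
// [[Rcpp::export]]
NumericMatrix cpp_truncnorm_moments(NumericVector mu, double sigma, int K,
                                    double seed, bool truncate, int degree) {
  int n = mu.size();
  Rng rng(seed);
  NumericMatrix out(n, degree);
  std::vector<double> acc(degree);
  for (int i = 0; i < n; ++i) {
    double p_neg = (truncate && sigma > 0.0)
      ? R::pnorm(0.0, mu[i], sigma, 1, 0) : 0.0;
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      double x = draw_one(rng, mu[i], sigma, truncate, p_neg);
      double xp = 1.0;
      for (int d = 0; d < degree; ++d) {
        xp *= x;
        acc[d] += xp;
      }
    }
    for (int d = 0; d < degree; ++d) out(i, d) = acc[d] / K;
  }
  return out;
}
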