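// Brownian-dynamics photon trace simulator for FCS.
//
// Independent point emitters diffuse in a periodic box and are sampled by a
// 3D Gaussian detection profile W(x,y,z) = exp(-2(x^2+y^2)/w0^2 - 2 z^2/z0^2).
// Optional 2D emitters are confined to the plane z = 0 (membrane). Per time
// bin the summed emission rate is converted to a Poisson photon count.
//
// All randomness comes from a self-contained xoshiro256++ stream seeded from
// the user's integer seed, so traces are bit-reproducible across platforms
// and independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform double in (0, 1]
  inline double unif_pos() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }
};

// Marsaglia-Tsang 128-layer ziggurat for standard normals.
struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];
  Xoshiro256* rng;

  explicit Ziggurat(Xoshiro256* r) : rng(r) {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;

    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<uint32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<uint32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw() {
    for (;;) {
      const int32_t hz = static_cast<int32_t>(static_cast<uint32_t>(rng->next()));
      const uint32_t iz = static_cast<uint32_t>(hz) & 127u;
      const uint32_t uabs = hz < 0
          ? static_cast<uint32_t>(-static_cast<int64_t>(hz))
          : static_cast<uint32_t>(hz);
      if (uabs < kn[iz]) return hz * wn[iz];
      const double x = tail_or_wedge(hz, iz);
      if (R_FINITE(x)) return x;
    }
  }

 private:
  // returns NaN to signal "retry"
  inline double tail_or_wedge(int32_t hz, uint32_t iz) {
    const double r = 3.442619855899;
    double x = hz * wn[iz];
    if (iz == 0) {
      double y;
      do {
        x = -std::log(rng->unif_pos()) * 0.2904764515262586;  // 1/r
        y = -std::log(rng->unif_pos());
      } while (y + y < x * x);
      return hz > 0 ? r + x : -r - x;
    }
    if (fn[iz] + rng->unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
      return x;
    return std::numeric_limits<double>::quiet_NaN();
  }
};

// Exact Poisson sampler; splits large means so exp(-lambda) never underflows.
inline int rpois_knuth(Xoshiro256& rng, double lambda) {
  if (lambda <= 0.0) return 0;
  int total = 0;
  while (lambda > 30.0) {
    // Poisson(lambda) = Poisson(30) + Poisson(lambda - 30), independent
    double l30 = std::exp(-30.0), p = 1.0;
    int k = -1;
    do { ++k; p *= rng.unif_pos(); } while (p > l30);
    total += k;
    lambda -= 30.0;
  }
  const double l = std::exp(-lambda);
  double p = 1.0;
  int k = -1;
  do { ++k; p *= rng.unif_pos(); } while (p > l);
  return total + k;
}

// wrap into [-half, half) (periodic boundary)
inline double wrap(double x, double half) {
  const double span = 2.0 * half;
  return x - span * std::floor((x + half) / span);
}

}  // namespace

// [[Rcpp::export(name = ".sim_trace_cpp")]]
List sim_trace_cpp(int n_bins, double bin_width,
                   double lambda3, double diff3, double eps3,
                   double lambda2, double diff2, double eps2,
                   double w0, double z0,
                   double half_xy, double half_z,
                   double bg_rate, double seed) {
  Xoshiro256 rng(static_cast<uint64_t>(seed));
  Ziggurat zig(&rng);

  const int n3 = rpois_knuth(rng, lambda3);
  const int n2 = rpois_knuth(rng, lambda2);

  if ((eps3 > 0 && lambda3 > 0 && n3 == 0) && lambda2 <= 0)
    stop("zero particles drawn in the simulation box; enlarge box or concentration");

  const double updates = static_cast<double>(n3 + n2) * n_bins;
  if (updates > 1e9)
    stop("simulation would need > 1e9 particle-bin updates; reduce duration, bin rate or concentration");

  std::vector<double> x3(n3), y3(n3), z3(n3), x2(n2), y2(n2);
  for (int i = 0; i < n3; ++i) {
    x3[i] = (rng.unif() * 2.0 - 1.0) * half_xy;
    y3[i] = (rng.unif() * 2.0 - 1.0) * half_xy;
    z3[i] = (rng.unif() * 2.0 - 1.0) * half_z;
  }
  for (int i = 0; i < n2; ++i) {
    x2[i] = (rng.unif() * 2.0 - 1.0) * half_xy;
    y2[i] = (rng.unif() * 2.0 - 1.0) * half_xy;
  }

  const double sd3 = std::sqrt(2.0 * diff3 * bin_width);
  const double sd2 = std::sqrt(2.0 * diff2 * bin_width);
  const double inv_w0sq = 2.0 / (w0 * w0);
  const double inv_z0sq = 2.0 / (z0 * z0);
  const double bg_mean = bg_rate * bin_width;
  // exp(-20) ~ 2e-9: emitters beyond this Gaussian exponent add nothing
  const double s_cut = 20.0;

  IntegerVector counts(n_bins);

  for (int t = 0; t < n_bins; ++t) {
    double rate = 0.0;
    for (int i = 0; i < n3; ++i) {
      double xx = x3[i] + sd3 * zig.draw();
      double yy = y3[i] + sd3 * zig.draw();
      double zz = z3[i] + sd3 * zig.draw();
      if (xx < -half_xy || xx >= half_xy) xx = wrap(xx, half_xy);
      if (yy < -half_xy || yy >= half_xy) yy = wrap(yy, half_xy);
      if (zz < -half_z || zz >= half_z) zz = wrap(zz, half_z);
      x3[i] = xx; y3[i] = yy; z3[i] = zz;
      const double s = (xx * xx + yy * yy) * inv_w0sq + zz * zz * inv_z0sq;
      if (s < s_cut) rate += std::exp(-s);
    }
    rate *= eps3;
    if (n2 > 0) {
      double rate2 = 0.0;
      for (int i = 0; i < n2; ++i) {
        double xx = x2[i] + sd2 * zig.draw();
        double yy = y2[i] + sd2 * zig.draw();
        if (xx < -half_xy || xx >= half_xy) xx = wrap(xx, half_xy);
        if (yy < -half_xy || yy >= half_xy) yy = wrap(yy, half_xy);
        x2[i] = xx; y2[i] = yy;
        const double s = (xx * xx + yy * yy) * inv_w0sq;
        if (s < s_cut) rate2 += std::exp(-s);
      }
      rate += eps2 * rate2;
    }
    counts[t] = rpois_knuth(rng, rate * bin_width + bg_mean);
  }

  return List::create(_["counts"] = counts,
                      _["n_particles_3d"] = n3,
                      _["n_particles_2d"] = n2);
}
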