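#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Photon transport in tissue surrounding a cylindrical air hole.
// Coordinates: cylinder axis along y; lumen cross-section x^2 + z^2 = Rin^2.
// Photons launch at (0, 0, Rin) with direction (0, 0, 1), i.e. radially
// outward into the tissue.
//
// RNG: xoshiro256++ seeded via splitmix64 from the user-supplied integer
// seed. Self-contained so that a (seed, config) pair gives bit-identical
// tallies on any platform, independent of R's RNG state.

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0, 1): 53-bit mantissa, zero mapped away
  inline double runif() {
    double u = (next() >> 11) * 0x1.0p-53;
    return (u > 0.0) ? u : 0x1.0p-53;
  }
};

inline void deflect_dir(double &ux, double &uy, double &uz,
                        double ct, double cp, double sp) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double nx, ny, nz;
  if (std::fabs(uz) > 0.99999) {
    nx = st * cp;
    ny = st * sp;
    nz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nz = -st * cp * den + uz * ct;
  }
  double nrm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / nrm; uy = ny / nrm; uz = nz / nrm;
}

} // namespace

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(double n_photons, int seed, double rin, double rout,
                double yhalf, double mu_a, double mu_s, double g,
                double az_bin, double ax_bin,
                double az_band, double long_band,
                bool keep_records, int max_records) {
  const double mu_t = mu_a + mu_s;
  if (mu_t <= 0) stop("mu_t must be positive");
  const double inv_mu_t = 1.0 / mu_t;
  const double rin2 = rin * rin, rout2 = rout * rout;
  const int n_az = (int)std::ceil(180.0 / az_bin);      // bins over (90, 270)
  const int n_ax = (int)std::ceil(yhalf / ax_bin);      // bins over [0, yhalf)
  const int n_az_full = (int)std::ceil(360.0 / az_bin); // bins over [0, 360)
  NumericVector az_hist(n_az), ax_hist(n_ax);
  NumericVector az_full(n_az_full), ax_full(n_ax);
  double n_det = 0, n_outer = 0, n_axial = 0;
  double total_steps = 0;
  std::vector<double> rec_phi, rec_y, rec_w;
  Xoshiro256pp rng((uint64_t)(uint32_t)seed);

  for (double ip = 0; ip < n_photons; ip += 1.0) {
    double x = 0.0, y = 0.0, z = rin;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double path = 0.0;
    bool first = true;
    for (;;) {
      total_steps += 1.0;
      double s = -std::log(rng.runif()) * inv_mu_t;
      // segment vs infinite cylinder x^2 + z^2 = rin^2 (first step leaves
      // the wall radially outward and cannot hit it)
      bool exited = false;
      if (!first) {
        double b = 2.0 * (x * ux + z * uz);
        if (b < 0.0) {
          double a = ux * ux + uz * uz;
          double c = x * x + z * z - rin2;
          double disc = b * b - 4.0 * a * c;
          if (disc >= 0.0 && a > 0.0) {
            double t1 = (-b - std::sqrt(disc)) / (2.0 * a);
            if (t1 > 0.0 && t1 <= s) {
              double hx = x + t1 * ux, hy = y + t1 * uy, hz = z + t1 * uz;
              path += t1;
              double phi = 180.0 + std::atan2(hx, hz) * 180.0 / M_PI;
              double w = (mu_a > 0.0) ? std::exp(-mu_a * path) : 1.0;
              n_det += 1.0;
              {
                int kf = (int)std::floor(phi / az_bin);
                if (kf < 0) kf = 0;
                if (kf >= n_az_full) kf = n_az_full - 1;
                az_full[kf] += w;
                int ka = (int)std::floor(std::fabs(hy) / ax_bin);
                if (ka >= n_ax) ka = n_ax - 1;
                ax_full[ka] += w;
              }
              if (std::fabs(hy) <= az_band) {
                int k = (int)std::floor((phi - 90.0) / az_bin);
                if (k >= 0 && k < n_az) az_hist[k] += w;
              }
              if (std::fabs(phi - 180.0) <= long_band) {
                int k = (int)std::floor(std::fabs(hy) / ax_bin);
                if (k >= 0 && k < n_ax) ax_hist[k] += w;
              }
              if (keep_records && (int)rec_phi.size() < max_records) {
                rec_phi.push_back(phi); rec_y.push_back(hy); rec_w.push_back(w);
              }
              exited = true;
            }
          }
        }
      }
      if (exited) break;
      x += s * ux; y += s * uy; z += s * uz;
      path += s;
      first = false;
      double r2 = x * x + z * z;
      if (r2 >= rout2) { n_outer += 1.0; break; }
      if (std::fabs(y) >= yhalf) { n_axial += 1.0; break; }
      if (!R_finite(x) || !R_finite(y) || !R_finite(z))
        stop("non-finite photon state");
      // Henyey-Greenstein polar deflection
      double u2 = rng.runif();
      double ct;
      if (g > 0.0) {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u2);
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      } else {
        ct = 2.0 * u2 - 1.0;
      }
      // uniform azimuth via rejection sampling in the unit disc
      double v1, v2, rr;
      do {
        v1 = 2.0 * rng.runif() - 1.0;
        v2 = 2.0 * rng.runif() - 1.0;
        rr = v1 * v1 + v2 * v2;
      } while (rr > 1.0 || rr == 0.0);
      double cp = (v1 * v1 - v2 * v2) / rr;
      double sp = 2.0 * v1 * v2 / rr;
      deflect_dir(ux, uy, uz, ct, cp, sp);
    }
  }

  List out = List::create(
    _["az_hist"] = az_hist,
    _["ax_hist"] = ax_hist,
    _["az_full"] = az_full,
    _["ax_full"] = ax_full,
    _["n_detected"] = n_det,
    _["n_lost_outer"] = n_outer,
    _["n_lost_axial"] = n_axial,
    _["total_steps"] = total_steps);
  if (keep_records) {
    out["exit_azimuth"] = wrap(rec_phi);
    out["exit_y"] = wrap(rec_y);
    out["weight"] = wrap(rec_w);
  }
  return out;
}
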