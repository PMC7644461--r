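#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Deterministic, platform-stable RNG for the permutation loop. R's RNG is
// deliberately not used here so that per-pair child seeds (derived from the
// ordered taxon-id pair) make every edge p-value independent of the order in
// which pairs are evaluated.
static inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// FNV-style mix of the master seed with the ordered id pair.
static inline uint64_t pair_seed(uint64_t master, uint64_t a, uint64_t b) {
  uint64_t x = master ^ 0xA0761D6478BD642FULL;
  x = (x ^ a) * 0x100000001B3ULL;
  x = (x ^ b) * 0x100000001B3ULL;
  return splitmix64(x);
}

static inline int rng_below(uint64_t &state, int n) {
  // modulo bias is < 2^-32 for n <= ~1e6; irrelevant at permutation sizes
  return static_cast<int>(splitmix64(state) % static_cast<uint64_t>(n));
}

// Pearson correlation of two pre-ranked vectors via sufficient statistics.
// sx, sy, ssx, ssy are precomputed; only the cross product varies under
// permutation of y.
static double rho_from_cross(double sxy, double sx, double sy, double ssx,
                             double ssy, int n) {
  double num = n * sxy - sx * sy;
  double den = std::sqrt((n * ssx - sx * sx) * (n * ssy - sy * sy));
  return num / den;
}

// Permutation test for one pre-ranked pair. Returns rho and the add-one
// two-sided p-value  p = (1 + #{|rho_b| >= |rho_obs|}) / (n_iter + 1).
static void perm_pair(const double *rx, const double *ry, int n, int n_iter,
                      uint64_t seed, double &rho_out, double &p_out) {
  double sx = 0, sy = 0, ssx = 0, ssy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sx += rx[i];
    sy += ry[i];
    ssx += rx[i] * rx[i];
    ssy += ry[i] * ry[i];
    sxy += rx[i] * ry[i];
  }
  double rho = rho_from_cross(sxy, sx, sy, ssx, ssy, n);
  double target = std::fabs(rho) - 1e-12;

  std::vector<double> perm(ry, ry + n);
  uint64_t state = seed;
  int hits = 0;
  for (int b = 0; b < n_iter; ++b) {
    // Fisher-Yates shuffle of the y ranks
    for (int i = n - 1; i > 0; --i) {
      int j = rng_below(state, i + 1);
      double tmp = perm[i];
      perm[i] = perm[j];
      perm[j] = tmp;
    }
    double cross = 0;
    for (int i = 0; i < n; ++i) cross += rx[i] * perm[i];
    double rb = rho_from_cross(cross, sx, sy, ssx, ssy, n);
    if (std::fabs(rb) >= target) ++hits;
  }
  rho_out = rho;
  p_out = (1.0 + hits) / (n_iter + 1.0);
}

// [[Rcpp::export(name = ".perm_spearman_pair")]]
List perm_spearman_pair_cpp(NumericVector rx, NumericVector ry, int n_iter,
                            double seed_a, double seed_b, double master_seed) {
  int n = rx.size();
  double rho, p;
  uint64_t seed = pair_seed(static_cast<uint64_t>(master_seed),
                            static_cast<uint64_t>(seed_a),
                            static_cast<uint64_t>(seed_b));
  perm_pair(REAL(rx), REAL(ry), n, n_iter, seed, rho, p);
  return List::create(_["rho"] = rho, _["p"] = p);
}

// All unordered column pairs of a pre-ranked matrix (n samples x k taxa).
// ids carries the taxon identifiers used for child-seed derivation.
// [[Rcpp::export(name = ".perm_spearman_all")]]
List perm_spearman_all_cpp(NumericMatrix ranks, IntegerVector ids, int n_iter,
                           double master_seed) {
  int n = ranks.nrow(), k = ranks.ncol();
  int n_pairs = k * (k - 1) / 2;
  IntegerVector out_a(n_pairs), out_b(n_pairs);
  NumericVector out_rho(n_pairs), out_p(n_pairs);
  uint64_t master = static_cast<uint64_t>(master_seed);

  int idx = 0;
  for (int a = 0; a < k - 1; ++a) {
    for (int b = a + 1; b < k; ++b, ++idx) {
      uint64_t lo = static_cast<uint64_t>(std::min(ids[a], ids[b]));
      uint64_t hi = static_cast<uint64_t>(std::max(ids[a], ids[b]));
      uint64_t seed = pair_seed(master, lo, hi);
      double rho, p;
      perm_pair(&ranks(0, a), &ranks(0, b), n, n_iter, seed, rho, p);
      out_a[idx] = ids[a];
      out_b[idx] = ids[b];
      out_rho[idx] = rho;
      out_p[idx] = p;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["taxon_a"] = out_a, _["taxon_b"] = out_b,
                      _["rho"] = out_rho, _["p"] = out_p);
}
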