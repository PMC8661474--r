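// Monte-Carlo non-rejection-rate estimation.
//
// For each feature pair (i, j): repeat n_tests times — draw a conditioning
// order q (fixed, or uniform on 1..q_max), draw a conditioning set Q of size
// q uniformly without replacement from the other features, compute the
// sample partial correlation of i and j given Q by inverting the covariance
// submatrix on {i, j} + Q, and apply the Fisher-z test at the supplied
// critical value.  The NRR is the fraction of non-rejections.
//
// Randomness: a counter-based generator (splitmix64) keyed by
// (seed, i, j) with i < j, so every pair has its own substream and results
// are independent of evaluation order and of parallelisation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline uint64_t splitmix64(uint64_t &state) {
  state += 0x9E3779B97F4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rand_below(uint64_t &state, uint64_t k) {
  // modulo bias is negligible for k << 2^64 and irrelevant to validity
  return splitmix64(state) % k;
}

// [[Rcpp::export]]
Rcpp::NumericVector nrr_pairs_mc(const arma::mat &S, int n,
                                 Rcpp::IntegerMatrix pairs, double crit,
                                 int n_tests, int q_fixed, int q_max,
                                 int seed) {
  const int p = S.n_rows;
  const int m = pairs.nrow();
  Rcpp::NumericVector out(m);

  std::vector<int> pool(p - 2), work(p - 2);
  arma::mat sub, omega;
  arma::uvec idx;

  for (int k = 0; k < m; ++k) {
    const int i = pairs(k, 0), j = pairs(k, 1);  // 0-based, i < j
    uint64_t state = (uint64_t)(uint32_t)seed;
    state = state * 0x9E3779B97F4A7C15ULL ^
            ((uint64_t)(uint32_t)i << 32) ^ (uint64_t)(uint32_t)j;
    splitmix64(state);  // decorrelate nearby keys
    splitmix64(state);

    int np = 0;
    for (int f = 0; f < p; ++f)
      if (f != i && f != j) pool[np++] = f;

    int nonreject = 0;
    for (int t = 0; t < n_tests; ++t) {
      const int q = (q_fixed > 0) ? q_fixed
                                  : 1 + (int)rand_below(state, (uint64_t)q_max);
      std::copy(pool.begin(), pool.end(), work.begin());
      // partial Fisher-Yates: first q entries are the conditioning set
      for (int a = 0; a < q; ++a) {
        int b = a + (int)rand_below(state, (uint64_t)(np - a));
        std::swap(work[a], work[b]);
      }
      idx.set_size(q + 2);
      idx[0] = (arma::uword)i;
      idx[1] = (arma::uword)j;
      for (int a = 0; a < q; ++a) idx[a + 2] = (arma::uword)work[a];

      sub = S.submat(idx, idx);
      bool ok = arma::inv_sympd(omega, sub);
      if (!ok) ok = arma::inv(omega, sub);
      if (!ok) {
        // a perfectly collinear pair makes every submatrix singular; its
        // partial correlation is +-1 and the test rejects
        const double rij = S(i, j) / std::sqrt(S(i, i) * S(j, j));
        if (std::abs(rij) >= 1.0 - 1e-12) continue;  // rejection
        Rcpp::stop("singular covariance submatrix for pair (%d, %d)", i + 1,
                   j + 1);
      }
      const double r = -omega(0, 1) / std::sqrt(omega(0, 0) * omega(1, 1));
      if (std::abs(r) >= 1.0 || !std::isfinite(r)) continue;  // rejection
      const double z = std::sqrt((double)(n - q - 3)) * std::atanh(r);
      if (std::abs(z) <= crit) ++nonreject;
    }
    out[k] = (double)nonreject / (double)n_tests;
  }
  return out;
}
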