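#include <Rcpp.h>
using namespace Rcpp;

// Independent fixed-margin randomizations of a binary matrix by curveball
// trades (Strona et al. 2014, Nat. Commun. 5:4114). Each of the nsim draws
// restarts from the observed matrix and applies n_trades trades, so draws
// are mutually independent; the trade chain has the uniform distribution on
// the margin-preserving class as its stationary distribution. Uses R's RNG.
// [[Rcpp::export]]
NumericVector curveball_draws_cpp(IntegerMatrix m, int nsim, int n_trades) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(Dimension(nr, nc, nsim));
  std::vector<int> w((size_t) nr * nc);
  std::vector<int> pool;
  pool.reserve(2 * nc);

  for (int s = 0; s < nsim; ++s) {
    for (int k = 0; k < nr * nc; ++k) w[k] = m[k];
    if (nr >= 2 && nc >= 2) {
      for (int t = 0; t < n_trades; ++t) {
        int i = (int) (unif_rand() * nr);
        if (i == nr) i = nr - 1;
        int j = (int) (unif_rand() * (nr - 1));
        if (j == nr - 1) j = nr - 2;
        if (j >= i) ++j;
        // columns held by exactly one of the two rows
        pool.clear();
        int a = 0;
        for (int c = 0; c < nc; ++c) {
          const int vi = w[i + (size_t) c * nr], vj = w[j + (size_t) c * nr];
          if (vi == 1 && vj == 0) { pool.push_back(c); ++a; }
        }
        const int a0 = a;
        for (int c = 0; c < nc; ++c) {
          const int vi = w[i + (size_t) c * nr], vj = w[j + (size_t) c * nr];
          if (vi == 0 && vj == 1) pool.push_back(c);
        }
        const int n = (int) pool.size();
        if (a0 == 0 || a0 == n) continue;   // no trade possible
        // partial Fisher-Yates: the first a0 pool entries go to row i
        for (int k = 0; k < a0; ++k) {
          int r = k + (int) (unif_rand() * (n - k));
          if (r >= n) r = n - 1;
          std::swap(pool[k], pool[r]);
        }
        for (int k = 0; k < n; ++k) {
          const int c = pool[k];
          const int vi = (k < a0) ? 1 : 0;
          w[i + (size_t) c * nr] = vi;
          w[j + (size_t) c * nr] = 1 - vi;
        }
      }
    }
    const size_t off = (size_t) s * nr * nc;
    for (int k = 0; k < nr * nc; ++k) out[off + k] = w[k];
  }
  return out;
}
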