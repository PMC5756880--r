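#include <Rcpp.h>
using namespace Rcpp;

// Markov-chain exact test of Hardy-Weinberg proportions.
//
// The state is a perfect pairing of the 2n observed allele copies into n
// diploid genotypes. The uniform distribution over pairings induces, on
// genotype tables, exactly the conditional HWE distribution
//   P(table | allele counts) = n! 2^h / (prod n_ij!) * (prod c_a!) / (2n)!
// so a symmetric partner-swap walk (always accepted) has the null
// distribution as its stationary law. The probability-test p-value is the
// stationary probability of tables no more probable than the observed one,
// estimated from batch means after a dememorization phase.

static double table_log_prob(const IntegerMatrix &cnt, int k) {
  // log of 2^h / prod n_ij!  (constant factors omitted: comparisons only)
  double lp = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = i; j < k; ++j) {
      lp -= lgamma((double)cnt(i, j) + 1.0);
      if (i != j) lp += cnt(i, j) * M_LN2;
    }
  return lp;
}

// [[Rcpp::export]]
NumericVector hwe_chain_cpp(IntegerVector a1, IntegerVector a2, int k,
                            int demem, int batches, int iter_per_batch) {
  int n = a1.size();
  std::vector<int> al(2 * n);
  for (int i = 0; i < n; ++i) { al[2 * i] = a1[i] - 1; al[2 * i + 1] = a2[i] - 1; }

  IntegerMatrix cnt(k, k);
  auto cell = [&](int x, int y) -> int& {
    return x <= y ? cnt(x, y) : cnt(y, x);
  };
  for (int i = 0; i < n; ++i) cell(al[2 * i], al[2 * i + 1])++;
  double lp_obs = table_log_prob(cnt, k);
  double lp_cur = lp_obs;

  auto step = [&]() {
    int u = (int)(unif_rand() * 2 * n);
    int v = (int)(unif_rand() * 2 * n);
    if (u / 2 == v / 2) return;            // same genotype: no-op
    int p1a = al[2 * (u / 2)], p1b = al[2 * (u / 2) + 1];
    int p2a = al[2 * (v / 2)], p2b = al[2 * (v / 2) + 1];
    cell(p1a, p1b)--; cell(p2a, p2b)--;
    std::swap(al[u], al[v]);
    int q1a = al[2 * (u / 2)], q1b = al[2 * (u / 2) + 1];
    int q2a = al[2 * (v / 2)], q2b = al[2 * (v / 2) + 1];
    cell(q1a, q1b)++; cell(q2a, q2b)++;
    lp_cur = table_log_prob(cnt, k);
  };

  for (int t = 0; t < demem; ++t) step();

  const double eps = 1e-9;
  NumericVector batch_means(batches);
  for (int b = 0; b < batches; ++b) {
    long hits = 0;
    for (int t = 0; t < iter_per_batch; ++t) {
      step();
      if (lp_cur <= lp_obs + eps) ++hits;
    }
    batch_means[b] = (double)hits / iter_per_batch;
  }
  double p = mean(batch_means);
  double se = sd(batch_means) / std::sqrt((double)batches);
  return NumericVector::create(_["p"] = p, _["se"] = se,
                               _["steps"] = (double)batches * iter_per_batch);
}
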