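#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for recent migration fractions
// (BayesAss-family model). Each individual sampled in population l has a
// latent migrant ancestry (s, g): non-migrant (l, 0), first-generation
// migrant from s (g = 1), or second-generation migrant with one parental
// gamete from s and one from l (g = 2). The ancestry prior given the
// migration matrix m is P(l,0) = m[l][l] and P(s,g) = m[l][s] / 2 for
// s != l, g in {1,2}. Genotype likelihoods use inbreeding coefficients:
//   P(hom a | p, F) = F p_a + (1-F) p_a^2
//   P(het ab | p, F) = (1-F) 2 p_a p_b
// for generation 0/1 (frequencies and F of the relevant population) and
// gamete-mixture terms for generation 2. Priors are uniform on the
// constrained supports: m rows with non-migrant fraction >= 2/3, allele
// frequencies on the simplex (floored at 1e-6), F in [0, 1).
//
// The mixing parameter (0, 1] scales each proposal window as a fraction
// of the parameter's support: window_m = mixing * 1/3 (an off-diagonal
// entry's range), window_p = mixing * 0.2 (mass shifted between two
// alleles), window_F = mixing * 1.0 (full F range, reflected at bounds).

struct MigState {
  int n, P, L;
  IntegerMatrix geno;          // n x 2L, 0 = missing
  IntegerVector pop;           // 1..P
  IntegerVector K;             // alleles per locus
  NumericMatrix m;             // P x P
  std::vector<NumericMatrix> p;// per locus: K_j x P
  NumericVector F;             // per population
  std::vector<int> src, gen;   // 0-based source, generation
};

static const double PFLOOR = 1e-6;

static double lik_locus(const MigState &st, int i, int j, int s, int g) {
  int a = st.geno(i, 2 * j), b = st.geno(i, 2 * j + 1);
  if (a == 0) return 1.0;
  int l = st.pop[i] - 1;
  const NumericMatrix &pj = st.p[j];
  if (g == 2) {
    double pla = pj(a - 1, l), psa = pj(a - 1, s);
    if (a == b) return pla * psa;
    double plb = pj(b - 1, l), psb = pj(b - 1, s);
    return pla * psb + plb * psa;
  }
  int f = (g == 0) ? l : s;
  double Fq = st.F[f];
  double pa = pj(a - 1, f);
  if (a == b) return Fq * pa + (1.0 - Fq) * pa * pa;
  double pb = pj(b - 1, f);
  return (1.0 - Fq) * 2.0 * pa * pb;
}

static double loglik_ind(const MigState &st, int i, int s, int g) {
  double ll = 0.0;
  for (int j = 0; j < st.L; ++j) ll += std::log(lik_locus(st, i, j, s, g));
  return ll;
}

static double loglik_total(const MigState &st) {
  double ll = 0.0;
  for (int i = 0; i < st.n; ++i) ll += loglik_ind(st, i, st.src[i], st.gen[i]);
  return ll;
}

// [[Rcpp::export]]
List migration_mcmc_cpp(IntegerMatrix geno, IntegerVector pop,
                        IntegerVector K, int P, int n_gen, int burn_in,
                        int thin, double mixing, bool use_likelihood) {
  MigState st;
  st.n = geno.nrow(); st.P = P; st.L = K.size();
  st.geno = geno; st.pop = pop; st.K = K;

  // init m: 90% non-migrant, rest spread evenly
  st.m = NumericMatrix(P, P);
  for (int l = 0; l < P; ++l)
    for (int q = 0; q < P; ++q)
      st.m(l, q) = (l == q) ? (P == 1 ? 1.0 : 0.9)
                            : 0.1 / (double)(P - 1);
  // init p from pooled-by-population counts with one pseudocount
  st.p.resize(st.L);
  for (int j = 0; j < st.L; ++j) {
    NumericMatrix pj(K[j], P);
    std::fill(pj.begin(), pj.end(), 1.0);
    for (int i = 0; i < st.n; ++i) {
      int a = geno(i, 2 * j), b = geno(i, 2 * j + 1);
      if (a > 0) { pj(a - 1, pop[i] - 1) += 1.0; pj(b - 1, pop[i] - 1) += 1.0; }
    }
    for (int q = 0; q < P; ++q) {
      double s = 0.0;
      for (int a = 0; a < K[j]; ++a) s += pj(a, q);
      for (int a = 0; a < K[j]; ++a)
        pj(a, q) = std::max(pj(a, q) / s, PFLOOR);
    }
    st.p[j] = pj;
  }
  st.F = NumericVector(P, 0.1);
  st.src.assign(st.n, 0); st.gen.assign(st.n, 0);
  for (int i = 0; i < st.n; ++i) st.src[i] = pop[i] - 1;

  double wm = mixing / 3.0, wp = mixing * 0.2, wF = mixing;
  long acc_m = 0, try_m = 0, acc_p = 0, try_p = 0, acc_F = 0, try_F = 0;

  int n_keep = (n_gen > burn_in) ? (n_gen - burn_in + thin - 1) / thin : 0;
  NumericMatrix m_samp(n_keep, P * P);
  NumericMatrix F_samp(n_keep, P);
  NumericVector ll_samp(n_keep);
  int ks = 0;

  for (int t = 0; t < n_gen; ++t) {
    // (i) ancestry resampling (Gibbs) for one random individual
    if (P > 1) {
      int i = (int)(unif_rand() * st.n);
      int l = st.pop[i] - 1;
      int ncand = 1 + 2 * (P - 1);
      std::vector<double> lw(ncand);
      std::vector<int> cs(ncand), cg(ncand);
      cs[0] = l; cg[0] = 0;
      lw[0] = std::log(st.m(l, l)) +
        (use_likelihood ? loglik_ind(st, i, l, 0) : 0.0);
      int c = 1;
      for (int q = 0; q < P; ++q) {
        if (q == l) continue;
        for (int g = 1; g <= 2; ++g, ++c) {
          cs[c] = q; cg[c] = g;
          lw[c] = std::log(st.m(l, q) / 2.0) +
            (use_likelihood ? loglik_ind(st, i, q, g) : 0.0);
        }
      }
      double mx = *std::max_element(lw.begin(), lw.end());
      double tot = 0.0;
      for (int cc = 0; cc < ncand; ++cc) { lw[cc] = std::exp(lw[cc] - mx); tot += lw[cc]; }
      double u = unif_rand() * tot, acc2 = 0.0;
      for (int cc = 0; cc < ncand; ++cc) {
        acc2 += lw[cc];
        if (u <= acc2) { st.src[i] = cs[cc]; st.gen[i] = cg[cc]; break; }
      }
    }
    // (ii)-(iv): one parameter-block move per generation, chosen at
    // random (a mixture of kernels, each leaving the target invariant)
    int mv = (int)(unif_rand() * 3.0);
    // (ii) migration-row perturbation
    if (mv == 0 && P > 1) {
      ++try_m;
      int l = (int)(unif_rand() * P);
      int q = (int)(unif_rand() * (P - 1)); if (q >= l) ++q;
      double d = (unif_rand() * 2.0 - 1.0) * wm;
      double nlq = st.m(l, q) + d, nll = st.m(l, l) - d;
      if (nlq >= 0.0 && nll >= 2.0 / 3.0) {
        double lr = 0.0;
        if (use_likelihood) {
          for (int i = 0; i < st.n; ++i) {
            if (st.pop[i] - 1 != l) continue;
            if (st.gen[i] == 0)
              lr += std::log(nll) - std::log(st.m(l, l));
            else if (st.src[i] == q)
              lr += std::log(nlq) - std::log(st.m(l, q));
          }
        }
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
          st.m(l, q) = nlq; st.m(l, l) = nll; ++acc_m;
        }
      }
    }
    // (iii) allele-frequency perturbation
    if (mv == 1) {
      int j = (int)(unif_rand() * st.L);
      if (st.K[j] >= 2) {
        ++try_p;
        int s = (int)(unif_rand() * P);
        int a = (int)(unif_rand() * st.K[j]);
        int b = (int)(unif_rand() * (st.K[j] - 1)); if (b >= a) ++b;
        double d = (unif_rand() * 2.0 - 1.0) * wp;
        double na = st.p[j](a, s) + d, nb = st.p[j](b, s) - d;
        if (na >= PFLOOR && nb >= PFLOOR) {
          double lr = 0.0;
          bool ok = true;
          if (use_likelihood) {
            double oa = st.p[j](a, s), ob = st.p[j](b, s);
            for (int i = 0; i < st.n; ++i) {
              int l = st.pop[i] - 1, g = st.gen[i], sr = st.src[i];
              bool uses = (g == 0 && l == s) || (g == 1 && sr == s) ||
                          (g == 2 && (l == s || sr == s));
              if (!uses) continue;
              double lo = lik_locus(st, i, j, sr, g);
              st.p[j](a, s) = na; st.p[j](b, s) = nb;
              double ln = lik_locus(st, i, j, sr, g);
              st.p[j](a, s) = oa; st.p[j](b, s) = ob;
              if (ln <= 0.0) { ok = false; break; }
              lr += std::log(ln) - std::log(lo);
            }
          }
          if (ok && (lr >= 0.0 || unif_rand() < std::exp(lr))) {
            st.p[j](a, s) = na; st.p[j](b, s) = nb; ++acc_p;
          }
        }
      }
    }
    // (iv) inbreeding-coefficient random walk (reflected at the bounds)
    if (mv == 2) {
      ++try_F;
      int l = (int)(unif_rand() * P);
      double hi = 0.999;
      double nF = st.F[l] + (unif_rand() * 2.0 - 1.0) * wF;
      while (nF < 0.0 || nF > hi) {
        if (nF < 0.0) nF = -nF;
        if (nF > hi) nF = 2.0 * hi - nF;
      }
      double lr = 0.0;
      if (use_likelihood) {
        double oF = st.F[l];
        for (int i = 0; i < st.n; ++i) {
          int g = st.gen[i];
          bool uses = (g == 0 && st.pop[i] - 1 == l) ||
                      (g == 1 && st.src[i] == l);
          if (!uses) continue;
          double lo = loglik_ind(st, i, st.src[i], g);
          st.F[l] = nF;
          double ln = loglik_ind(st, i, st.src[i], g);
          st.F[l] = oF;
          lr += ln - lo;
        }
      }
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) { st.F[l] = nF; ++acc_F; }
    }

    if (t >= burn_in && (t - burn_in) % thin == 0 && ks < n_keep) {
      for (int l = 0; l < P; ++l)
        for (int q = 0; q < P; ++q)
          m_samp(ks, l * P + q) = st.m(l, q);
      for (int l = 0; l < P; ++l) F_samp(ks, l) = st.F[l];
      ll_samp[ks] = use_likelihood ? loglik_total(st) : 0.0;
      ++ks;
    }
  }

  return List::create(
    _["m_samples"] = m_samp, _["F_samples"] = F_samp,
    _["loglik"] = ll_samp,
    _["accept"] = NumericVector::create(
      _["m"] = try_m ? (double)acc_m / try_m : NA_REAL,
      _["p"] = try_p ? (double)acc_p / try_p : NA_REAL,
      _["F"] = try_F ? (double)acc_F / try_F : NA_REAL));
}
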