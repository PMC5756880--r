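#' Combine independent p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square with `2k` degrees of
#' freedom. A component p-value of zero (a Monte-Carlo estimate in which
#' no sampled table reached the observed one) propagates as an infinite
#' statistic; the combined p-value is then reported as below the
#' Monte-Carlo resolution `1 / chain_length`.
#'
#' @param p Numeric vector of p-values (NA entries dropped).
#' @param chain_length Monte-Carlo sample size behind the component
#'   p-values, used only to label an infinite statistic.
#' @return List with `statistic`, `df`, `p_value` and `p_label` (a
#'   display string, `"< 1/N"` when the statistic is infinite).
#' @export
fisher_combine <- function(p, chain_length = NA) {
  p <- p[!is.na(p)]
  k <- length(p)
  if (k == 0L) {
    return(list(statistic = NA_real_, df = 0L, p_value = NA_real_,
                p_label = NA_character_))
  }
  if (any(p == 0)) {
    lab <- if (is.na(chain_length)) "< resolution" else
      sprintf("< %g", 1 / chain_length)
    return(list(statistic = Inf, df = 2L * k, p_value = 0,
                p_label = lab))
  }
  x2 <- -2 * sum(log(p))
  pv <- stats::pchisq(x2, df = 2 * k, lower.tail = FALSE)
  list(statistic = x2, df = 2L * k, p_value = pv,
       p_label = format(pv, digits = 3))
}

# Exact HWE probability test by complete enumeration of genotype tables
# with the observed allele counts. g: n x 2 allele matrix (no missing).
# Returns the exact p-value (sum of conditional probabilities of tables
# no more probable than the observed one).
hwe_enumerate <- function(g) {
  alleles <- sort(unique(c(g[, 1], g[, 2])))
  k <- length(alleles)
  i1 <- match(g[, 1], alleles); i2 <- match(g[, 2], alleles)
  counts <- tabulate(c(i1, i2), nbins = k)
  cells <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  obs <- matrix(0L, k, k)
  for (r in seq_len(nrow(g))) {
    i <- min(i1[r], i2[r]); j <- max(i1[r], i2[r])
    obs[i, j] <- obs[i, j] + 1L
  }
  logw_table <- function(tab) {
    h <- sum(tab[cells[cells[, 1] != cells[, 2], , drop = FALSE]])
    h * log(2) - sum(lgamma(tab[cells] + 1))
  }
  logw_obs <- logw_table(obs)
  logws <- numeric(0)
  tab <- matrix(0L, k, k)
  recurse <- function(ci, rem) {
    if (ci > nrow(cells)) {
      if (all(rem == 0L)) logws[length(logws) + 1L] <<- logw_table(tab)
      return(invisible())
    }
    i <- cells[ci, 1]; j <- cells[ci, 2]
    max_n <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (nij in 0:max_n) {
      tab[i, j] <<- nij
      rem2 <- rem
      rem2[i] <- rem2[i] - nij * (if (i == j) 2L else 1L)
      if (i != j) rem2[j] <- rem2[j] - nij
      # prune: allele i is finished once its last cell (i, k) is set
      if (j == k && rem2[i] != 0L) next
      recurse(ci + 1L, rem2)
    }
    tab[i, j] <<- 0L
  }
  recurse(1L, counts)
  w <- exp(logws - max(logws))
  sum(w[logws <= logw_obs + 1e-9]) / sum(w)
}

#' Exact tests of Hardy--Weinberg proportions
#'
#' Per polymorphic locus and population, the exact probability test of
#' Hardy--Weinberg genotype proportions conditional on the allele
#' counts: complete enumeration of genotype tables when the allele
#' configuration is small (at most `enum_max_tables` candidate tables),
#' otherwise a Markov chain over allele pairings (dememorization,
#' batches and iterations as in the `chain` list), whose stationary law
#' is the exact conditional distribution. Per population, locus p-values
#' are combined by [fisher_combine()].
#'
#' @param ds A [genotype_dataset()].
#' @param chain List with `dememorization`, `batches`,
#'   `iterations` (per batch).
#' @param enum_max_tables Switch to the Markov chain above this many
#'   enumerated tables.
#' @param seed Optional seed for the Markov chains.
#' @return List of class `hwe_exact`: `per_locus` (data frame `pop`,
#'   `locus`, `p`, `se`, `method`; monomorphic or all-missing loci are
#'   absent) and `combined` (per population: `statistic`, `df`,
#'   `p_value`, `p_label`).
#' @export
hwe_exact <- function(ds, chain = list(dememorization = 10000,
                                       batches = 20, iterations = 5000),
                      enum_max_tables = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chain_len <- chain$batches * chain$iterations
  perloc <- list(); comb <- list()
  for (p in ds$populations) {
    ps <- c()
    for (j in seq_along(ds$loci)) {
      g <- genotype_rows_at(p, j)
      if (nrow(g) == 0L) next
      alleles <- unique(c(g[, 1], g[, 2]))
      if (length(alleles) < 2L) next
      counts <- table(c(g[, 1], g[, 2]))
      n_tab_bound <- prod(pmin(as.vector(counts) + 1, 50))
      if (n_tab_bound <= enum_max_tables) {
        pv <- hwe_enumerate(g)
        se <- 0; method <- "enumeration"
      } else {
        i1 <- match(g[, 1], sort(alleles)); i2 <- match(g[, 2], sort(alleles))
        res <- hwe_chain_cpp(i1, i2, length(alleles),
                             chain$dememorization, chain$batches,
                             chain$iterations)
        pv <- res[["p"]]; se <- res[["se"]]; method <- "chain"
      }
      perloc[[length(perloc) + 1L]] <- data.frame(
        pop = p$id, locus = ds$loci[j], p = pv, se = se, method = method)
      ps <- c(ps, pv)
    }
    fc <- fisher_combine(ps, chain_len)
    comb[[length(comb) + 1L]] <- data.frame(
      pop = p$id, n_loci = length(ps), statistic = fc$statistic,
      df = fc$df, p_value = fc$p_value, p_label = fc$p_label)
  }
  structure(list(per_locus = do.call(rbind, perloc),
                 combined = do.call(rbind, comb),
                 chain = chain),
            class = "hwe_exact")
}

g_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ok <- tab > 0
  2 * sum(tab[ok] * log(tab[ok] / e[ok]))
}

#' Exact tests of genotypic linkage disequilibrium
#'
#' For every locus pair and population, a permutation log-likelihood-
#' ratio (G) test on the two-locus genotype contingency table, permuting
#' one locus' genotypes among the population's individuals. Population
#' p-values for a pair are combined across populations by
#' [fisher_combine()] (`df = 2 x` populations contributing). The
#' Bonferroni-corrected significance level `0.05 / n_pairs` is attached.
#'
#' @param ds A [genotype_dataset()].
#' @param n_perm Permutations per population and pair.
#' @param seed Optional RNG seed.
#' @return List of class `ld_exact`: `per_pop` (pop x pair p-values),
#'   `combined` (per pair Fisher combination), `n_pairs`,
#'   `bonferroni_alpha`.
#' @export
ld_exact <- function(ds, n_perm = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(ds$loci)
  prs <- utils::combn(L, 2)
  perpop <- list(); comb <- list()
  for (k in seq_len(ncol(prs))) {
    j1 <- prs[1, k]; j2 <- prs[2, k]
    ps <- c()
    for (p in ds$populations) {
      g1 <- p$genotypes[, j1, , drop = FALSE]
      g2 <- p$genotypes[, j2, , drop = FALSE]
      ok <- !is.na(g1[, 1, 1]) & !is.na(g2[, 1, 1])
      if (sum(ok) < 2L) next
      c1 <- paste(pmin(g1[ok, 1, 1], g1[ok, 1, 2]),
                  pmax(g1[ok, 1, 1], g1[ok, 1, 2]))
      c2 <- paste(pmin(g2[ok, 1, 1], g2[ok, 1, 2]),
                  pmax(g2[ok, 1, 1], g2[ok, 1, 2]))
      f1 <- as.integer(factor(c1)); f2 <- as.integer(factor(c2))
      r <- max(f1); s <- max(f2)
      if (r < 2L || s < 2L) next
      n <- length(f1)
      obs <- g_statistic(matrix(tabulate(f1 + (f2 - 1L) * r, r * s), r, s))
      hits <- 0L
      for (b in seq_len(n_perm)) {
        f2p <- f2[sample.int(n)]
        gg <- g_statistic(matrix(tabulate(f1 + (f2p - 1L) * r, r * s),
                                 r, s))
        if (gg >= obs - 1e-9) hits <- hits + 1L
      }
      pv <- (1 + hits) / (1 + n_perm)
      perpop[[length(perpop) + 1L]] <- data.frame(
        locus1 = ds$loci[j1], locus2 = ds$loci[j2], pop = p$id, p = pv)
      ps <- c(ps, pv)
    }
    fc <- fisher_combine(ps, n_perm)
    comb[[length(comb) + 1L]] <- data.frame(
      locus1 = ds$loci[j1], locus2 = ds$loci[j2],
      n_pops = length(ps), statistic = fc$statistic, df = fc$df,
      p_value = fc$p_value, p_label = fc$p_label)
  }
  structure(list(per_pop = do.call(rbind, perpop),
                 combined = do.call(rbind, comb),
                 n_pairs = ncol(prs),
                 bonferroni_alpha = 0.05 / ncol(prs)),
            class = "ld_exact")
}

#' Exact G tests of genic differentiation between population pairs
#'
#' Per locus, a Monte-Carlo exact G test of allele-frequency homogeneity
#' on the 2 x alleles contingency table of the pair: null tables with
#' the observed margins are drawn by the Patefield algorithm
#' ([stats::r2dtable()]), giving independent samples from the exact
#' conditional null distribution. Locus p-values are combined by
#' [fisher_combine()], matching the conventional pairwise-
#' differentiation table (p-values above the diagonal, F_ST below). The
#' Bonferroni level `0.05 / n_pairs` is attached.
#'
#' @param ds A [genotype_dataset()].
#' @param pairs `"all"` or a 2-column matrix of population ids.
#' @param n_tables Monte-Carlo tables per locus.
#' @param seed Optional RNG seed.
#' @return List of class `genic_exact`: `per_locus`, `combined` (per
#'   pair), `n_pairs`, `bonferroni_alpha`.
#' @export
genic_differentiation_exact <- function(ds, pairs = "all",
                                        n_tables = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- resolve_pairs(ds, pairs)
  perloc <- list(); comb <- list()
  for (k in seq_len(nrow(pr))) {
    id1 <- pr[k, 1]; id2 <- pr[k, 2]
    ps <- c()
    for (j in seq_along(ds$loci)) {
      a1 <- alleles_at(ds$populations[[id1]], j)
      a2 <- alleles_at(ds$populations[[id2]], j)
      if (length(a1) == 0L || length(a2) == 0L) next
      alleles <- sort(unique(c(a1, a2)))
      if (length(alleles) < 2L) next
      tab <- rbind(tabulate(match(a1, alleles), length(alleles)),
                   tabulate(match(a2, alleles), length(alleles)))
      obs <- g_statistic(tab)
      sims <- stats::r2dtable(n_tables, rowSums(tab), colSums(tab))
      gs <- vapply(sims, g_statistic, 0)
      pv <- (1 + sum(gs >= obs - 1e-9)) / (1 + n_tables)
      perloc[[length(perloc) + 1L]] <- data.frame(
        pop1 = id1, pop2 = id2, locus = ds$loci[j], p = pv,
        se = sqrt(pv * (1 - pv) / n_tables))
      ps <- c(ps, pv)
    }
    fc <- fisher_combine(ps, n_tables)
    comb[[length(comb) + 1L]] <- data.frame(
      pop1 = id1, pop2 = id2, n_loci = length(ps),
      statistic = fc$statistic, df = fc$df, p = fc$p_value,
      p_label = fc$p_label)
  }
  structure(list(per_locus = do.call(rbind, perloc),
                 combined = do.call(rbind, comb),
                 n_pairs = nrow(pr),
                 bonferroni_alpha = 0.05 / nrow(pr)),
            class = "genic_exact")
}
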