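#' Bayesian estimation of recent migration fractions
#'
#' Runs a Metropolis-within-Gibbs sampler over migration fractions `m`
#' (where `m[l, q]` is the fraction of population `l` with recent
#' ancestry in `q`), per-population allele frequencies, per-population
#' inbreeding coefficients and per-individual migrant ancestries
#' (generation 0, 1 or 2). The non-migrant fraction of every population
#' is constrained to at least 2/3, so off-diagonal posterior means lie
#' in `[0, 1/3]`. Chains are pooled after burn-in; an ordered pair is
#' flagged significant when `mean +/- 1.96 * SD` excludes zero (the
#' usual reporting rule for recent-migration tables).
#'
#' @param ds A [genotype_dataset()] with at least one population.
#' @param n_gen Generations per chain.
#' @param burn_in Burn-in generations (discarded), `< n_gen`.
#' @param mixing Mixing parameter in (0, 1]: each proposal window is
#'   this fraction of the parameter's support (see the sampler source
#'   for the exact window arithmetic).
#' @param thin Record every `thin`-th generation after burn-in.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior_only If `TRUE`, disable the likelihood (the sampler then
#'   targets the prior; used for sampler validation).
#' @return A `migration_posterior`: matrices `mean`, `sd`,
#'   `significant` (rows = destination, columns = source population, the
#'   `Row -> Column` orientation of migration tables), per-chain traces,
#'   acceptance rates and run parameters.
#' @export
run_migration_mcmc <- function(ds, n_gen = 200000, burn_in = 20000,
                               mixing = 0.8, thin = 50, n_chains = 4,
                               seed = 1L, prior_only = FALSE) {
  stopifnot(burn_in < n_gen, mixing > 0, mixing <= 1)
  enc <- encode_genotypes(ds)
  P <- length(ds$populations)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    res <- migration_mcmc_cpp(enc$geno, enc$pop, enc$K, P,
                              as.integer(n_gen), as.integer(burn_in),
                              as.integer(thin), mixing, !prior_only)
    low <- !is.na(res$accept) & (res$accept < 0.01 | res$accept > 0.99)
    if (any(low)) {
      warning("chain ", ch, ": acceptance rate outside [1%, 99%] for ",
              paste(names(res$accept)[low], collapse = ", "))
    }
    chains[[ch]] <- res
  }
  pooled <- do.call(rbind, lapply(chains, `[[`, "m_samples"))
  ids <- pop_ids(ds)
  mn <- matrix(colMeans(pooled), P, P, byrow = TRUE,
               dimnames = list(ids, ids))
  sdm <- matrix(apply(pooled, 2, stats::sd), P, P, byrow = TRUE,
                dimnames = list(ids, ids))
  sig <- (mn - 1.96 * sdm) > 0 & mn > 0
  diag(sig) <- FALSE
  structure(list(mean = mn, sd = sdm, significant = sig,
                 chains = chains, pops = ids,
                 params = list(n_gen = n_gen, burn_in = burn_in,
                               mixing = mixing, thin = thin,
                               n_chains = n_chains, seed = seed,
                               prior_only = prior_only)),
            class = "migration_posterior")
}

# integer-recoded alleles (1..K per locus; 0 = missing) for the sampler
encode_genotypes <- function(ds) {
  L <- length(ds$loci)
  allg <- lapply(ds$populations, function(p) p$genotypes)
  n_i <- vapply(allg, function(g) dim(g)[1], 0L)
  n <- sum(n_i)
  geno <- matrix(0L, n, 2L * L)
  popv <- rep.int(seq_along(allg), n_i)
  K <- integer(L)
  for (j in seq_len(L)) {
    a1 <- unlist(lapply(allg, function(g) g[, j, 1]))
    a2 <- unlist(lapply(allg, function(g) g[, j, 2]))
    alleles <- sort(unique(c(a1, a2)))
    K[j] <- max(length(alleles), 1L)
    geno[, 2L * j - 1L] <- ifelse(is.na(a1), 0L, match(a1, alleles))
    geno[, 2L * j] <- ifelse(is.na(a2), 0L, match(a2, alleles))
  }
  list(geno = geno, pop = as.integer(popv), K = K)
}

#' @export
print.migration_posterior <- function(x, digits = 3, ...) {
  cat("<migration_posterior> ", length(x$pops), "populations,",
      x$params$n_chains, "chains x", x$params$n_gen, "generations\n")
  cat("Posterior mean migration fractions (rows = into, cols = from;",
      "* = mean +/- 1.96 SD excludes 0):\n")
  m <- format(round(x$mean, digits))
  m[x$significant] <- paste0(m[x$significant], "*")
  print(m, quote = FALSE)
  invisible(x)
}

#' Write plain-text MCMC traces
#'
#' One tab-separated file per chain (`state`, `loglik`, then one column
#' per migration parameter `m_into.from` and inbreeding coefficient),
#' loadable by standard trace viewers.
#'
#' @param post A `migration_posterior`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_traces <- function(post, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  P <- length(post$pops)
  mcols <- as.vector(t(outer(post$pops, post$pops,
                             function(a, b) paste0("m_", a, ".", b))))
  paths <- character(length(post$chains))
  for (ch in seq_along(post$chains)) {
    tr <- post$chains[[ch]]
    df <- data.frame(state = seq_len(nrow(tr$m_samples)) *
                       post$params$thin,
                     loglik = tr$loglik)
    df[mcols] <- tr$m_samples
    df[paste0("F_", post$pops)] <- tr$F_samples
    paths[ch] <- file.path(dir, sprintf("chain%02d.tsv", ch))
    utils::write.table(df, paths[ch], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

# effective sample size from the initial-positive autocorrelation sum
ess_trace <- function(x) {
  n <- length(x)
  if (n < 3L || stats::var(x) == 0) return(n)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  rho_sum <- 0
  for (k in seq_len(n - 2L)) {
    rho <- sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
    if (rho < 0) break
    rho_sum <- rho_sum + rho
  }
  max(1, n / (1 + 2 * rho_sum))
}

#' Across-chain convergence diagnostics
#'
#' Per migration parameter: pooled mean and SD, effective sample size
#' (initial-positive autocorrelation-sum estimator, summed over chains)
#' and the between/within-chain variance ratio
#' `sqrt(((n-1)/n * W + B/n) / W)` (the usual potential-scale-reduction
#' statistic). Parameters with ratio above `flag_above` are flagged.
#'
#' @param post A `migration_posterior` with at least 2 chains.
#' @param flag_above Ratio threshold for the `flagged` column.
#' @return Data frame with one row per ordered population pair.
#' @export
convergence_report <- function(post, flag_above = 1.1) {
  stopifnot(length(post$chains) >= 2L)
  P <- length(post$pops)
  rows <- list()
  for (l in seq_len(P)) for (q in seq_len(P)) {
    col <- (l - 1L) * P + q
    per_chain <- lapply(post$chains, function(tr) tr$m_samples[, col])
    n <- length(per_chain[[1]])
    mns <- vapply(per_chain, mean, 0)
    vars <- vapply(per_chain, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(mns)
    ratio <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else 1
    pooled <- unlist(per_chain)
    rows[[length(rows) + 1L]] <- data.frame(
      into = post$pops[l], from = post$pops[q],
      mean = mean(pooled), sd = stats::sd(pooled),
      ess = sum(vapply(per_chain, ess_trace, 0)),
      psrf = ratio, flagged = ratio > flag_above)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
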