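# Fixture builders and independent oracles shared across test files.

# genotype array from a character matrix of "a/b" calls ("." = missing)
geno_array <- function(calls) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  g <- array(NA_integer_, c(n, L, 2L))
  for (i in seq_len(n)) for (j in seq_len(L)) {
    if (calls[i, j] == ".") next
    ab <- as.integer(strsplit(calls[i, j], "/", fixed = TRUE)[[1]])
    g[i, j, ] <- ab
  }
  g
}

make_pop <- function(id, calls) {
  population_sample(id, id, geno_array(calls))
}

make_ds <- function(species, loci, pops) {
  genotype_dataset(species, loci, pops)
}

# two-population, two-locus deterministic fixture
toy_two_pop <- function() {
  p1 <- make_pop("P1", rbind(c("1/2", "100/104"), c("1/1", "100/100"),
                             c("2/2", "104/104"), c("1/2", "100/104"),
                             c("1/1", "100/104")))
  p2 <- make_pop("P2", rbind(c("2/3", "104/108"), c("3/3", "108/108"),
                             c("2/2", "104/104"), c("2/3", "104/108"),
                             c("3/3", "104/108")))
  make_ds("toy", c("locA", "locB"), list(p1, p2))
}

# Independent Weir & Cockerham (1984) theta: literal per-allele loop
# transcription of the published variance components, separate from the
# package's vectorised implementation. groups: list of n x 2 matrices.
oracle_wc_theta <- function(groups) {
  r <- length(groups)
  alleles <- sort(unique(unlist(groups)))
  n_i <- vapply(groups, nrow, 0L)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (g in seq_len(r)) {
      m <- groups[[g]]
      p_i[g] <- sum(m == al) / (2 * n_i[g])
      h_i[g] <- sum(xor(m[, 1] == al, m[, 2] == al)) / n_i[g]
    }
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# independent allele-size variance-component rho via stats::aov
oracle_rho_aov <- function(groups) {
  sizes <- unlist(groups)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  ms <- anova(stats::aov(sizes ~ grp))[["Mean Sq"]]
  n_i <- lengths(groups)
  N <- sum(n_i)
  n0 <- (N - sum(n_i^2) / N) / (length(groups) - 1)
  s2a <- (ms[1] - ms[2]) / n0
  s2a / (s2a + ms[2])
}

# from-scratch Welch t and Welch-Satterthwaite df
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, df = df)
}
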