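test_that("EM finds no null alleles in Hardy-Weinberg-exact counts", {
  # p = 0.5, n = 100: 25 AA, 50 AB, 25 BB, no missing
  calls <- c(rep("1/1", 25), rep("1/2", 50), rep("2/2", 25))
  ds <- make_ds("t", "locA", list(make_pop("P1", cbind(calls))))
  nf <- estimate_null_freq(ds)
  expect_lt(nf$null_freq[1, 1], 1e-3)
  expect_true(nf$converged[1, 1])
})

test_that("EM recovers a planted null-allele frequency at n = 500", {
  cfg <- sim_config(pop_labels = "A", n_individuals = 500, n_loci = 3,
                    n_alleles = 6, dirichlet_alpha = 1,
                    theta_divergence = 0, selfing_F = 0, null_rate = 0.2,
                    missing_rate = 0, species = "t", seed = 55)
  ds <- simulate_dataset(cfg)$dataset
  nf <- estimate_null_freq(ds)
  expect_lt(max(abs(nf$null_freq[1, ] - 0.2)), 0.05)
})

test_that("an all-missing locus is the flagged degenerate boundary", {
  p <- make_pop("P1", rbind(c("1/2", "."), c("1/1", "."), c("2/2", ".")))
  nf <- estimate_null_freq(make_ds("t", c("l1", "l2"), list(p)))
  expect_equal(nf$null_freq[1, 2], 1)
  expect_false(nf$converged[1, 2])
})

test_that("ENA and uncorrected F_ST coincide when no null mass is found", {
  # heterozygote-only genotypes drive the null estimate to exactly zero
  pa <- make_pop("A", cbind(c(rep("1/2", 6), rep("1/3", 4))))
  pb <- make_pop("B", cbind(c(rep("2/3", 7), rep("1/2", 3))))
  ds <- make_ds("t", "locA", list(pa, pb))
  nf <- estimate_null_freq(ds)
  expect_lt(max(nf$null_freq), 1e-6)
  f <- fst_ena(ds, nf)
  expect_lt(abs(f$global$fst_ena - f$global$fst_raw), 1e-9)
})

test_that("Weir-Cockerham theta matches an independent transcription", {
  sim <- simulate_dataset(sim_config(
    pop_labels = c("A", "B", "C"), n_individuals = c(8, 12, 10),
    n_loci = 4, n_alleles = 5, dirichlet_alpha = 1,
    theta_divergence = 0.1, selfing_F = 0.2, null_rate = 0,
    missing_rate = 0, species = "t", seed = 13))
  ds <- sim$dataset
  f <- fst_ena(ds, pairs = rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  for (k in seq_len(nrow(f$global))) {
    id1 <- f$global$pop1[k]; id2 <- f$global$pop2[k]
    num <- den <- 0
    for (j in seq_along(ds$loci)) {
      g1 <- coevmosaic:::genotype_rows_at(ds$populations[[id1]], j)
      g2 <- coevmosaic:::genotype_rows_at(ds$populations[[id2]], j)
      # oracle per locus, accumulated as a ratio of sums
      r <- length(unique(c(g1, g2)))
      th <- oracle_wc_theta(list(g1, g2))
      pl <- f$per_locus[f$per_locus$pop1 == id1 &
                          f$per_locus$pop2 == id2, ]
      expect_lt(abs(pl$fst_raw[j] - th), 1e-10)
    }
  }
  # three-population variance components against the same oracle
  gs <- lapply(ds$populations, coevmosaic:::genotype_rows_at, 1)
  stats3 <- lapply(ds$populations, coevmosaic:::wc_pop_stats, 1)
  cmp <- coevmosaic:::wc_components(
    stats3, sort(unique(unlist(lapply(stats3, function(z) names(z$p)))))
  )
  expect_lt(abs(sum(cmp[, "a"]) / sum(cmp) - oracle_wc_theta(gs)), 1e-10)
})

test_that("degenerate differentiation endpoints are exact", {
  # disjoint monomorphic populations
  pa <- make_pop("A", cbind(rep("1/1", 8)))
  pb <- make_pop("B", cbind(rep("2/2", 8)))
  f <- fst_ena(make_ds("t", "locA", list(pa, pb)))
  expect_equal(f$global$fst_raw, 1)
  # identically sourced populations at n = 200: near zero
  cfg <- sim_config(pop_labels = c("A", "B"), n_individuals = 200,
                    n_loci = 15, n_alleles = 5, dirichlet_alpha = 1,
                    theta_divergence = 0, selfing_F = 0, null_rate = 0,
                    missing_rate = 0, species = "t", seed = 17)
  f0 <- fst_ena(simulate_dataset(cfg)$dataset)
  expect_lt(abs(f0$global$fst_raw), 0.01)
})

test_that("F_ST ignores allele sizes while Rho_ST uses them", {
  sim <- simulate_dataset(sim_config(
    pop_labels = c("A", "B"), n_individuals = 30, n_loci = 5,
    n_alleles = 4, dirichlet_alpha = 1, theta_divergence = 0.1,
    selfing_F = 0, null_rate = 0, missing_rate = 0, species = "t",
    seed = 23))
  ds <- sim$dataset
  f1 <- fst_ena(ds); r1 <- rho_st(ds)
  # scrambled size labels: identity map is permuted per locus
  scram <- ds
  set.seed(99)
  for (j in seq_along(ds$loci)) {
    sizes <- sort(unique(unlist(lapply(ds$populations,
                                       function(p) p$genotypes[, j, ]))))
    new <- sample(1000:2000, length(sizes))
    for (id in pop_ids(scram)) {
      g <- scram$populations[[id]]$genotypes
      g[, j, ] <- new[match(g[, j, ], sizes)]
      scram$populations[[id]]$genotypes <- g
    }
  }
  f2 <- fst_ena(scram); r2 <- rho_st(scram)
  expect_equal(f1$global$fst_raw, f2$global$fst_raw, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r1$global$rho_st, r2$global$rho_st)))
  # affine size shifts leave Rho_ST unchanged
  aff <- ds
  for (id in pop_ids(aff)) {
    g <- aff$populations[[id]]$genotypes
    aff$populations[[id]]$genotypes <-
      array(ifelse(is.na(g), NA_integer_, 3L * g + 7L), dim(g))
  }
  r3 <- rho_st(aff)
  expect_equal(r1$global$rho_st, r3$global$rho_st, tolerance = 1e-12)
})

test_that("Rho_ST matches an aov-based variance-component oracle", {
  sim <- simulate_dataset(sim_config(
    pop_labels = c("A", "B"), n_individuals = c(9, 14), n_loci = 3,
    n_alleles = 6, dirichlet_alpha = 1, theta_divergence = 0.15,
    selfing_F = 0, null_rate = 0, missing_rate = 0, species = "t",
    seed = 29))
  ds <- sim$dataset
  r <- rho_st(ds)
  for (j in seq_along(ds$loci)) {
    groups <- lapply(ds$populations, coevmosaic:::alleles_at, j)
    expect_lt(abs(r$per_locus$rho_st[j] - oracle_rho_aov(groups)), 1e-10)
  }
})

test_that("Rho_ST exceeds F_ST when divergence is in size, not identity", {
  # both pops use alleles {100, 104, 140} at similar identity frequencies
  pa <- make_pop("A", cbind(c(rep("100/104", 8), rep("100/140", 2))))
  pb <- make_pop("B", cbind(c(rep("100/140", 8), rep("100/104", 2))))
  ds <- make_ds("t", "locA", list(pa, pb))
  f <- fst_ena(ds); r <- rho_st(ds)
  expect_gt(r$global$rho_st, f$global$fst_raw)
})

test_that("island-model simulations recover the drift parameter", {
  for (theta in c(0.01, 0.05, 0.15)) {
    ests <- vapply(1:100, function(s) {
      cfg <- sim_config(pop_labels = c("A", "B"), n_individuals = 40,
                        n_loci = 10, n_alleles = 8, dirichlet_alpha = 1,
                        theta_divergence = theta, selfing_F = 0,
                        null_rate = 0, missing_rate = 0, species = "t",
                        seed = 7000 + s + round(theta * 1e4))
      fst_ena(simulate_dataset(cfg)$dataset)$global$fst_raw
    }, 0)
    expect_lt(abs(mean(ests) - theta), 0.2 * theta)
  }
})
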