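test_that("complete enumeration reproduces hand-computed exact p-values", {
  # AA=1, AB=2, BB=1: the most probable table given 4A/4B, so p = 1
  g <- rbind(c(1, 1), c(1, 2), c(1, 2), c(2, 2))
  expect_equal(coevmosaic:::hwe_enumerate(g), 1.0)
  # all heterozygotes, n = 4 (4A/4B): p(only tables at least as extreme)
  # computed from the closed-form conditional probabilities:
  # P(0,4,0) = 0.2286, P(2,0,2) = 0.0857, P(1,2,1) = 0.6857
  gh <- rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2))
  expect_equal(coevmosaic:::hwe_enumerate(gh), 0.2286 + 0.0857,
               tolerance = 1e-3)
})

test_that("a strong heterozygote excess is detected by the chain", {
  p <- make_pop("P1", cbind(rep("1/2", 50)))
  ds <- make_ds("t", "locA", list(p))
  res <- hwe_exact(ds, chain = list(dememorization = 2000, batches = 20,
                                    iterations = 1000), seed = 1)
  expect_lt(res$per_locus$p, 0.01)
  expect_equal(res$per_locus$method, "chain")
})

test_that("chain p-values agree with enumeration within Monte-Carlo error", {
  set.seed(42)
  alle <- sample(rep(c(1, 1, 1, 2), 10))       # 30 A / 10 B over n = 20
  g <- matrix(alle, ncol = 2)
  p_exact <- coevmosaic:::hwe_enumerate(g)
  ds <- make_ds("t", "locA",
                list(population_sample("P1", genotypes =
                       array(c(g[, 1], g[, 2]), c(nrow(g), 1, 2)))))
  res <- hwe_exact(ds, chain = list(dememorization = 5000, batches = 20,
                                    iterations = 2000),
                   enum_max_tables = 1, seed = 7)
  expect_equal(res$per_locus$method, "chain")
  expect_lt(abs(res$per_locus$p - p_exact),
            3 * res$per_locus$se + 1e-6)
})

test_that("Fisher combination follows its closed form and zero rule", {
  fc <- fisher_combine(rep(1, 10))
  expect_equal(fc$statistic, 0)
  expect_equal(fc$df, 20L)
  expect_equal(fc$p_value, 1)
  fz <- fisher_combine(c(0.5, 0, 0.2), chain_length = 1e5)
  expect_identical(fz$statistic, Inf)
  expect_equal(fz$p_label, "< 1e-05")
  # monotone: lowering any component p raises the statistic
  set.seed(1)
  for (k in 1:20) {
    p <- runif(6)
    i <- sample(6, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    expect_gt(fisher_combine(p2)$statistic, fisher_combine(p)$statistic)
  }
})

test_that("exact HWE test holds its nominal size under the null", {
  pvals <- vapply(1:300, function(s) {
    set.seed(4000 + s)
    a <- sample(c(rep(1L, 22), rep(2L, 18)))   # random HW pairing, n = 20
    g <- matrix(a, ncol = 2)
    coevmosaic:::hwe_enumerate(g)
  }, 0)
  rate <- mean(pvals <= 0.05)
  # exact conditional tests are valid (often conservative)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("a duplicated locus shows extreme linkage disequilibrium", {
  set.seed(3)
  calls <- replicate(30, paste(sort(sample(1:4, 2, TRUE)), collapse = "/"))
  p <- make_pop("P1", cbind(calls, calls))
  ds <- make_ds("t", c("l1", "l2"), list(p))
  res <- ld_exact(ds, n_perm = 500, seed = 2)
  expect_lt(res$combined$p_value, 0.01)
  expect_equal(res$n_pairs, 1L)
})

test_that("independent loci give calibrated LD p-values", {
  pvals <- vapply(1:150, function(s) {
    cfg <- sim_config(pop_labels = "A", n_individuals = 30, n_loci = 2,
                      n_alleles = 4, dirichlet_alpha = 1,
                      theta_divergence = 0, selfing_F = 0, null_rate = 0,
                      missing_rate = 0, species = "t", seed = 5000 + s)
    ds <- simulate_dataset(cfg)$dataset
    ld_exact(ds, n_perm = 300, seed = s)$per_pop$p
  }, 0)
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
})

test_that("locus-pair counts and Bonferroni thresholds follow the design", {
  ds15 <- simulate_dataset(sim_config_parasitoid(seed = 1))$dataset
  ds12 <- simulate_dataset(sim_config_aphid(seed = 1))$dataset
  expect_equal(choose(length(ds15$loci), 2), 105)
  expect_equal(choose(length(ds12$loci), 2), 66)
  g <- genic_differentiation_exact(ds15, n_tables = 200, seed = 1)
  expect_equal(g$n_pairs, 10L)
  expect_equal(g$bonferroni_alpha, 0.005)
})

test_that("genic differentiation separates identical from fixed pops", {
  # identical source frequencies: combined p should not be extreme
  cfg <- sim_config(pop_labels = c("A", "B"), n_individuals = 50,
                    n_loci = 6, n_alleles = 4, dirichlet_alpha = 1,
                    theta_divergence = 0, selfing_F = 0, null_rate = 0,
                    missing_rate = 0, species = "t", seed = 31)
  ds <- simulate_dataset(cfg)$dataset
  res <- genic_differentiation_exact(ds, n_tables = 1000, seed = 4)
  expect_gt(res$combined$p, 0.001)
  # fixed difference: below Monte-Carlo resolution
  pa <- make_pop("A", cbind(rep("1/1", 10)))
  pb <- make_pop("B", cbind(rep("2/2", 10)))
  dsf <- make_ds("t", "locA", list(pa, pb))
  resf <- genic_differentiation_exact(dsf, n_tables = 2000, seed = 4)
  expect_lt(resf$per_locus$p, 0.01)
})
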