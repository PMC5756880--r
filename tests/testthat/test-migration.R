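test_that("a single population has the degenerate posterior", {
  sim <- simulate_dataset(sim_config(pop_labels = "A",
                                     n_individuals = 15, n_loci = 4,
                                     species = "t", seed = 1))
  post <- run_migration_mcmc(sim$dataset, n_gen = 2000, burn_in = 500,
                             thin = 10, n_chains = 1, seed = 1)
  expect_equal(unname(post$mean[1, 1]), 1)
  expect_equal(unname(post$sd[1, 1]), 0)
  expect_false(any(post$significant))
})

test_that("with the likelihood disabled the sampler recovers the prior", {
  sim <- simulate_dataset(sim_config(pop_labels = c("A", "B", "C"),
                                     n_individuals = 8, n_loci = 3,
                                     species = "t", seed = 2))
  post <- run_migration_mcmc(sim$dataset, n_gen = 120000, burn_in = 20000,
                             thin = 20, n_chains = 2, seed = 3,
                             prior_only = TRUE)
  # uniform over each row's constrained simplex: E[m_lq] = (1/3)/P for
  # q != l, E[m_ll] = 1 - (P-1)/(3P); F uniform on [0, 0.999]
  off <- post$mean[row(post$mean) != col(post$mean)]
  expect_lt(max(abs(off - 1 / 9)), 0.012)
  expect_lt(max(abs(diag(post$mean) - 7 / 9)), 0.02)
  Fs <- do.call(rbind, lapply(post$chains, `[[`, "F_samples"))
  expect_lt(max(abs(colMeans(Fs) - 0.4995)), 0.025)
})

test_that("planted first-generation migrants are recovered", {
  m <- matrix(c(0.8, 0.2, 0, 1), 2, 2, byrow = TRUE)
  cfg <- sim_config(pop_labels = c("A", "B"), n_individuals = 50,
                    n_loci = 10, n_alleles = 6, dirichlet_alpha = 1,
                    theta_divergence = 0.2, selfing_F = 0, null_rate = 0,
                    missing_rate = 0, migration_truth = m, species = "t",
                    seed = 101)
  sim <- simulate_dataset(cfg)
  post <- suppressWarnings(
    run_migration_mcmc(sim$dataset, n_gen = 100000, burn_in = 20000,
                       thin = 50, n_chains = 2, seed = 11))
  est <- post$mean["A", "B"]
  expect_true(est - 1.96 * post$sd["A", "B"] <= 0.2 &&
                0.2 <= est + 1.96 * post$sd["A", "B"])
  expect_true(post$significant["A", "B"])
})

test_that("unstructured data produce no significant migration calls", {
  cfg <- sim_config(pop_labels = c("A", "B", "C"), n_individuals = 25,
                    n_loci = 10, n_alleles = 6, dirichlet_alpha = 1,
                    theta_divergence = 0.1, selfing_F = 0, null_rate = 0,
                    missing_rate = 0, species = "t", seed = 303)
  sim <- simulate_dataset(cfg)
  post <- suppressWarnings(
    run_migration_mcmc(sim$dataset, n_gen = 100000, burn_in = 20000,
                       thin = 50, n_chains = 2, seed = 13))
  expect_false(any(post$significant))
  expect_true(all(post$mean[row(post$mean) != col(post$mean)] <= 1 / 3))
})

test_that("the log-likelihood trace is trend-free after burn-in", {
  cfg <- sim_config(pop_labels = c("A", "B"), n_individuals = 20,
                    n_loci = 6, n_alleles = 4, dirichlet_alpha = 1,
                    theta_divergence = 0.1, species = "t", seed = 5)
  sim <- simulate_dataset(cfg)
  post <- suppressWarnings(
    run_migration_mcmc(sim$dataset, n_gen = 150000, burn_in = 30000,
                       thin = 50, n_chains = 1, seed = 21))
  ll <- post$chains[[1]]$loglik
  bm <- tapply(ll, cut(seq_along(ll), 10), mean)   # batch means
  fit <- summary(lm(bm ~ seq_along(bm)))
  expect_gt(fit$coefficients[2, 4], 0.01)
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  fake_post <- function(traces) {
    structure(list(chains = lapply(traces, function(x)
      list(m_samples = cbind(x), F_samples = cbind(rep(0.1, length(x))))),
      pops = "A"), class = "migration_posterior")
  }
  set.seed(6)
  x <- runif(500)
  same <- convergence_report(fake_post(list(x, x)))
  # identical chains: B = 0, ratio = sqrt((n-1)/n)
  expect_equal(same$psrf, sqrt(499 / 500), tolerance = 1e-12)
  expect_false(same$flagged)
  shifted <- convergence_report(fake_post(list(x, x + 2)))
  expect_true(shifted$flagged)
})

test_that("effective sample size matches an acf-based oracle", {
  set.seed(9)
  x <- as.numeric(arima.sim(list(ar = 0.7), n = 2000))
  ess <- coevmosaic:::ess_trace(x)
  rho <- acf(x, lag.max = length(x) - 2, plot = FALSE)$acf[-1]
  upto <- which(rho < 0)[1] - 1
  oracle <- length(x) / (1 + 2 * sum(rho[seq_len(upto)]))
  expect_equal(ess, oracle, tolerance = 0.02)
  # iid white noise: ESS close to n
  expect_gt(coevmosaic:::ess_trace(rnorm(1000)), 500)
})

test_that("trace files round-trip through plain text", {
  sim <- simulate_dataset(sim_config(pop_labels = c("A", "B"),
                                     n_individuals = 10, n_loci = 3,
                                     species = "t", seed = 4))
  post <- suppressWarnings(
    run_migration_mcmc(sim$dataset, n_gen = 4000, burn_in = 1000,
                       thin = 10, n_chains = 2, seed = 2))
  d <- withr::local_tempdir()
  paths <- write_traces(post, d)
  expect_length(paths, 2L)
  tr <- read.delim(paths[1])
  expect_true(all(c("state", "loglik", "m_A.B", "F_A") %in% names(tr)))
  expect_equal(nrow(tr), nrow(post$chains[[1]]$m_samples))
})
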