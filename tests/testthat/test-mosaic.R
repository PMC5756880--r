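test_that("Tukey fences flag hand-computed outliers", {
  tf <- tukey_fence_outliers(c(a = 1, b = 2, c = 3, d = 4, e = 100))
  # hinges 2 and 4, IQR 2, fences at -1 and 7
  expect_equal(tf$lower, -1)
  expect_equal(tf$upper, 7)
  expect_equal(tf$outliers, "e")
  expect_equal(tf$tails, "high")

  none <- tukey_fence_outliers(rep(0.3, 6))
  expect_length(none$outliers, 0L)
  one_off <- tukey_fence_outliers(c(rep(0.3, 5), 0.31))
  expect_equal(one_off$outliers, "6")

  with_na <- tukey_fence_outliers(c(1, 2, NA, 3, 4, 100))
  expect_equal(with_na$outliers, "6")
  expect_warning(tukey_fence_outliers(c(1, 2, 3)), "fewer than 4")
})

test_that("outlier calls are invariant under constant shifts", {
  set.seed(12)
  v <- c(rnorm(12, 0.05, 0.02), 0.6)
  t1 <- tukey_fence_outliers(v)
  t2 <- tukey_fence_outliers(v + 7)
  expect_equal(t1$outliers, t2$outliers)
})

test_that("divergence from an identical reference is near zero", {
  sim <- simulate_dataset(sim_config(pop_labels = "A", n_individuals = 30,
                                     n_loci = 8, n_alleles = 5,
                                     dirichlet_alpha = 1, null_rate = 0,
                                     missing_rate = 0, species = "t",
                                     seed = 41))
  p <- sim$dataset$populations[[1]]
  twin <- population_sample("A2", "A2", p$genotypes)
  ds <- genotype_dataset("t", sim$dataset$loci, list(p, twin))
  div <- locus_specific_divergence(ds, reference_pop = "A")
  expect_lt(max(abs(div$fst_raw)), 0.05)
})

test_that("a planted hotspot locus breaches the location's upper fence", {
  cfg <- sim_config_parasitoid(
    seed = 61, hotspot_loci = data.frame(locus = 5, pop = "Escalon"))
  sim <- simulate_dataset(cfg)
  div <- locus_specific_divergence(sim$dataset, "Yuba City")
  rep <- screen_outliers(div)
  expect_true(sim$dataset$loci[5] %in% rep$outliers[["Escalon"]])
})

test_that("classification requires outliers in both species", {
  mk_report <- function(ref, outl) {
    structure(list(outliers = outl,
                   fences = NULL, metric = "fst_ena", reference = ref,
                   species = "x"), class = "mosaic_species_report")
  }
  co <- c("L1", "L2", "L3")
  empty <- list(L1 = character(0), L2 = character(0), L3 = character(0))
  both_cold <- classify_locations(mk_report("RH", empty),
                                  mk_report("RP", empty), co)
  expect_true(all(both_cold$classification[both_cold$location %in% co] ==
                    "candidate_cold_spot"))
  expect_setequal(
    both_cold$location[both_cold$classification == "reference_cold_spot"],
    c("RH", "RP"))

  h <- empty; h$L2 <- "locX"
  p <- empty; p$L2 <- "locY"; p$L3 <- "locZ"
  mixed <- classify_locations(mk_report("RH", h), mk_report("RP", p), co)
  expect_equal(mixed$classification[mixed$location == "L2"],
               "candidate_hot_spot")
  expect_equal(mixed$classification[mixed$location == "L3"],
               "candidate_cold_spot")
  # symmetric in which species is called host
  sw <- classify_locations(mk_report("RP", p), mk_report("RH", h), co)
  expect_equal(sw$classification[match(co, sw$location)],
               mixed$classification[match(co, mixed$location)])
})

test_that("reciprocally planted hotspots mark exactly one location hot", {
  hot <- data.frame(locus = 4, pop = "Newark")
  pair <- simulate_pair(
    sim_config_aphid(seed = 71, hotspot_loci = hot),
    sim_config_parasitoid(seed = 72, hotspot_loci = hot))
  div_h <- locus_specific_divergence(pair$host, "Linden")
  div_p <- locus_specific_divergence(pair$parasitoid, "Yuba City")
  cls <- classify_locations(screen_outliers(div_h), screen_outliers(div_p),
                            pair$co_sampled)
  hot_locs <- cls$location[cls$classification == "candidate_hot_spot"]
  expect_equal(hot_locs, "Newark")
})

test_that("the permutation test matches exhaustive label enumeration", {
  pa <- make_pop("A", cbind(c("1/2", "1/1", "2/2")))
  pb <- make_pop("B", cbind(c("2/3", "3/3", "2/3")))
  ds <- make_ds("t", "locA", list(pa, pb))
  res <- outlier_permutation_test(ds, "A", "B", "locA", n_perm = 4000,
                                  seed = 3)
  # oracle: all choose(6, 3) assignments of individuals to group A
  pool <- rbind(geno_array(cbind(c("1/2", "1/1", "2/2")))[, 1, ],
                geno_array(cbind(c("2/3", "3/3", "2/3")))[, 1, ])
  combos <- combn(6, 3)
  fsts <- apply(combos, 2, function(idx)
    coevmosaic:::fst_locus_two_groups(pool[idx, , drop = FALSE],
                                      pool[-idx, , drop = FALSE]))
  exact_p <- mean(fsts >= res$observed - 1e-12)
  se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(res$p - exact_p), 3 * se + 2 / 4000)
})

test_that("permutation p-values hit the resolution floor on fixed splits", {
  pa <- make_pop("A", cbind(rep("100/100", 8)))
  pb <- make_pop("B", cbind(rep("104/104", 8)))
  ds <- make_ds("t", "locA", list(pa, pb))
  res <- outlier_permutation_test(ds, "A", "B", "locA", n_perm = 500,
                                  seed = 1)
  expect_equal(res$observed, 1)
  expect_lte(res$p, 2 / 501)
  expect_error(outlier_permutation_test(ds, "A", "B", "locA", n_perm = 50),
               "at least 100")
})

test_that("the Welch G_IS comparison reproduces published arithmetic", {
  aphid <- data.frame(gis = c(0.143, 0.444, 0.089, -0.048, 0.043))
  parasitoid <- data.frame(gis = c(0.448, 0.210, 0.211, 0.245, 0.107))
  w <- compare_species_gis(aphid, parasitoid)
  expect_equal(round(w$t, 2), -1.09)
  expect_equal(round(w$df, 2), 6.99)
  expect_equal(round(w$p, 2), 0.31)
  # identical vectors: t = 0
  same <- compare_species_gis(parasitoid, parasitoid)
  expect_equal(same$t, 0)
  # from-scratch Welch formula on random vectors
  set.seed(8)
  for (k in 1:10) {
    x <- rnorm(5); y <- rnorm(7)
    w2 <- compare_species_gis(data.frame(gis = x), data.frame(gis = y))
    o <- oracle_welch(x, y)
    expect_equal(w2$t, unname(o["t"]), tolerance = 1e-12)
    expect_equal(w2$df, unname(o["df"]), tolerance = 1e-12)
  }
})

test_that("divergence boxplots render to a file", {
  sim <- simulate_dataset(sim_config_aphid(seed = 81))
  div <- locus_specific_divergence(sim$dataset, "Linden")
  f <- withr::local_tempfile(fileext = ".pdf")
  bp <- plot_mosaic_divergence(div, file = f)
  expect_true(file.exists(f))
  expect_equal(length(bp$names), length(unique(div$location)))
})
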