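#' Configuration for the two-species microsatellite simulator
#'
#' Describes one species' sampling design and latent population-genetic
#' structure. Defaults (together with [sim_config_parasitoid()] and
#' [sim_config_aphid()]) emulate a five-orchard host--parasitoid survey:
#' 7--14 genotyped diploid females per location, microsatellite allele
#' ladders, low heterozygosity, per-population inbreeding, island-model
#' divergence, null alleles and occasional dropout.
#'
#' @param pop_labels Character vector of location labels (also population
#'   ids). Co-sampled locations of a species pair must share labels.
#' @param n_individuals Per-population sample sizes (recycled if scalar).
#' @param n_loci Number of microsatellite loci.
#' @param n_alleles Visible alleles per locus (recycled).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for ancestral
#'   allele frequencies; smaller values give more skewed frequencies and
#'   lower heterozygosity.
#' @param theta_divergence Target Weir F_ST level: per-population drift
#'   parameter of the Balding--Nichols kernel, in `[0, 1)`. Recycled over
#'   populations.
#' @param selfing_F Per-population inbreeding coefficient in `[0, 1)`
#'   (recycled): genotypes are drawn with
#'   `P(hom a) = F p_a + (1-F) p_a^2`, `P(het ab) = (1-F) 2 p_a p_b`.
#' @param null_rate Per-locus null-allele frequency in `[0, 0.5]`
#'   (recycled). A null/visible heterozygote is recorded as a visible
#'   homozygote; a null/null homozygote is recorded as missing.
#' @param missing_rate Probability that a genotype drops out for reasons
#'   unrelated to null alleles (recorded as missing).
#' @param clone_rate Probability an individual duplicates an existing
#'   individual's genotype (cyclically parthenogenetic aphid mode); 0 for
#'   sexual species.
#' @param hotspot_loci `NULL`, or a data frame with columns `locus`
#'   (index) and `pop` (label): loci given inflated divergence at the
#'   designated locations by a selective-sweep-style shift — the
#'   ancestrally rarest allele rises to frequency `hotspot_sweep_freq`
#'   in that population (local adaptation at a hot spot), instead of
#'   the neutral drift kernel.
#' @param hotspot_sweep_freq Post-sweep frequency of the locally
#'   favoured allele at hotspot locus/location combinations.
#' @param migration_truth `NULL`, or a row-stochastic matrix `m` over
#'   `pop_labels` with `m[l, q]` the fraction of population `l` planted
#'   as recent migrants from `q`; off-diagonal row sums must be at most
#'   1/3 (the migration model's support constraint).
#' @param migrant_generation Generation of planted migrants: 1 (genotype
#'   drawn wholly from the source) or 2 (one parental gamete from each
#'   population).
#' @param species Species label written into the dataset.
#' @param seed RNG seed used by [simulate_dataset()] for this species.
#' @return A `sim_config` list with validated fields.
#' @export
sim_config <- function(pop_labels = c("Arbuckle", "Upper Lake", "Escalon",
                                      "Newark", "Yuba City"),
                       n_individuals = c(14, 13, 12, 10, 7),
                       n_loci = 15, n_alleles = 4,
                       dirichlet_alpha = 0.27,
                       theta_divergence = 0.03,
                       selfing_F = 0.24,
                       null_rate = 0.05,
                       missing_rate = 0.02,
                       clone_rate = 0,
                       hotspot_loci = NULL,
                       hotspot_sweep_freq = 0.9,
                       migration_truth = NULL,
                       migrant_generation = 1,
                       species = "species",
                       seed = 1L) {
  P <- length(pop_labels)
  if (anyDuplicated(pop_labels)) stop("pop_labels must be unique")
  n_individuals <- rep_len(n_individuals, P)
  theta_divergence <- rep_len(theta_divergence, P)
  selfing_F <- rep_len(selfing_F, P)
  n_alleles <- rep_len(n_alleles, n_loci)
  null_rate <- rep_len(null_rate, n_loci)
  if (any(n_individuals < 1)) stop("n_individuals must be >= 1")
  if (any(theta_divergence < 0 | theta_divergence >= 1)) {
    stop("theta_divergence must lie in [0, 1)")
  }
  if (any(selfing_F < 0 | selfing_F >= 1)) stop("selfing_F must lie in [0, 1)")
  if (any(null_rate < 0 | null_rate > 0.5)) stop("null_rate must lie in [0, 0.5]")
  if (any(n_alleles < 2 & null_rate > 0)) {
    stop("null_rate > 0 requires at least 2 visible alleles per locus")
  }
  if (clone_rate < 0 || clone_rate >= 1) stop("clone_rate must lie in [0, 1)")
  if (!is.null(hotspot_loci)) {
    hotspot_loci <- as.data.frame(hotspot_loci)
    stopifnot(all(c("locus", "pop") %in% names(hotspot_loci)))
    if (any(hotspot_loci$locus < 1 | hotspot_loci$locus > n_loci)) {
      stop("hotspot locus index out of range")
    }
    if (!all(hotspot_loci$pop %in% pop_labels)) {
      stop("hotspot pop label not among pop_labels")
    }
  }
  if (!is.null(migration_truth)) {
    migration_truth <- as.matrix(migration_truth)
    stopifnot(nrow(migration_truth) == P, ncol(migration_truth) == P)
    if (any(abs(rowSums(migration_truth) - 1) > 1e-8)) {
      stop("migration_truth rows must sum to 1")
    }
    off <- rowSums(migration_truth) - diag(migration_truth)
    if (any(off > 1 / 3 + 1e-12)) {
      stop("off-diagonal migration fractions must sum to at most 1/3 per row")
    }
    dimnames(migration_truth) <- list(pop_labels, pop_labels)
  }
  if (!migrant_generation %in% c(1, 2)) stop("migrant_generation must be 1 or 2")
  structure(list(pop_labels = pop_labels, n_individuals = n_individuals,
                 n_loci = n_loci, n_alleles = n_alleles,
                 dirichlet_alpha = dirichlet_alpha,
                 theta_divergence = theta_divergence, selfing_F = selfing_F,
                 null_rate = null_rate, missing_rate = missing_rate,
                 clone_rate = clone_rate, hotspot_loci = hotspot_loci,
                 hotspot_sweep_freq = hotspot_sweep_freq,
                 migration_truth = migration_truth,
                 migrant_generation = migrant_generation,
                 species = species, seed = as.integer(seed)),
            class = "sim_config")
}

#' Parasitoid-shaped simulator preset (15 loci, moderate diversity)
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_parasitoid <- function(...) {
  defaults <- list(pop_labels = c("Yuba City", "Arbuckle", "Upper Lake",
                                  "Escalon", "Newark"),
                   n_individuals = c(7, 14, 13, 12, 10),
                   n_loci = 15, n_alleles = 4, dirichlet_alpha = 0.27,
                   theta_divergence = 0.03, selfing_F = 0.24,
                   clone_rate = 0, species = "parasitoid", seed = 101L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#' Aphid-shaped simulator preset (12 loci, low diversity, clonal)
#' @param ... Overrides passed to [sim_config()].
#' @export
sim_config_aphid <- function(...) {
  defaults <- list(pop_labels = c("Linden", "Arbuckle", "Upper Lake",
                                  "Escalon", "Newark"),
                   n_individuals = c(7, 12, 9, 9, 12),
                   n_loci = 12, n_alleles = 3, dirichlet_alpha = 0.17,
                   theta_divergence = 0.15, selfing_F = 0.13,
                   clone_rate = 0.1, species = "aphid", seed = 202L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1  # degenerate guard
  x / sum(x)
}

#' Simulate one species' genotype dataset with known truth
#'
#' Ancestral allele frequencies per locus are symmetric-Dirichlet draws;
#' per-population frequencies come from the Balding--Nichols drift kernel
#' `Dirichlet(p_anc (1-c)/c)`, whose expected Weir F_ST equals the drift
#' parameter `c = theta_divergence` exactly. Genotypes are drawn with
#' inbreeding, then null-allele masking, clone duplication, migrant
#' planting and dropout are applied. Allele codes are fragment lengths on
#' a per-locus microsatellite ladder (random offset, motif 2--4 bp).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `dataset` (a [genotype_dataset()]) and
#'   `truth` (a `truth_record` holding every latent quantity).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  P <- length(cfg$pop_labels)
  L <- cfg$n_loci
  loci <- sprintf("%s_L%02d", toupper(substr(cfg$species, 1, 2)), seq_len(L))

  ladders <- vector("list", L)
  anc <- vector("list", L)
  popfreq <- vector("list", L)  # per locus: (k+1) x P matrix, last row null
  for (j in seq_len(L)) {
    k <- cfg$n_alleles[j]
    motif <- sample(2:4, 1)
    offset <- sample(100:260, 1)
    ladders[[j]] <- offset + motif * seq_len(k)
    anc[[j]] <- rdirichlet1(rep(cfg$dirichlet_alpha, k))
    f <- matrix(0, k + 1L, P, dimnames = list(NULL, cfg$pop_labels))
    for (l in seq_len(P)) {
      c_theta <- cfg$theta_divergence[l]
      is_hot <- !is.null(cfg$hotspot_loci) &&
        any(cfg$hotspot_loci$locus == j &
              cfg$hotspot_loci$pop == cfg$pop_labels[l])
      pvis <- if (is_hot) {
        # sweep-style local adaptation: the ancestrally rarest allele
        # is driven to high frequency in the designated population
        fav <- which.min(anc[[j]])
        out <- anc[[j]] * (1 - cfg$hotspot_sweep_freq) /
          max(sum(anc[[j]][-fav]), 1e-12)
        out[fav] <- cfg$hotspot_sweep_freq
        out / sum(out)
      } else if (c_theta <= 0) anc[[j]] else {
        rdirichlet1(anc[[j]] * (1 - c_theta) / c_theta)
      }
      f[, l] <- c(pvis * (1 - cfg$null_rate[j]), cfg$null_rate[j])
    }
    popfreq[[j]] <- f
  }

  draw_genotype <- function(freq, F_coef) {
    # freq over k visible alleles + null (index k+1)
    if (stats::runif(1) < F_coef) {
      a <- sample.int(length(freq), 1, prob = freq)
      c(a, a)
    } else {
      sample.int(length(freq), 2, replace = TRUE, prob = freq)
    }
  }

  migrants <- list()
  clones <- list()
  pops <- vector("list", P)
  for (l in seq_len(P)) {
    n <- cfg$n_individuals[l]
    lat <- array(NA_integer_, dim = c(n, L, 2L))  # latent allele indices
    src <- rep(l, n); gen <- rep(0L, n)
    if (!is.null(cfg$migration_truth)) {
      # plant the stated fractions exactly: round(m[l, q] * n) migrants
      # per source, assigned to randomly chosen individuals
      free <- sample.int(n)
      for (q in setdiff(seq_len(P), l)) {
        k <- round(cfg$migration_truth[l, q] * n)
        if (k > 0L && length(free) >= k) {
          take <- free[seq_len(k)]
          free <- free[-seq_len(k)]
          src[take] <- q
          gen[take] <- cfg$migrant_generation
        }
      }
    }
    for (i in seq_len(n)) {
      if (cfg$clone_rate > 0 && i > 1 && stats::runif(1) < cfg$clone_rate) {
        donor <- sample.int(i - 1L, 1)
        lat[i, , ] <- lat[donor, , ]
        src[i] <- src[donor]; gen[i] <- gen[donor]
        clones[[length(clones) + 1L]] <- data.frame(
          pop = cfg$pop_labels[l], individual = i, donor = donor)
        next
      }
      for (j in seq_len(L)) {
        if (gen[i] == 2L) {
          # one gamete from home, one from source
          a1 <- sample.int(nrow(popfreq[[j]]), 1, prob = popfreq[[j]][, l])
          a2 <- sample.int(nrow(popfreq[[j]]), 1,
                           prob = popfreq[[j]][, src[i]])
          lat[i, j, ] <- c(a1, a2)
        } else {
          fl <- if (gen[i] == 1L) src[i] else l
          lat[i, j, ] <- draw_genotype(popfreq[[j]][, fl],
                                       cfg$selfing_F[fl])
        }
      }
    }
    if (any(gen > 0L)) {
      mig <- which(gen > 0L)
      migrants[[length(migrants) + 1L]] <- data.frame(
        pop = cfg$pop_labels[l], individual = mig,
        source = cfg$pop_labels[src[mig]], generation = gen[mig])
    }
    # emit observed calls: null masking, dropout, ladder coding
    obs <- array(NA_integer_, dim = c(n, L, 2L))
    for (j in seq_len(L)) {
      k <- cfg$n_alleles[j]
      for (i in seq_len(n)) {
        a <- lat[i, j, ]
        is_null <- a == k + 1L
        if (all(is_null) || stats::runif(1) < cfg$missing_rate) next
        if (any(is_null)) a <- rep(a[!is_null][1], 2L)  # apparent homozygote
        obs[i, j, ] <- sort(ladders[[j]][a])
      }
    }
    pops[[l]] <- population_sample(cfg$pop_labels[l], cfg$pop_labels[l], obs)
  }

  ds <- genotype_dataset(cfg$species, loci, pops)
  truth <- structure(list(
    species = cfg$species, config = cfg, loci = loci, ladders = ladders,
    ancestral_freq = anc, pop_freq = popfreq,
    selfing_F = stats::setNames(cfg$selfing_F, cfg$pop_labels),
    theta_divergence = stats::setNames(cfg$theta_divergence, cfg$pop_labels),
    null_rate = stats::setNames(cfg$null_rate, loci),
    hotspot_loci = cfg$hotspot_loci,
    migration_truth = cfg$migration_truth,
    migrants = if (length(migrants)) do.call(rbind, migrants) else
      data.frame(pop = character(), individual = integer(),
                 source = character(), generation = integer()),
    clones = if (length(clones)) do.call(rbind, clones) else
      data.frame(pop = character(), individual = integer(),
                 donor = integer())), class = "truth_record")
  list(dataset = ds, truth = truth)
}

#' Simulate a paired host/parasitoid survey
#'
#' The two configurations must agree on their shared (co-sampled)
#' location labels; each species may add its own extra location (a
#' reference coevolutionary cold spot where the partner is absent).
#'
#' @param cfg_host [sim_config()] for the host (e.g. aphid) species.
#' @param cfg_parasitoid [sim_config()] for the parasitoid species.
#' @return A list with `host`, `parasitoid` (each a [genotype_dataset()]),
#'   `truth` (list of the two `truth_record`s) and `co_sampled` (the
#'   shared location labels).
#' @export
simulate_pair <- function(cfg_host, cfg_parasitoid) {
  co <- intersect(cfg_host$pop_labels, cfg_parasitoid$pop_labels)
  if (length(co) < 2L) {
    stop("host and parasitoid configs share fewer than 2 location labels")
  }
  h <- simulate_dataset(cfg_host)
  p <- simulate_dataset(cfg_parasitoid)
  list(host = h$dataset, parasitoid = p$dataset,
       truth = list(host = h$truth, parasitoid = p$truth),
       co_sampled = co)
}

#' Serialize a truth record as a long-format table
#'
#' One row per latent scalar: per-population drift and inbreeding
#' parameters, per-locus null-allele frequencies, hotspot assignments,
#' planted migrants and clone duplications. Used by parameter-recovery
#' tests and written alongside simulated datasets.
#'
#' @param t A `truth_record` from [simulate_dataset()].
#' @return A data frame with columns `parameter`, `unit`, `value`.
#' @export
truth_report <- function(t) {
  stopifnot(inherits(t, "truth_record"))
  rows <- list(
    data.frame(parameter = "theta_divergence",
               unit = names(t$theta_divergence),
               value = as.character(unname(t$theta_divergence))),
    data.frame(parameter = "selfing_F", unit = names(t$selfing_F),
               value = as.character(unname(t$selfing_F))),
    data.frame(parameter = "null_rate", unit = names(t$null_rate),
               value = as.character(unname(t$null_rate))))
  if (!is.null(t$hotspot_loci) && nrow(t$hotspot_loci)) {
    rows <- c(rows, list(data.frame(
      parameter = "hotspot",
      unit = paste(t$loci[t$hotspot_loci$locus], t$hotspot_loci$pop,
                   sep = "@"),
      value = "theta_boosted")))
  }
  if (nrow(t$migrants)) {
    rows <- c(rows, list(data.frame(
      parameter = "migrant",
      unit = paste0(t$migrants$pop, "#", t$migrants$individual),
      value = paste0(t$migrants$source, ":gen", t$migrants$generation))))
  }
  if (nrow(t$clones)) {
    rows <- c(rows, list(data.frame(
      parameter = "clone",
      unit = paste0(t$clones$pop, "#", t$clones$individual),
      value = paste0("donor", t$clones$donor))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
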