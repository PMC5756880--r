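#' Per-population, per-locus allele counts and effective allele numbers
#'
#' @param ds A [genotype_dataset()].
#' @return Data frame with one row per population x locus: `pop`,
#'   `locus`, `n_typed` (individuals with a genotype), `n_alleles`
#'   (distinct observed alleles) and `eff_num` (`1 / sum(p^2)` over
#'   observed allele frequencies). Loci untyped in a population get
#'   `n_typed = 0` and `NA` statistics; such exclusions are listed in
#'   attribute `"excluded"`.
#' @export
allele_counts <- function(ds) {
  rows <- list()
  for (p in ds$populations) {
    for (j in seq_along(ds$loci)) {
      a <- alleles_at(p, j)
      if (length(a) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pop = p$id, locus = ds$loci[j], n_typed = 0L,
          n_alleles = NA_integer_, eff_num = NA_real_)
      } else {
        pr <- as.vector(table(a)) / length(a)
        rows[[length(rows) + 1L]] <- data.frame(
          pop = p$id, locus = ds$loci[j], n_typed = length(a) %/% 2L,
          n_alleles = length(pr), eff_num = 1 / sum(pr^2))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- out[out$n_typed == 0L, c("pop", "locus")]
  out
}

# per pop x locus components used by diversity and F-statistics
locus_components <- function(pop, locus_index) {
  g <- genotype_rows_at(pop, locus_index)
  n <- nrow(g)
  if (n == 0L) return(NULL)
  a <- c(g[, 1], g[, 2])
  tab <- table(a)
  p <- as.vector(tab) / (2 * n)
  names(p) <- names(tab)
  list(n = n, p = p, ho = mean(g[, 1] != g[, 2]))
}

#' Population diversity and inbreeding summary
#'
#' Per-population means over loci of the number of alleles (`num`), the
#' effective number of alleles (`eff_num`), observed heterozygosity
#' (`ho`), Nei's unbiased within-population gene diversity (`hs`), total
#' heterozygosity (`ht`) and the multilocus inbreeding coefficient
#' `gis = 1 - sum(Ho_l) / sum(Hs_l)` (ratio of locus-summed components,
#' not of rounded means).
#'
#' Per locus within one population, with `n` typed individuals:
#' `Hs = n/(n-1) * (1 - sum(p^2) - Ho/(2n))` (Nei & Chesser's
#' small-sample correction). When a single population is summarised,
#' total heterozygosity equals `hs`, so the per-population report prints
#' `ht = hs`; the pooled rows at the bottom (one per dataset) give the
#' multi-population `Ht` from mean allele frequencies with the analogous
#' correction, using the harmonic mean sample size across populations.
#'
#' @param ds A [genotype_dataset()].
#' @return A `diversity_summary` data frame with one row per population
#'   (`id`, `location`, `n`, `num`, `eff_num`, `ho`, `hs`, `ht`, `gis`)
#'   and attribute `"pooled"` holding the across-population `ho`, `hs`,
#'   `ht` and `gis` for the whole dataset.
#' @export
diversity_summary <- function(ds) {
  L <- length(ds$loci)
  res <- lapply(ds$populations, function(p) {
    num <- eff <- ho <- hs <- rep(NA_real_, L)
    for (j in seq_len(L)) {
      cmp <- locus_components(p, j)
      if (is.null(cmp)) next
      if (cmp$n < 2L) next  # Hs undefined for n < 2
      num[j] <- length(cmp$p)
      eff[j] <- 1 / sum(cmp$p^2)
      ho[j] <- cmp$ho
      hs[j] <- cmp$n / (cmp$n - 1) *
        (1 - sum(cmp$p^2) - cmp$ho / (2 * cmp$n))
    }
    ok <- !is.na(hs)
    gis <- if (sum(hs[ok]) > 0) 1 - sum(ho[ok]) / sum(hs[ok]) else NA_real_
    data.frame(id = p$id, location = p$location,
               n = dim(p$genotypes)[1],
               num = mean(num[ok]), eff_num = mean(eff[ok]),
               ho = mean(ho[ok]), hs = mean(hs[ok]), ht = mean(hs[ok]),
               gis = gis, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "pooled") <- pooled_diversity(ds)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# Nei & Chesser multi-population Ho / Hs / Ht / Gis over all populations
pooled_diversity <- function(ds) {
  L <- length(ds$loci)
  ho_l <- hs_l <- ht_l <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    cmps <- Filter(function(z) !is.null(z) && z$n >= 2L,
                   lapply(ds$populations, locus_components, j))
    r <- length(cmps)
    if (r == 0L) next
    ntilde <- r / sum(1 / vapply(cmps, function(z) z$n, 0))
    ho <- mean(vapply(cmps, function(z) z$ho, 0))
    sumsq <- mean(vapply(cmps, function(z) sum(z$p^2), 0))
    hs <- ntilde / (ntilde - 1) * (1 - sumsq - ho / (2 * ntilde))
    alleles <- sort(unique(unlist(lapply(cmps, function(z) names(z$p)))))
    pbar <- rowMeans(matrix(vapply(cmps, function(z) {
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      v[names(z$p)] <- z$p
      v
    }, numeric(length(alleles))), nrow = length(alleles)))
    ht <- 1 - sum(pbar^2) + hs / (ntilde * r) - ho / (2 * ntilde * r)
    ho_l[j] <- ho; hs_l[j] <- hs; ht_l[j] <- ht
  }
  ok <- !is.na(hs_l)
  c(ho = mean(ho_l[ok]), hs = mean(hs_l[ok]), ht = mean(ht_l[ok]),
    gis = if (sum(hs_l[ok]) > 0) 1 - sum(ho_l[ok]) / sum(hs_l[ok]) else NA)
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num_cols <- vapply(y, is.numeric, TRUE) & names(y) != "n"
  y[num_cols] <- lapply(y[num_cols], round, digits = digits)
  print.data.frame(y, row.names = FALSE, ...)
  p <- attr(x, "pooled")
  if (!is.null(p)) {
    cat("pooled:", paste(names(p), round(p, digits), sep = "=",
                         collapse = "  "), "\n")
  }
  invisible(x)
}
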