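#' Diploid multilocus genotype dataset
#'
#' The universal input container of the package: diploid co-dominant
#' allele calls (microsatellite fragment lengths or repeat counts) for a
#' set of individuals grouped into sampled populations, with a species
#' tag. Allele codes are positive integers; a missing genotype is `NA`
#' in both allele slots (half-missing calls are invalid: co-dominant
#' scoring yields both alleles or neither).
#'
#' @param species Free-text species label.
#' @param loci Character vector of locus names (ordered).
#' @param populations Named list of [population_sample()] objects; names
#'   must equal the population ids and be unique.
#' @return An object of class `genotype_dataset`.
#' @seealso [population_sample()], [read_genepop()], [read_genotypes_csv()]
#' @export
genotype_dataset <- function(species, loci, populations) {
  stopifnot(is.character(species), length(species) == 1L)
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("duplicated locus names")
  if (length(populations) == 0L) stop("dataset needs at least one population")
  ids <- vapply(populations, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("population ids must be unique within a dataset")
  names(populations) <- ids
  for (p in populations) {
    g <- p$genotypes
    if (!is.array(g) || length(dim(g)) != 3L || dim(g)[2] != length(loci) ||
        dim(g)[3] != 2L) {
      stop("population '", p$id, "': genotypes must be an n x ",
           length(loci), " x 2 array")
    }
    half <- xor(is.na(g[, , 1, drop = FALSE]), is.na(g[, , 2, drop = FALSE]))
    if (any(half)) stop("population '", p$id, "': half-missing genotype calls")
    if (any(g[!is.na(g)] <= 0)) stop("allele codes must be positive integers")
  }
  structure(list(species = species, loci = loci, populations = populations),
            class = "genotype_dataset")
}

#' One sampled population of diploid individuals
#'
#' @param id Short population code (e.g. `"J0178"`).
#' @param location Free-text sampling location name.
#' @param genotypes Integer array `n_individuals x n_loci x 2` of allele
#'   codes, `NA` (both slots) for missing genotypes.
#' @param individuals Optional character vector of individual names.
#' @return An object of class `population_sample`.
#' @export
population_sample <- function(id, location = id, genotypes,
                              individuals = NULL) {
  genotypes <- structure(as.integer(round(genotypes)), dim = dim(genotypes))
  n <- dim(genotypes)[1]
  if (n < 1L) stop("population '", id, "' has no individuals")
  if (is.null(individuals)) individuals <- paste0(id, "_", seq_len(n))
  stopifnot(length(individuals) == n)
  structure(list(id = as.character(id), location = as.character(location),
                 genotypes = genotypes, individuals = as.character(individuals)),
            class = "population_sample")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  ns <- vapply(x$populations, function(p) dim(p$genotypes)[1], integer(1))
  cat("<genotype_dataset> species:", x$species, "\n")
  cat("  ", length(x$loci), "loci;", length(x$populations),
      "populations;", sum(ns), "individuals\n")
  for (p in x$populations) {
    cat(sprintf("   %-8s %-12s n=%d\n", p$id, p$location,
                dim(p$genotypes)[1]))
  }
  invisible(x)
}

#' Population ids of a dataset
#' @param ds A [genotype_dataset()].
#' @return Character vector of population ids.
#' @export
pop_ids <- function(ds) names(ds$populations)

#' Location names of a dataset, keyed by population id
#' @param ds A [genotype_dataset()].
#' @return Named character vector (names = population ids).
#' @export
pop_locations <- function(ds) {
  vapply(ds$populations, function(p) p$location, character(1))
}

#' Restrict a dataset to a subset of populations
#' @param ds A [genotype_dataset()].
#' @param ids Population ids to keep, in the order given.
#' @return A [genotype_dataset()] with only the requested populations.
#' @export
subset_pops <- function(ds, ids) {
  miss <- setdiff(ids, pop_ids(ds))
  if (length(miss)) stop("unknown population id(s): ", paste(miss, collapse = ", "))
  genotype_dataset(ds$species, ds$loci, ds$populations[ids])
}

# All allele calls (2 per typed individual) for one pop x locus;
# missing genotypes dropped.
alleles_at <- function(pop, locus_index) {
  a <- c(pop$genotypes[, locus_index, 1], pop$genotypes[, locus_index, 2])
  a[!is.na(a)]
}

# n_ind x 2 allele matrix for one pop x locus, missing rows dropped
genotype_rows_at <- function(pop, locus_index) {
  g <- pop$genotypes[, locus_index, , drop = FALSE]
  dim(g) <- c(dim(g)[1], 2L)
  g[!is.na(g[, 1]), , drop = FALSE]
}

#' Remove repeated identical multilocus genotypes within populations
#'
#' Aphids reproducing by cyclical parthenogenesis can contribute several
#' clonal copies of one genet to a sample; this reduces every set of
#' individuals sharing an identical complete multilocus genotype (missing
#' treated as a distinct state, so two genotypes differing only in
#' missingness are distinct) to a single representative. Deduplication is
#' an explicit opt-in step: field sampling designs usually limit clonal
#' resampling already, so the analysis pipeline leaves it off by default.
#'
#' @param ds A [genotype_dataset()].
#' @return A [genotype_dataset()] with clones collapsed, with attribute
#'   `"removal_log"`: a data frame of `population`, `removed`, `kept`
#'   individual names (one row per removed individual).
#' @export
deduplicate_clones <- function(ds) {
  log_rows <- list()
  pops <- lapply(ds$populations, function(p) {
    g <- p$genotypes
    key <- apply(g, 1, function(row) paste(ifelse(is.na(row), ".", row),
                                           collapse = "|"))
    keep <- !duplicated(key)
    if (any(!keep)) {
      first_of <- match(key[!keep], key)
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        population = p$id,
        removed = p$individuals[!keep],
        kept = p$individuals[first_of],
        stringsAsFactors = FALSE)
    }
    population_sample(p$id, p$location,
                      g[keep, , , drop = FALSE], p$individuals[keep])
  })
  out <- genotype_dataset(ds$species, ds$loci, pops)
  attr(out, "removal_log") <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(population = character(), removed = character(),
               kept = character(), stringsAsFactors = FALSE)
  }
  out
}
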