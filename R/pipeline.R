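#' Configuration for a full two-species analysis run
#'
#' @param host,parasitoid The two species' data: either
#'   [genotype_dataset()] objects or file paths (`.csv` for the CSV
#'   dialect, anything else parsed as GenePop).
#' @param reference_host,reference_parasitoid Population id of each
#'   species' reference cold spot (a location where the partner species
#'   is absent).
#' @param co_sampled Location labels sampled for both species; defaults
#'   to the shared non-reference labels.
#' @param allele_digits GenePop allele width used when reading paths.
#' @param seed Root seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir Output directory for report tables, traces and the
#'   run manifest.
#' @param chain HWE chain parameters (see [hwe_exact()]).
#' @param n_perm Permutations for the LD tests.
#' @param n_tables Monte-Carlo tables for the genic differentiation
#'   tests.
#' @param mcmc List of migration-sampler settings: `n_gen`, `burn_in`,
#'   `mixing`, `thin`, `n_chains`.
#' @param run_migration Set `FALSE` to skip the migration stage.
#' @return A validated `run_config` object.
#' @export
run_config <- function(host, parasitoid, reference_host,
                       reference_parasitoid, co_sampled = NULL,
                       allele_digits = 3, seed = 1L,
                       out_dir = "coevmosaic_out",
                       chain = list(dememorization = 10000, batches = 20,
                                    iterations = 5000),
                       n_perm = 2000, n_tables = 5000,
                       mcmc = list(n_gen = 200000, burn_in = 20000,
                                   mixing = 0.8, thin = 50, n_chains = 4),
                       run_migration = TRUE) {
  load_ds <- function(x, digits) {
    if (inherits(x, "genotype_dataset")) return(x)
    if (grepl("\\.csv$", x, ignore.case = TRUE)) return(read_genotypes_csv(x))
    read_genepop(x, allele_digits = digits)
  }
  host <- load_ds(host, allele_digits)
  parasitoid <- load_ds(parasitoid, allele_digits)
  if (!reference_host %in% pop_ids(host)) {
    stop("reference population '", reference_host,
         "' absent from the host dataset")
  }
  if (!reference_parasitoid %in% pop_ids(parasitoid)) {
    stop("reference population '", reference_parasitoid,
         "' absent from the parasitoid dataset")
  }
  if (is.null(co_sampled)) {
    co_sampled <- intersect(setdiff(pop_ids(host), reference_host),
                            setdiff(pop_ids(parasitoid),
                                    reference_parasitoid))
  }
  if (length(co_sampled) < 1L) stop("no co-sampled locations")
  miss <- setdiff(co_sampled, pop_ids(host))
  miss <- c(miss, setdiff(co_sampled, pop_ids(parasitoid)))
  if (length(miss)) {
    stop("co-sampled location(s) absent from a dataset: ",
         paste(unique(miss), collapse = ", "))
  }
  structure(list(host = host, parasitoid = parasitoid,
                 reference_host = reference_host,
                 reference_parasitoid = reference_parasitoid,
                 co_sampled = co_sampled, seed = as.integer(seed),
                 out_dir = out_dir, chain = chain, n_perm = n_perm,
                 n_tables = n_tables, mcmc = mcmc,
                 run_migration = isTRUE(run_migration)),
            class = "run_config")
}

#' Run the full comparative analysis
#'
#' Executes, for both species: diversity summaries; exact HWE, LD and
#' genic-differentiation tests; null-allele EM and pairwise ENA F_ST /
#' Rho_ST; (optionally) the recent-migration MCMC; and the
#' reference-cold-spot outlier screen with reciprocal hot/cold-spot
#' classification, plus the between-species Welch comparison of G_IS.
#' Report tables are written to `cfg$out_dir` as they are produced
#' (full precision in CSV, 3-decimal rounding in the printed summary),
#' together with MCMC trace files and a machine-readable JSON manifest
#' of seeds and parameters. A stage failure aborts with the stage name;
#' tables already written are preserved.
#'
#' @param cfg A [run_config()].
#' @return A `run_bundle` list with every stage's result.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  wr <- function(df, name) {
    utils::write.csv(df, file.path(cfg$out_dir, name), row.names = FALSE)
  }
  species <- list(host = cfg$host, parasitoid = cfg$parasitoid)
  refs <- c(host = cfg$reference_host,
            parasitoid = cfg$reference_parasitoid)

  bundle$diversity <- stage("diversity", lapply(species, diversity_summary))
  for (sp in names(species)) {
    wr(as.data.frame(bundle$diversity[[sp]]),
       paste0("diversity_", sp, ".csv"))
  }
  bundle$gis_comparison <- stage("diversity", compare_species_gis(
    bundle$diversity$host, bundle$diversity$parasitoid))

  bundle$hwe <- stage("exact_tests", lapply(seq_along(species), function(i) {
    hwe_exact(species[[i]], chain = cfg$chain, seed = cfg$seed + 10L + i)
  }))
  names(bundle$hwe) <- names(species)
  bundle$ld <- stage("exact_tests", lapply(seq_along(species), function(i) {
    ld_exact(species[[i]], n_perm = cfg$n_perm, seed = cfg$seed + 20L + i)
  }))
  names(bundle$ld) <- names(species)
  for (sp in names(species)) {
    wr(bundle$hwe[[sp]]$combined, paste0("hwe_", sp, ".csv"))
    wr(bundle$ld[[sp]]$combined, paste0("ld_", sp, ".csv"))
  }

  bundle$null_freq <- stage("null_fst", lapply(species, estimate_null_freq))
  bundle$fst <- stage("null_fst", lapply(names(species), function(sp) {
    fst_ena(species[[sp]], freqs = bundle$null_freq[[sp]])
  }))
  names(bundle$fst) <- names(species)
  bundle$rho <- stage("null_fst", lapply(species, rho_st))
  bundle$genic <- stage("exact_tests", lapply(seq_along(species), function(i) {
    genic_differentiation_exact(species[[i]], n_tables = cfg$n_tables,
                                seed = cfg$seed + 30L + i)
  }))
  names(bundle$genic) <- names(species)
  for (sp in names(species)) {
    wr(bundle$fst[[sp]]$global, paste0("fst_", sp, ".csv"))
    wr(bundle$genic[[sp]]$combined, paste0("genic_tests_", sp, ".csv"))
    m <- pairwise_matrix(bundle$fst[[sp]], "fst_ena",
                         upper = data.frame(
                           pop1 = bundle$genic[[sp]]$combined$pop1,
                           pop2 = bundle$genic[[sp]]$combined$pop2,
                           p = bundle$genic[[sp]]$combined$p))
    utils::write.csv(round(m, 3),
                     file.path(cfg$out_dir,
                               paste0("differentiation_matrix_", sp, ".csv")))
  }

  if (cfg$run_migration) {
    bundle$migration <- stage("migration_mcmc", lapply(
      seq_along(species), function(i) {
        post <- run_migration_mcmc(
          species[[i]], n_gen = cfg$mcmc$n_gen,
          burn_in = cfg$mcmc$burn_in, mixing = cfg$mcmc$mixing,
          thin = cfg$mcmc$thin, n_chains = cfg$mcmc$n_chains,
          seed = cfg$seed + 40L + i)
        write_traces(post, file.path(cfg$out_dir,
                                     paste0("traces_", names(species)[i])))
        post
      }))
    names(bundle$migration) <- names(species)
    for (sp in names(species)) {
      m <- bundle$migration[[sp]]$mean
      utils::write.csv(round(m, 3),
                       file.path(cfg$out_dir,
                                 paste0("migration_", sp, ".csv")))
    }
  }

  bundle$divergence <- stage("mosaic_screen", lapply(
    names(species), function(sp) {
      locus_specific_divergence(species[[sp]], refs[[sp]],
                                freqs = bundle$null_freq[[sp]])
    }))
  names(bundle$divergence) <- names(species)
  bundle$screens <- stage("mosaic_screen",
                          lapply(bundle$divergence, screen_outliers))
  bundle$mosaic <- stage("mosaic_screen", classify_locations(
    bundle$screens$host, bundle$screens$parasitoid, cfg$co_sampled))
  wr(as.data.frame(bundle$mosaic), "mosaic_classification.csv")
  for (sp in names(species)) {
    wr(as.data.frame(bundle$divergence[[sp]]),
       paste0("locus_divergence_", sp, ".csv"))
  }

  manifest <- list(
    package = "coevmosaic",
    package_version = as.character(utils::packageVersion("coevmosaic")),
    r_version = R.version.string,
    seed = cfg$seed,
    species = list(host = cfg$host$species,
                   parasitoid = cfg$parasitoid$species),
    reference_cold_spots = as.list(refs),
    co_sampled = cfg$co_sampled,
    parameters = list(chain = cfg$chain, n_perm = cfg$n_perm,
                      n_tables = cfg$n_tables,
                      mcmc = if (cfg$run_migration) cfg$mcmc else NULL))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(bundle) <- "run_bundle"
  bundle
}

#' Build a run configuration from a YAML document
#'
#' Expected keys: `host`, `parasitoid` (file paths),
#' `reference_host`, `reference_parasitoid`, and optionally
#' `co_sampled`, `allele_digits`, `seed`, `out_dir`, `n_perm`,
#' `n_tables`, `chain` and `mcmc` sub-maps, `run_migration`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("host", "parasitoid", "reference_host", "reference_parasitoid")
  miss <- setdiff(req, names(y))
  if (length(miss)) stop("config missing field(s): ",
                         paste(miss, collapse = ", "))
  args <- y[intersect(names(y), names(formals(run_config)))]
  defaults <- formals(run_config)
  for (nm in c("chain", "mcmc")) {
    if (!is.null(y[[nm]])) {
      args[[nm]] <- utils::modifyList(eval(defaults[[nm]]), y[[nm]])
    }
  }
  do.call(run_config, args)
}
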