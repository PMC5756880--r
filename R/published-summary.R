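#' Published per-population summary statistics for the walnut system
#'
#' The per-population genetic summary reported for California
#' populations of the walnut aphid (*Chromaphis juglandicola*) and its
#' introduced parasitoid (*Trioxys pallidus*): sample sizes, mean and
#' effective allele numbers, observed heterozygosity, within-population
#' and total gene diversity, and the inbreeding coefficient G_IS.
#' Shipped as a plain-text table; used by the species-comparison stage
#' and as a reference shape for the simulator presets.
#'
#' @return Data frame with columns `species`, `id`, `location`, `n`,
#'   `num`, `eff_num`, `ho`, `hs`, `ht`, `gis`.
#' @export
walnut_summary_table <- function() {
  utils::read.csv(system.file("extdata",
                              "walnut_system_population_summary.csv",
                              package = "coevmosaic"),
                  stringsAsFactors = FALSE)
}

#' Between-species summary comparison from per-population statistics
#'
#' Species means of observed heterozygosity, mean and SD of G_IS, and
#' the Welch unequal-variance t comparison of G_IS between the host and
#' the parasitoid (host minus parasitoid), via [compare_species_gis()].
#'
#' @param summary_df A data frame shaped like [walnut_summary_table()]
#'   (columns `species`, `ho`, `gis`), or `NULL` to use the shipped
#'   table.
#' @param host,parasitoid The two `species` values; defaults are the
#'   walnut system's aphid host and parasitoid.
#' @return List with per-species `mean_ho`, `mean_gis`, `sd_gis`, and
#'   `welch` (`t`, `df`, `p`).
#' @export
species_summary_comparison <- function(summary_df = NULL,
                                       host = "Chromaphis juglandicola",
                                       parasitoid = "Trioxys pallidus") {
  if (is.null(summary_df)) summary_df <- walnut_summary_table()
  hs <- summary_df[summary_df$species == host, ]
  ps <- summary_df[summary_df$species == parasitoid, ]
  if (!nrow(hs) || !nrow(ps)) stop("species not found in summary table")
  w <- compare_species_gis(hs, ps)
  list(mean_ho = c(host = mean(hs$ho), parasitoid = mean(ps$ho)),
       mean_gis = c(host = mean(hs$gis), parasitoid = mean(ps$gis)),
       sd_gis = c(host = stats::sd(hs$gis), parasitoid = stats::sd(ps$gis)),
       welch = list(t = w$t, df = w$df, p = w$p))
}
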