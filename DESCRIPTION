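Package: coevmosaic
Title: Comparative Population Genetics for Geographic Mosaics of Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative microsatellite population genetics of
    interacting species, motivated by host-parasitoid systems such as the
    walnut aphid (Chromaphis juglandicola) and its introduced parasitoid
    (Trioxys pallidus) in California walnut orchards. Provides GenePop and
    CSV genotype input/output, per-population diversity and inbreeding
    statistics (Nei gene diversities, G_IS), Markov-chain exact tests for
    Hardy-Weinberg equilibrium, linkage disequilibrium and genic
    differentiation with Fisher combination and Bonferroni control, EM
    estimation of null-allele frequencies with null-corrected (ENA)
    Weir-Cockerham F_ST and the allele-size analogue Rho_ST, a Bayesian
    MCMC sampler for recent migration fractions among populations, and a
    reference-cold-spot locus-outlier screen that classifies locations as
    candidate coevolutionary hot or cold spots. A synthetic-data generator
    produces paired two-species datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
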