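---
title: "Methods: comparative population genetics for geographic mosaics of coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative population genetics for geographic mosaics of coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevmosaic)
```

## The scientific problem

When an introduced natural enemy (here the parasitoid wasp *Trioxys
pallidus*) is deployed against an invasive pest (the walnut aphid
*Chromaphis juglandicola*), the stability of biological control may
depend on whether the two species coevolve. The geographic-mosaic view
predicts that reciprocal selection is strong at some locations ("hot
spots") and weak or absent at others ("cold spots"). With co-dominant
neutral markers (microsatellites) scored for both species at a set of
shared locations, one can look for indirect evidence: locations where
*both* species show locus-specific divergence outliers relative to a
reference location where the partner species is absent (a known cold
spot).

`coevmosaic` implements that comparative analysis end to end: diversity
and inbreeding summaries, exact tests (Hardy–Weinberg equilibrium,
linkage disequilibrium, genic differentiation), null-allele-corrected
F\_ST and the allele-size analogue Rho\_ST, Bayesian estimation of
recent migration fractions, and the reference-cold-spot outlier screen
with reciprocal hot/cold-spot classification. A synthetic-data
generator with full latent-truth records makes every stage testable.

## Data model

A `genotype_dataset` holds diploid two-allele calls (positive integer
allele codes — fragment lengths or repeat counts) for individuals
grouped into populations, with a species tag. A genotype is missing
only when both alleles are missing; half-missing calls are rejected at
parse time because co-dominant scoring yields both alleles or neither.
GenePop (2- and 3-digit) and a CSV dialect (`a1/a2` cells, `.` for
missing) are supported for input and output, and `read` after `write`
is the identity on valid datasets.

Clone deduplication (`deduplicate_clones()`) collapses identical
complete multilocus genotypes within a population. It is off by default
in the pipeline: field designs usually limit clonal resampling by
spreading collections across trees, and removing genotypes is a choice
the analyst should make explicitly. Missing values are treated as a
distinct state, so near-identical genotypes differing in missingness
are never collapsed.

## Diversity and inbreeding

Per population and locus, with `n` typed individuals and observed
allele frequencies `p`:

* observed heterozygosity `Ho` = fraction of heterozygous individuals;
* Nei's unbiased gene diversity
  `Hs = n/(n-1) * (1 - sum(p^2) - Ho/(2n))`;
* with a single population, total diversity equals `Hs` (the
  per-population report therefore prints `Ht = Hs`, and the pooled,
  across-population `Ht` uses mean allele frequencies with the
  analogous harmonic-mean-sample-size correction);
* the multilocus inbreeding coefficient is
  `G_IS = 1 - sum(Ho_l) / sum(Hs_l)`, a ratio of locus-summed
  components. Summing before taking the ratio matters: with rounded
  per-locus means the ratio can shift by several units in the third
  decimal, which is visible at the 3-decimal reporting precision used
  in the field's tables.

`Num` and `Eff_num` are the means over loci of the number of distinct
alleles and of `1/sum(p^2)`. Loci untyped in a population are excluded
from the means and logged.

## Exact tests

All three tests are exact conditional Monte-Carlo tests; their default
chain parameters (10,000 dememorization steps, 20 batches of 5,000
iterations) follow the conventions of the classical population-genetics
test software and are configurable.

**HWE.** The probability test conditions on allele counts. For small
allele configurations the genotype-table distribution is enumerated
completely. Otherwise a Markov chain runs over *pairings* of the
observed allele copies into genotypes: the uniform distribution over
pairings induces exactly the conditional null distribution on genotype
tables, and a partner-swap move is symmetric, so every proposal is
accepted and correctness does not rest on a Metropolis ratio. The
p-value is the time fraction spent in tables no more probable than the
observed one; batch means give a Monte-Carlo standard error.

**Linkage disequilibrium.** Per population, a permutation G test on the
two-locus genotype contingency table (one locus' genotypes shuffled
among individuals); combined across populations by Fisher's method.

**Genic differentiation.** Per locus, a G test on the population-by-
allele contingency table with null tables drawn *independently* from
the fixed-margin distribution by the Patefield algorithm
(`stats::r2dtable`); combined across loci by Fisher's method.

Fisher's statistic is `-2 * sum(log(p))` on `2k` degrees of freedom. A
Monte-Carlo p-value of zero propagates as an infinite statistic and the
combined p-value is reported as below `1/N` — the convention used when
test batteries print a chi-square of infinity. Bonferroni-corrected
levels (`0.05 / 105` for 15 loci, `0.05 / 66` for 12, `0.05 / 10` for
five populations) are attached to the reports.

## Null alleles and differentiation

Microsatellite null alleles inflate apparent homozygosity (null/visible
heterozygotes are scored as visible homozygotes) and missingness
(null/null homozygotes fail entirely). Per population and locus an EM
algorithm under Hardy–Weinberg with one null allele apportions the
observed homozygote counts between true homozygotes and null-masked
heterozygotes, attributing missing genotypes to the null/null class,
and iterates to an L-infinity change below 1e-6 (cap 10,000 iterations,
non-convergence flagged). An all-missing cell is the degenerate
boundary `null_freq = 1`.

Pairwise differentiation uses the multiallelic Weir–Cockerham variance
components. The ENA ("excluding null alleles") correction replaces
observed allele frequencies with the EM-corrected visible frequencies —
which sum to `1 - null_freq`, the null class absorbing the masked
mass — and sums components over visible alleles only. Global values are
always ratios of summed components across loci and alleles, never means
of per-locus ratios; negative estimates are reported as computed, since
truncation at zero would bias the outlier screen's fences. Pairwise
estimates use only the two focal populations because the screen needs
locus-specific values against a designated reference.

Rho\_ST is the allele-size analogue: one-way variance components of
allele size at the gene-copy level, with the unequal-sample-size
coefficient, reported per locus and as a ratio of sums. It is *not*
null-corrected (the correction is defined on identity frequencies, not
sizes); the output records this. Rho\_ST is invariant under affine
transformations of allele size, and F\_ST under arbitrary relabelling.

## Recent migration

The migration model follows the BayesAss family. Each individual in
population `l` carries a latent migrant ancestry: non-migrant,
first-generation migrant from `q` (genotype drawn wholly from `q`'s
frequencies), or second-generation (one parental gamete from each
population). The prior given the migration matrix is `m[l][l]` for
non-migrants and `m[l][q]/2` for each generation of migrants from `q`;
each row's non-migrant fraction is constrained to at least 2/3 —
migration fractions beyond 1/3 per generation are not identifiable as
"recent migration" in this model family. Genotype probabilities include
per-population inbreeding coefficients
(`P(hom) = F p + (1-F) p^2`, `P(het) = (1-F) 2 p_a p_b`).

The sampler (compiled, Rcpp) performs one Gibbs resampling of a random
individual's ancestry per generation plus one randomly chosen
parameter-block move: a migration-row perturbation, a two-allele
frequency mass shift, or a reflected random walk on an inbreeding
coefficient. The mixing parameter in (0, 1] scales each proposal window
as a fraction of the parameter's support (window, in order: `1/3`,
`0.2` mass, the full F range). Priors are uniform on the constrained
supports, verified by prior-only runs whose moments match the uniform
law on the scaled simplex. Default desk-scale runs use 4 chains of
200,000 generations, 20,000 burn-in, thinning 50; the classical
10-million-generation configuration is a parameter choice away. An
ordered pair is reported significant when `mean ± 1.96 SD` of the
pooled posterior excludes zero, the standard reporting rule for such
tables. `convergence_report()` gives effective sample sizes
(initial-positive autocorrelation-sum estimator) and the
between/within-chain variance ratio with a 1.1 flag.

## The mosaic screen

For each species, per-locus ENA-corrected F\_ST (and Rho\_ST) is
computed between the species' reference cold spot and every candidate
location. Outliers fall outside Tukey fences — quartiles via Tukey
hinges (the `fivenum`/boxplot-whisker convention, since the original
procedure read outliers off R boxplots) at 1.5 IQR, both tails
reported; an interpolated-quantile option exists behind a flag. A
co-sampled location is a candidate hot spot when **both** species show
at least one outlier locus there; otherwise a candidate cold spot;
reference locations are labelled reference cold spots. The rule is
symmetric in which species is called "host".

Two numerical guards matter in practice:

* **Uninformative loci.** A locus with fewer than 2 copies of the
  pair's second-most-common allele yields an estimate determined
  entirely by where one gene copy happens to sit. Such values are
  small-sample artifacts; left in, they inflate the IQR until the upper
  fence can exceed 1 (no locus can then ever be flagged). The screen
  excludes them, like loci untyped in one member of the pair.
* **Chance outliers.** Tukey fences applied to 12–15 values flag at
  least one spurious locus in roughly a quarter to a third of
  location-species combinations, for essentially any realistic
  configuration — a textbook property of boxplots on small samples.
  The reciprocity requirement multiplies the two species' rates, but a
  screen of this design is *not* a hypothesis test. The package
  therefore also provides `outlier_permutation_test()`, a plain
  label-permutation test of locus-specific differentiation
  (`p = (1 + #[perm >= obs]) / (1 + n_perm)`), as an explicitly
  labelled substitute for model-based outlier significance machinery;
  its p-values are reported as permutation p-values and nothing else.

The species comparison of inbreeding uses Welch's unequal-variance t
with Welch–Satterthwaite degrees of freedom on the per-population
G\_IS values (host minus parasitoid).

## The synthetic-data generator

`simulate_dataset()` draws, per locus, ancestral allele frequencies
from a symmetric Dirichlet and per-population frequencies from the
Balding–Nichols kernel `Dirichlet(p_anc (1-c)/c)`, whose expected Weir
F\_ST equals `c` exactly — so the calibration map from drift parameter
to target F\_ST is the identity and needs no lookup table. Genotypes
are drawn with inbreeding (`P(hom) = F p + (1-F) p^2`), then null
alleles (a hidden allele of the stated frequency; null/visible pairs
emitted as visible homozygotes, null/null as missing), clone
duplication (cyclical-parthenogenesis mode for the aphid; only diploid
females are emitted for either species, since only females are
genotyped in such surveys), migrant planting, and dropout are applied.
Allele codes are fragment lengths on a per-locus ladder (random offset,
2–4 bp motif).

Choices worth stating:

* **Presets.** `sim_config_parasitoid()` (15 loci, 4 alleles/locus,
  Dirichlet 0.27, drift 0.03, F = 0.24) and `sim_config_aphid()`
  (12 loci, 3 alleles, Dirichlet 0.17, drift 0.15, F = 0.13,
  clone rate 0.1) were calibrated once, analytically, to the published
  species-level summaries of the walnut system (observed
  heterozygosity near 0.28 and 0.15, inbreeding near 0.24 and 0.13,
  parasitoid pairwise F\_ST a few percent, aphid differentiation
  higher), with sample sizes 7–14 as in that survey.
* **Migrant planting is deterministic**: `round(m[l,q] * n)`
  individuals per source, assigned at random. A planted fraction of
  0.2 then means exactly 20%, so parameter-recovery checks measure
  sampler error, not binomial realization noise.
* **Hot spots are sweeps.** A hotspot locus/location gets the
  ancestrally rarest allele driven to frequency 0.9 (local adaptation)
  rather than an extra dose of neutral drift: a drift boost is
  statistically invisible against small-sample per-locus F\_ST noise,
  and a sweep is the kind of signature the screen is meant to find.
* **What the generator does not emulate:** mutation-model realism
  (stepwise vs infinite-alleles beyond the size ladder), coalescent
  genealogies, temporal sampling, linked loci, and marker ascertainment
  (real panels are pre-screened for polymorphism; the Dirichlet model
  produces occasional near-monomorphic loci instead). Passing tests
  therefore validate the estimators and the screen's logic under an
  island-model idealization, not the field realism of any particular
  dataset.

## Problem sizes used in the checks

The package's own validation uses desk-scale problem sizes chosen to
make each property measurable: complete enumeration for HWE oracles at
n = 4–20; EM recovery at 500 diploids; inbreeding recovery at 200;
migration recovery with two populations of 50 at 200,000 generations
per chain (20 seeded surveys for the coverage rate); the screen's
planted-sweep demonstrations on surveys of 30 diploids per location
with eight-allele loci (where whisker screens have real power), and its
null calibration on several hundred replicate small surveys. The
acceptance script (`scripts/acceptance.R`) re-runs all of these from
scratch.

## Known limitations

* The Tukey-fence screen is descriptive; its location classifications
  inherit the boxplot's small-sample false-flag rate, and locations
  with wide locus-to-locus F\_ST spread can have an upper fence above
  the statistic's maximum (no detectable outlier at all). This is a
  property of the published procedure, reproduced faithfully.
* Rho\_ST is computed from a gene-copy-level variance decomposition;
  an individual-level layer (as in the full hierarchical treatments)
  is not included.
* The migration sampler targets the BayesAss model family but is not a
  numerical clone of any particular implementation; posterior means
  carry Monte-Carlo and model error of a few hundredths at the
  desk-scale defaults.
* The null-allele EM assumes Hardy–Weinberg within populations; with
  strong inbreeding the homozygote excess is partly absorbed into the
  null-frequency estimate. The ENA correction inherits this.
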