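#' Locus-specific divergence from a reference cold spot
#'
#' For every candidate location (every population except the reference),
#' the per-locus ENA-corrected F_ST and allele-size Rho_ST between the
#' reference population and that location, computed on the two focal
#' populations only. This is the input to the Tukey-fence outlier screen
#' of the geographic-mosaic procedure: the reference is a location where
#' the interacting partner species is absent, taken as a known
#' coevolutionary cold spot.
#'
#' Loci carrying (almost) no polymorphism within a pair are excluded:
#' with fewer than `min_minor_copies` copies of the pair's second-most-
#' common allele, the locus-specific estimate is determined entirely by
#' the placement of one or two gene copies and would only blur the
#' fences, so it is reported as `NA` (and excluded from them), like a
#' locus untyped in one member of the pair.
#'
#' @param ds A [genotype_dataset()].
#' @param reference_pop Population id of the species' reference cold
#'   spot.
#' @param freqs Optional [estimate_null_freq()] result for `ds`.
#' @param min_minor_copies Minimum pooled copies of the pair's
#'   second-most-common allele for a locus to enter the screen.
#' @return A `locus_divergence` data frame: `location`, `locus`,
#'   `fst_ena`, `fst_raw`, `rho_st` (`NA` where a locus is untyped or
#'   uninformative in a pair), with attributes `reference` and
#'   `species`.
#' @export
locus_specific_divergence <- function(ds, reference_pop, freqs = NULL,
                                      min_minor_copies = 2) {
  ids <- pop_ids(ds)
  if (!reference_pop %in% ids) {
    stop("reference population '", reference_pop, "' not in dataset")
  }
  others <- setdiff(ids, reference_pop)
  pairs <- cbind(rep(reference_pop, length(others)), others)
  fst <- fst_ena(ds, freqs = freqs, pairs = pairs)
  rho <- rho_st(ds, pairs = pairs)
  out <- data.frame(location = fst$per_locus$pop2,
                    locus = fst$per_locus$locus,
                    fst_ena = fst$per_locus$fst_ena,
                    fst_raw = fst$per_locus$fst_raw,
                    rho_st = rho$per_locus$rho_st,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    j <- match(out$locus[k], ds$loci)
    a <- c(alleles_at(ds$populations[[reference_pop]], j),
           alleles_at(ds$populations[[out$location[k]]], j))
    cnt <- sort(tabulate(factor(a)), decreasing = TRUE)
    if (length(cnt) < 2L || cnt[2] < min_minor_copies) {
      out[k, c("fst_ena", "fst_raw", "rho_st")] <- NA_real_
    }
  }
  structure(out, reference = reference_pop, species = ds$species,
            class = c("locus_divergence", "data.frame"))
}

#' Tukey-fence (boxplot-whisker) outlier detection
#'
#' Quartiles are Tukey hinges (the [stats::fivenum()] convention used by
#' R's boxplot whiskers); outliers fall below `Q1 - coef * IQR` or above
#' `Q3 + coef * IQR`. Both tails are reported and labelled. The
#' interpolated-quantile convention ([stats::quantile()] type 7) is
#' available behind `quartiles = "interpolated"`.
#'
#' @param values Numeric vector (may be named; `NA`s are ignored).
#' @param coef Whisker multiplier (1.5 = standard boxplot whiskers).
#' @param quartiles `"hinges"` (default) or `"interpolated"`.
#' @return List with `outliers` (names or indices), `tails` (`"low"` /
#'   `"high"` per outlier), `lower`, `upper` (fence positions) and
#'   `n_used`. Fewer than 4 non-missing values yields no fences and an
#'   empty outlier set, with a warning.
#' @export
tukey_fence_outliers <- function(values, coef = 1.5,
                                 quartiles = c("hinges", "interpolated")) {
  quartiles <- match.arg(quartiles)
  if (is.null(names(values))) names(values) <- seq_along(values)
  v <- values[!is.na(values)]
  if (length(v) < 4L) {
    warning("fewer than 4 non-missing values: no fences computed")
    return(list(outliers = character(0), tails = character(0),
                lower = NA_real_, upper = NA_real_, n_used = length(v)))
  }
  if (quartiles == "hinges") {
    fn <- stats::fivenum(v)
    q1 <- fn[2]; q3 <- fn[4]
  } else {
    qs <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    q1 <- qs[1]; q3 <- qs[2]
  }
  iqr <- q3 - q1
  lower <- unname(q1 - coef * iqr)
  upper <- unname(q3 + coef * iqr)
  lo <- v < lower
  hi <- v > upper
  list(outliers = names(v)[lo | hi],
       tails = c(rep("low", sum(lo)), rep("high", sum(hi)))[
         order(c(which(lo), which(hi)))],
       lower = lower, upper = upper, n_used = length(v))
}

#' Outlier screen for one species
#'
#' Applies [tukey_fence_outliers()] to each candidate location's
#' per-locus divergence-from-reference vector.
#'
#' @param div A [locus_specific_divergence()] result.
#' @param metric Column of `div` to screen (`"fst_ena"` is the primary
#'   metric of the procedure; `"rho_st"` is a secondary parallel).
#' @param coef,quartiles Passed to [tukey_fence_outliers()].
#' @return A `mosaic_species_report`: list with `outliers` (named list,
#'   per location, of outlier locus names), `fences` (data frame),
#'   `metric`, `reference`, `species`.
#' @export
screen_outliers <- function(div, metric = "fst_ena", coef = 1.5,
                            quartiles = "hinges") {
  stopifnot(inherits(div, "locus_divergence"), metric %in% names(div))
  locs <- unique(div$location)
  outl <- stats::setNames(vector("list", length(locs)), locs)
  fences <- list()
  for (lc in locs) {
    sub <- div[div$location == lc, ]
    v <- stats::setNames(sub[[metric]], sub$locus)
    tf <- tukey_fence_outliers(v, coef = coef, quartiles = quartiles)
    outl[[lc]] <- tf$outliers
    fences[[length(fences) + 1L]] <- data.frame(
      location = lc, lower = tf$lower, upper = tf$upper,
      n_used = tf$n_used, n_outliers = length(tf$outliers))
  }
  structure(list(outliers = outl, fences = do.call(rbind, fences),
                 metric = metric, reference = attr(div, "reference"),
                 species = attr(div, "species")),
            class = "mosaic_species_report")
}

#' Reciprocal hot/cold-spot classification of locations
#'
#' A co-sampled location is a candidate coevolutionary hot spot when
#' BOTH interacting species show at least one outlier locus there, and a
#' candidate cold spot otherwise; each species' reference population is
#' labelled a reference cold spot. The rule is symmetric in which
#' species is called the host. Locations present in only one species'
#' data (and not a reference) are excluded with a warning.
#'
#' @param host_report,parasitoid_report [screen_outliers()] results for
#'   the two species.
#' @param co_sampled Character vector of location labels sampled for
#'   both species.
#' @return A `mosaic_report` data frame: `location`, `classification`
#'   (`candidate_hot_spot` / `candidate_cold_spot` /
#'   `reference_cold_spot`), `host_outliers`, `parasitoid_outliers`
#'   (comma-separated locus names), with the two species reports
#'   attached as attributes.
#' @export
classify_locations <- function(host_report, parasitoid_report,
                               co_sampled) {
  refs <- c(host_report$reference, parasitoid_report$reference)
  seen <- unique(c(names(host_report$outliers),
                   names(parasitoid_report$outliers), refs))
  stray <- setdiff(seen, c(co_sampled, refs))
  if (length(stray)) {
    warning("location(s) present for one species only, excluded: ",
            paste(stray, collapse = ", "))
  }
  rows <- list()
  for (lc in co_sampled) {
    ho <- host_report$outliers[[lc]] %||% character(0)
    po <- parasitoid_report$outliers[[lc]] %||% character(0)
    cls <- if (length(ho) >= 1L && length(po) >= 1L) {
      "candidate_hot_spot"
    } else "candidate_cold_spot"
    rows[[length(rows) + 1L]] <- data.frame(
      location = lc, classification = cls,
      host_outliers = paste(ho, collapse = ","),
      parasitoid_outliers = paste(po, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (rf in unique(refs)) {
    if (rf %in% co_sampled) next
    rows[[length(rows) + 1L]] <- data.frame(
      location = rf, classification = "reference_cold_spot",
      host_outliers = "", parasitoid_outliers = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, host_report = host_report,
            parasitoid_report = parasitoid_report,
            class = c("mosaic_report", "data.frame"))
}

#' Permutation significance assessment for an outlier locus
#'
#' A permutation alternative to model-based outlier tests: individuals
#' are shuffled between the two focal populations (sample sizes held
#' fixed), the locus' uncorrected Weir--Cockerham F_ST recomputed each
#' time, and `p = (1 + #[perm >= observed]) / (1 + n_perm)`. This is a
#' plain label-permutation test of differentiation at one locus, not a
#' selection model.
#'
#' @param ds A [genotype_dataset()].
#' @param pop1,pop2 The two population ids (e.g. reference cold spot and
#'   candidate location).
#' @param locus Locus name.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional RNG seed.
#' @return List with `p`, `observed` (the locus F_ST), `n_perm`.
#' @export
outlier_permutation_test <- function(ds, pop1, pop2, locus,
                                     n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  j <- match(locus, ds$loci)
  if (is.na(j)) stop("unknown locus '", locus, "'")
  g1 <- genotype_rows_at(ds$populations[[pop1]], j)
  g2 <- genotype_rows_at(ds$populations[[pop2]], j)
  if (nrow(g1) < 2L || nrow(g2) < 2L) {
    stop("locus '", locus, "' needs at least 2 typed individuals per population")
  }
  obs <- fst_locus_two_groups(g1, g2)
  pool <- rbind(g1, g2)
  n1 <- nrow(g1); n <- nrow(pool)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    f <- fst_locus_two_groups(pool[idx, , drop = FALSE],
                              pool[-idx, , drop = FALSE])
    if (!is.na(f) && f >= obs - 1e-12) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + n_perm), observed = obs, n_perm = n_perm)
}

# single-locus Weir-Cockerham theta from two n x 2 allele matrices
fst_locus_two_groups <- function(g1, g2) {
  mk <- function(g) {
    n <- nrow(g)
    a <- c(g[, 1], g[, 2])
    tab <- table(a)
    p <- stats::setNames(as.vector(tab) / (2 * n), names(tab))
    het <- g[g[, 1] != g[, 2], , drop = FALSE]
    h <- stats::setNames(rep(0, length(p)), names(p))
    if (nrow(het)) {
      th <- table(factor(c(het[, 1], het[, 2]), levels = names(p)))
      h[] <- as.vector(th) / n
    }
    list(n = n, p = p, h = h)
  }
  s1 <- mk(g1); s2 <- mk(g2)
  cmp <- wc_components(list(s1, s2), union(names(s1$p), names(s2$p)))
  ratio_or_na(sum(cmp[, "a"]), sum(cmp))
}

#' Welch comparison of multilocus inbreeding between two species
#'
#' Per-species mean and SD of the per-population inbreeding coefficient
#' G_IS, and the Welch unequal-variance t statistic (host minus
#' parasitoid) with Welch--Satterthwaite degrees of freedom and
#' two-sided p-value.
#'
#' @param host_summary,parasitoid_summary [diversity_summary()] results
#'   (or data frames with a `gis` column).
#' @return List with `t`, `df`, `p`, and per-species `mean` and `sd`.
#' @export
compare_species_gis <- function(host_summary, parasitoid_summary) {
  x <- host_summary$gis; y <- parasitoid_summary$gis
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 populations per species")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean = c(host = mean(x), parasitoid = mean(y)),
                sd = c(host = 0, parasitoid = 0)))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       mean = c(host = mean(x), parasitoid = mean(y)),
       sd = c(host = stats::sd(x), parasitoid = stats::sd(y)))
}

#' Boxplot panels of locus-specific divergence per location
#'
#' One boxplot per candidate location (whiskers at `coef` times the
#' interquartile range from the Tukey hinges, outliers as open circles),
#' mirroring the usual presentation of reference-cold-spot outlier
#' screens.
#'
#' @param div A [locus_specific_divergence()] result.
#' @param metric Column to plot.
#' @param coef Whisker multiplier.
#' @param file Optional PDF path; plotted to the active device if
#'   `NULL`.
#' @return Invisibly, the list returned by [graphics::boxplot()].
#' @export
plot_mosaic_divergence <- function(div, metric = "fst_ena", coef = 1.5,
                                   file = NULL) {
  stopifnot(inherits(div, "locus_divergence"))
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  bp <- graphics::boxplot(
    div[[metric]] ~ factor(div$location), range = coef,
    xlab = "candidate location",
    ylab = paste0(metric, " vs reference (", attr(div, "reference"), ")"),
    main = attr(div, "species"))
  invisible(bp)
}
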