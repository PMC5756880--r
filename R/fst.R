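#' EM estimation of null-allele frequencies
#'
#' Microsatellite null alleles fail to amplify: a null/visible
#' heterozygote is scored as a visible homozygote and a null/null
#' homozygote as a missing genotype. Under Hardy--Weinberg proportions
#' with one null allele per locus, an expectation--maximisation
#' algorithm apportions each population's observed homozygote counts
#' between true homozygotes and null-masked heterozygotes (missing
#' genotypes are attributed to the null/null class) and re-estimates the
#' visible-plus-null allele frequencies until the largest frequency
#' change falls below `tol`.
#'
#' @param ds A [genotype_dataset()].
#' @param tol Convergence tolerance on the L-infinity frequency change.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @return An `allele_freq_table`: list with `freq[[pop]][[locus]]`
#'   (named vector of corrected visible-allele frequencies, summing to
#'   `1 - null_freq`), matrices `null_freq`, `iterations` and `converged`
#'   (populations x loci), and `loci`/`pops` labels. An all-missing
#'   pop x locus cell is the degenerate boundary `null_freq = 1`, flagged
#'   non-converged.
#' @export
estimate_null_freq <- function(ds, tol = 1e-6, max_iter = 10000L) {
  P <- length(ds$populations)
  L <- length(ds$loci)
  ids <- pop_ids(ds)
  nullf <- iter <- matrix(NA_real_, P, L, dimnames = list(ids, ds$loci))
  conv <- matrix(NA, P, L, dimnames = list(ids, ds$loci))
  freq <- stats::setNames(vector("list", P), ids)
  for (ip in seq_len(P)) {
    pop <- ds$populations[[ip]]
    freq[[ip]] <- stats::setNames(vector("list", L), ds$loci)
    for (j in seq_len(L)) {
      g <- genotype_rows_at(pop, j)
      n_total <- dim(pop$genotypes)[1]
      n_miss <- n_total - nrow(g)
      if (nrow(g) == 0L) {
        freq[[ip]][[j]] <- numeric(0)
        nullf[ip, j] <- 1; iter[ip, j] <- 0; conv[ip, j] <- FALSE
        next
      }
      fit <- null_em_one(g, n_miss, tol, max_iter)
      freq[[ip]][[j]] <- fit$p_vis
      nullf[ip, j] <- fit$p_null
      iter[ip, j] <- fit$iterations
      conv[ip, j] <- fit$converged
    }
  }
  structure(list(freq = freq, null_freq = nullf, iterations = iter,
                 converged = conv, pops = ids, loci = ds$loci),
            class = "allele_freq_table")
}

# EM for one pop x locus. g: typed n x 2 allele matrix; n_miss missing.
null_em_one <- function(g, n_miss, tol, max_iter) {
  alleles <- sort(unique(c(g[, 1], g[, 2])))
  k <- length(alleles)
  i1 <- match(g[, 1], alleles)
  i2 <- match(g[, 2], alleles)
  hom <- i1 == i2
  n_hom <- tabulate(i1[hom], nbins = k)        # apparent homozygotes
  het_copies <- tabulate(c(i1[!hom], i2[!hom]), nbins = k)
  n <- nrow(g) + n_miss                        # individuals in the model
  # init: naive counts, small null mass
  p <- c(tabulate(c(i1, i2), nbins = k), 2 * n_miss + 0.5)
  p <- p / sum(p)
  it <- 0L
  repeat {
    it <- it + 1L
    pv <- p[seq_len(k)]
    pn <- p[k + 1L]
    # E-step: split apparent homozygotes of allele i into true hom vs i/null
    denom <- pv^2 + 2 * pv * pn
    w_true <- ifelse(denom > 0, pv^2 / denom, 1)
    exp_true_hom <- n_hom * w_true
    exp_null_het <- n_hom * (1 - w_true)
    # M-step from expected allele-copy counts
    cnt_vis <- 2 * exp_true_hom + het_copies + exp_null_het
    cnt_null <- sum(exp_null_het) + 2 * n_miss
    p_new <- c(cnt_vis, cnt_null) / (2 * n)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol || it >= max_iter) break
  }
  list(p_vis = stats::setNames(p[seq_len(k)], alleles), p_null = p[k + 1L],
       iterations = it, converged = it < max_iter || max_iter == 0L)
}

# Weir & Cockerham (1984) per-allele variance components.
# stats: list over populations of list(n, p (named freq vector over the
# union allele set, may sum to < 1 under the ENA correction), h (named
# observed heterozygote frequency involving each allele)).
wc_components <- function(stats_list, alleles) {
  r <- length(stats_list)
  n_i <- vapply(stats_list, function(z) z$n, 0)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  out <- matrix(0, length(alleles), 3,
                dimnames = list(alleles, c("a", "b", "c")))
  for (a in alleles) {
    p_ia <- vapply(stats_list, function(z) {
      if (a %in% names(z$p)) unname(z$p[a]) else 0
    }, 0)
    h_ia <- vapply(stats_list, function(z) {
      if (a %in% names(z$h)) unname(z$h[a]) else 0
    }, 0)
    pbar <- sum(n_i * p_ia) / (r * nbar)
    s2 <- sum(n_i * (p_ia - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_ia) / (r * nbar)
    va <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    vb <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    vc <- hbar / 2
    out[a, ] <- c(va, vb, vc)
  }
  out
}

# observed per-locus stats for one population (for W&C)
wc_pop_stats <- function(pop, locus_index) {
  g <- genotype_rows_at(pop, locus_index)
  if (nrow(g) < 2L) return(NULL)
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

#' Pairwise Weir--Cockerham F_ST with the ENA null-allele correction
#'
#' Multiallelic Weir & Cockerham (1984) theta for each population pair,
#' in two flavours: uncorrected (allele frequencies tallied from the
#' observed calls) and ENA-corrected ("excluding null alleles"): allele
#' frequencies are replaced by the EM-corrected visible-allele
#' frequencies from [estimate_null_freq()] — which sum to
#' `1 - null_freq`, the null class absorbing the masked mass — and the
#' variance-component sums run over visible alleles only. Global values
#' are ratios of variance-component sums across loci and alleles, never
#' means of per-locus ratios; negative estimates are reported as
#' computed.
#'
#' @param ds A [genotype_dataset()].
#' @param freqs An `allele_freq_table` from [estimate_null_freq()];
#'   computed from `ds` if `NULL`.
#' @param pairs `"all"`, or a 2-column matrix / data frame of population
#'   ids.
#' @return A `pairwise_fst` object: `global` (data frame `pop1`, `pop2`,
#'   `fst_ena`, `fst_raw`) and `per_locus` (long data frame with
#'   per-locus `fst_ena`, `fst_raw`; `NA` where a pair has no co-typed
#'   copies at a locus).
#' @export
fst_ena <- function(ds, freqs = NULL, pairs = "all") {
  if (is.null(freqs)) freqs <- estimate_null_freq(ds)
  pr <- resolve_pairs(ds, pairs)
  glob <- list(); perloc <- list()
  for (k in seq_len(nrow(pr))) {
    id1 <- pr[k, 1]; id2 <- pr[k, 2]
    p1 <- ds$populations[[id1]]; p2 <- ds$populations[[id2]]
    num_e <- den_e <- num_r <- den_r <- 0
    rows <- data.frame(pop1 = id1, pop2 = id2, locus = ds$loci,
                       fst_ena = NA_real_, fst_raw = NA_real_)
    for (j in seq_along(ds$loci)) {
      s1 <- wc_pop_stats(p1, j); s2 <- wc_pop_stats(p2, j)
      if (is.null(s1) || is.null(s2)) next
      alleles <- union(names(s1$p), names(s2$p))
      raw <- wc_components(list(s1, s2), alleles)
      # ENA: EM-corrected visible frequencies, same observed het terms
      e1 <- s1; e2 <- s2
      e1$p <- freqs$freq[[id1]][[j]]
      e2$p <- freqs$freq[[id2]][[j]]
      ena <- wc_components(list(e1, e2), alleles)
      rows$fst_raw[j] <- ratio_or_na(sum(raw[, "a"]), sum(raw))
      rows$fst_ena[j] <- ratio_or_na(sum(ena[, "a"]), sum(ena))
      num_r <- num_r + sum(raw[, "a"]); den_r <- den_r + sum(raw)
      num_e <- num_e + sum(ena[, "a"]); den_e <- den_e + sum(ena)
    }
    glob[[k]] <- data.frame(pop1 = id1, pop2 = id2,
                            fst_ena = ratio_or_na(num_e, den_e),
                            fst_raw = ratio_or_na(num_r, den_r))
    perloc[[k]] <- rows
  }
  structure(list(global = do.call(rbind, glob),
                 per_locus = do.call(rbind, perloc),
                 species = ds$species),
            class = "pairwise_fst")
}

ratio_or_na <- function(num, den) if (abs(den) < 1e-300) NA_real_ else num / den

resolve_pairs <- function(ds, pairs) {
  ids <- pop_ids(ds)
  if (identical(pairs, "all")) {
    if (length(ids) < 2L) stop("need at least two populations")
    pr <- t(utils::combn(ids, 2))
  } else {
    pr <- as.matrix(pairs)
    if (ncol(pr) != 2L) stop("pairs must have two columns")
    bad <- setdiff(unique(as.vector(pr)), ids)
    if (length(bad)) stop("unknown population id(s): ",
                          paste(bad, collapse = ", "))
  }
  dimnames(pr) <- NULL
  pr
}

#' Allele-size differentiation Rho_ST
#'
#' The allele-size analogue of F_ST for stepwise-mutating
#' microsatellites: a variance-components analysis of allele size at the
#' gene-copy level. Per locus, among-population and within-population
#' mean squares of allele size give `sigma2_a = (MSA - MSW) / n0` (with
#' `n0` the unequal-sample-size coefficient over gene copies) and
#' `rho = sigma2_a / (sigma2_a + MSW)`. Global values are ratios of
#' summed components across loci. No null-allele correction is applied
#' to Rho_ST; the output records this in attribute `"null_corrected"`.
#'
#' @param ds A [genotype_dataset()] whose allele codes carry size
#'   meaning (fragment lengths or repeat counts).
#' @param pairs `"all"`, or a 2-column matrix / data frame of ids.
#' @return A `pairwise_rho` object with `global` and `per_locus` data
#'   frames (columns `pop1`, `pop2`, [`locus`,] `rho_st`).
#' @export
rho_st <- function(ds, pairs = "all") {
  pr <- resolve_pairs(ds, pairs)
  glob <- list(); perloc <- list()
  for (k in seq_len(nrow(pr))) {
    id1 <- pr[k, 1]; id2 <- pr[k, 2]
    num <- den <- 0
    rows <- data.frame(pop1 = id1, pop2 = id2, locus = ds$loci,
                       rho_st = NA_real_)
    for (j in seq_along(ds$loci)) {
      x1 <- alleles_at(ds$populations[[id1]], j)
      x2 <- alleles_at(ds$populations[[id2]], j)
      if (length(x1) < 2L || length(x2) < 2L) next
      cmp <- size_components(list(x1, x2))
      rows$rho_st[j] <- ratio_or_na(cmp["s2a"], cmp["s2a"] + cmp["s2w"])
      num <- num + cmp["s2a"]; den <- den + cmp["s2a"] + cmp["s2w"]
    }
    glob[[k]] <- data.frame(pop1 = id1, pop2 = id2,
                            rho_st = unname(ratio_or_na(num, den)),
                            row.names = NULL)
    perloc[[k]] <- rows
  }
  structure(list(global = do.call(rbind, glob),
                 per_locus = do.call(rbind, perloc),
                 species = ds$species),
            class = "pairwise_rho", null_corrected = FALSE)
}

# one-way ANOVA variance components of allele size over gene copies
size_components <- function(groups) {
  n_i <- lengths(groups)
  r <- length(groups)
  N <- sum(n_i)
  means <- vapply(groups, mean, 0)
  gm <- sum(unlist(groups)) / N
  ssa <- sum(n_i * (means - gm)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  msa <- ssa / (r - 1)
  msw <- ssw / (N - r)
  n0 <- (N - sum(n_i^2) / N) / (r - 1)
  c(s2a = (msa - msw) / n0, s2w = msw)
}

#' Lay out pairwise results as a square matrix
#'
#' @param x A `pairwise_fst` or `pairwise_rho` object.
#' @param value Column of `x$global` to place in the lower triangle.
#' @param upper Optional data frame `pop1`, `pop2`, `p` whose values
#'   fill the upper triangle (e.g. exact-test p-values, the conventional
#'   differentiation-table layout).
#' @return A square numeric matrix over the populations involved.
#' @export
pairwise_matrix <- function(x, value = "fst_ena", upper = NULL) {
  g <- x$global
  ids <- unique(c(g$pop1, g$pop2))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  for (k in seq_len(nrow(g))) {
    m[g$pop2[k], g$pop1[k]] <- g[[value]][k]
  }
  if (!is.null(upper)) {
    for (k in seq_len(nrow(upper))) {
      m[upper$pop1[k], upper$pop2[k]] <- upper$p[k]
    }
  }
  m
}
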