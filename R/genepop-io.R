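#' Read a GenePop genotype file
#'
#' Parses the classical GenePop layout: a title line, one locus name per
#' line (or a single comma-separated line), `Pop` separator lines, then
#' one individual per line as `name ,  a1a2 a1a2 ...` with alleles packed
#' at a fixed digit width. `00`/`000` encodes a missing allele; a
#' genotype is missing only when both alleles are missing — half-missing
#' calls are rejected.
#'
#' @param path Path to a GenePop file.
#' @param allele_digits Width of one allele code: 2 or 3.
#' @param species Species label to attach to the dataset (defaults to the
#'   file's title line).
#' @param pop_ids Optional character vector of population ids, one per
#'   `Pop` block. By default each block is named after the GenePop
#'   convention: the name of its last individual.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, allele_digits = 3, species = NULL,
                         pop_ids = NULL) {
  if (!allele_digits %in% c(2L, 3L)) {
    stop("allele_digits must be 2 or 3, got ", allele_digits)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GenePop file: fewer than 3 lines")
  title <- trimws(lines[1])

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names before first 'Pop'")

  blocks <- split(seq_along(lines)[seq_along(lines) > first_pop &
                                     !is_pop],
                  cumsum(is_pop)[seq_along(lines) > first_pop & !is_pop])
  if (any(lengths(blocks) == 0L)) stop("empty 'Pop' block")

  miss_code <- strrep("0", allele_digits)
  parse_block <- function(idx) {
    n <- length(idx)
    g <- array(NA_integer_, dim = c(n, length(loci), 2L))
    nm <- character(n)
    for (k in seq_len(n)) {
      ln <- lines[idx[k]]
      parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(parts) < 2L) {
        stop("line ", idx[k], ": expected 'name , genotypes'")
      }
      nm[k] <- trimws(parts[1])
      calls <- strsplit(trimws(paste(parts[-1], collapse = ",")),
                        "[[:space:]]+")[[1]]
      calls <- calls[nzchar(calls)]
      if (length(calls) != length(loci)) {
        stop("line ", idx[k], ": ", length(calls),
             " genotype fields for ", length(loci), " loci")
      }
      if (any(nchar(calls) != 2L * allele_digits)) {
        bad <- which(nchar(calls) != 2L * allele_digits)[1]
        stop("line ", idx[k], ": call '", calls[bad],
             "' does not match allele width ", allele_digits)
      }
      a1 <- substr(calls, 1L, allele_digits)
      a2 <- substr(calls, allele_digits + 1L, 2L * allele_digits)
      m1 <- a1 == miss_code
      m2 <- a2 == miss_code
      if (any(xor(m1, m2))) {
        stop("line ", idx[k], ": half-missing genotype call")
      }
      v1 <- suppressWarnings(as.integer(a1))
      v2 <- suppressWarnings(as.integer(a2))
      if (anyNA(v1) || anyNA(v2)) {
        stop("line ", idx[k], ": non-numeric allele code")
      }
      v1[m1] <- NA_integer_
      v2[m2] <- NA_integer_
      g[k, , 1] <- v1
      g[k, , 2] <- v2
    }
    list(names = nm, genotypes = g)
  }

  parsed <- lapply(blocks, parse_block)
  if (is.null(pop_ids)) {
    pop_ids <- vapply(parsed, function(b) b$names[length(b$names)],
                      character(1))
    if (anyDuplicated(pop_ids)) {
      pop_ids <- make.unique(pop_ids, sep = "_")
    }
  } else if (length(pop_ids) != length(parsed)) {
    stop(length(pop_ids), " pop_ids supplied for ", length(parsed),
         " Pop blocks")
  }
  pops <- mapply(function(b, id) {
    population_sample(id, id, b$genotypes, b$names)
  }, parsed, pop_ids, SIMPLIFY = FALSE)
  genotype_dataset(species %||% title, loci, pops)
}

#' Write a dataset as a GenePop file
#'
#' Emits a file that [read_genepop()] parses back to an identical
#' dataset (same locus names, population ids as the `pop_ids` override,
#' allele calls and missingness).
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @param allele_digits Width of one allele code: 2 or 3. All allele
#'   codes must fit (`< 10^allele_digits`).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, allele_digits = 3) {
  if (!allele_digits %in% c(2L, 3L)) {
    stop("allele_digits must be 2 or 3, got ", allele_digits)
  }
  mx <- max(unlist(lapply(ds$populations,
                          function(p) p$genotypes[!is.na(p$genotypes)])),
            0L)
  if (mx >= 10^allele_digits) {
    stop("allele code ", mx, " does not fit ", allele_digits, " digits")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ds$species, con)
  writeLines(ds$loci, con)
  for (p in ds$populations) {
    writeLines("Pop", con)
    g <- p$genotypes
    enc <- function(a) {
      a[is.na(a)] <- 0L
      formatC(a, width = allele_digits, flag = "0")
    }
    for (i in seq_len(dim(g)[1])) {
      calls <- paste0(enc(g[i, , 1]), enc(g[i, , 2]))
      writeLines(paste0(p$individuals[i], " ,  ",
                        paste(calls, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read genotypes from the CSV dialect
#'
#' One row per individual: columns `id`, `population`, then one column
#' per locus holding `a1/a2` (e.g. `"152/156"`) with `"."` for a missing
#' genotype.
#'
#' @param path Path to a CSV file.
#' @param species Species label (default: file name without extension).
#' @return A [genotype_dataset()].
#' @export
read_genotypes_csv <- function(path, species = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3L || !all(c("id", "population") %in% names(df)[1:2])) {
    stop("CSV dialect requires columns id, population, then loci")
  }
  loci <- names(df)[-(1:2)]
  pops <- split(df, factor(df$population, levels = unique(df$population)))
  pop_objs <- lapply(pops, function(sub) {
    g <- array(NA_integer_, dim = c(nrow(sub), length(loci), 2L))
    for (j in seq_along(loci)) {
      cell <- trimws(as.character(sub[[loci[j]]]))
      ok <- cell != "." & nzchar(cell)
      parts <- strsplit(cell[ok], "/", fixed = TRUE)
      if (any(lengths(parts) != 2L)) {
        stop("locus ", loci[j], ": genotype cells must be 'a1/a2' or '.'")
      }
      g[ok, j, 1] <- as.integer(vapply(parts, `[`, "", 1L))
      g[ok, j, 2] <- as.integer(vapply(parts, `[`, "", 2L))
    }
    population_sample(sub$population[1], sub$population[1], g, sub$id)
  })
  if (is.null(species)) species <- sub("\\.[^.]*$", "", basename(path))
  genotype_dataset(species, loci, pop_objs)
}

#' Write genotypes in the CSV dialect
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(ds, path) {
  rows <- lapply(ds$populations, function(p) {
    g <- p$genotypes
    cells <- matrix("", dim(g)[1], length(ds$loci))
    for (j in seq_along(ds$loci)) {
      a1 <- g[, j, 1]; a2 <- g[, j, 2]
      cells[, j] <- ifelse(is.na(a1), ".", paste0(a1, "/", a2))
    }
    out <- data.frame(id = p$individuals, population = p$id,
                      stringsAsFactors = FALSE)
    out[ds$loci] <- as.data.frame(cells, stringsAsFactors = FALSE)
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
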