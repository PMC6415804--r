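#' Diploid SSR genotype matrix
#'
#' The central container of the package: a rectangular grid of diploid
#' genotypes (unordered allele pairs) for a set of individuals at a set of
#' microsatellite loci, with a population label per individual and optional
#' region labels and coordinates. Alleles are positive integer labels
#' (fragment sizes in bp or repeat counts); a missing genotype is recorded as
#' `NA` in both allele slots. Half-missing genotypes (one allele called, one
#' not) are promoted to fully missing with a warning, since every downstream
#' estimator assumes either 0 or 2 gene copies per individual and locus.
#'
#' @param a1,a2 integer matrices, individuals x loci, the two allele labels
#'   per genotype (`NA` = missing). Order within the pair carries no meaning.
#' @param pop character or factor of population labels, one per individual.
#' @param loci character vector of unique locus names.
#' @param ind character vector of individual identifiers.
#' @param region optional character vector of sub-population labels.
#' @param coords optional two-column matrix (lat, lon) per individual.
#' @return An object of class `genotype_matrix` with components `a1`, `a2`,
#'   `pop`, `region`, `coords`, `loci`, `ind`.
#' @export
genotype_matrix <- function(a1, a2, pop, loci = colnames(a1), ind = rownames(a1),
                            region = NULL, coords = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("allele matrices must have equal dimensions")
  if (nrow(a1) < 1L || ncol(a1) < 1L) stop("need >= 1 individual and >= 1 locus")
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(a1)))
  if (is.null(ind)) ind <- paste0("ind", seq_len(nrow(a1)))
  if (anyDuplicated(loci)) stop("locus names must be unique")
  if (length(pop) != nrow(a1)) stop("one population label per individual required")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) promoted to fully missing")
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  if (any(c(a1, a2) <= 0L, na.rm = TRUE)) stop("allele labels must be positive")
  # canonical within-pair order so identical genotypes compare equal
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(ind, loci)
  if (!is.null(region) && length(region) != nrow(a1))
    stop("one region label per individual required")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(a1) || ncol(coords) != 2L)
      stop("coords must be an individuals x 2 (lat, lon) matrix")
    colnames(coords) <- c("lat", "lon")
  }
  structure(list(a1 = a1, a2 = a2, pop = as.character(pop),
                 region = if (is.null(region)) NULL else as.character(region),
                 coords = coords, loci = loci, ind = ind),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ind), "individuals x", length(x$loci),
      "loci;", length(unique(x$pop)), "population(s)\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$ind), length(x$loci))

#' Subset a genotype matrix by individuals
#'
#' @param gm a [genotype_matrix()].
#' @param i integer or logical index over individuals.
#' @return A `genotype_matrix` restricted to the selected individuals.
#' @export
subset_individuals <- function(gm, i) {
  genotype_matrix(gm$a1[i, , drop = FALSE], gm$a2[i, , drop = FALSE],
                  pop = gm$pop[i], loci = gm$loci, ind = gm$ind[i],
                  region = if (is.null(gm$region)) NULL else gm$region[i],
                  coords = if (is.null(gm$coords)) NULL else gm$coords[i, , drop = FALSE])
}

#' Read a GenePop file
#'
#' Parses the widely used GenePop 4.x text dialect: a title line, one locus
#' name per line (or comma-separated on one line), and `POP`-delimited blocks
#' of `id , a1a2 a1a2 ...` rows in 2- or 3-digit allele coding. An all-zero
#' allele code is the missing sentinel. Population labels are taken from the
#' identifier of the last individual of each block (the GenePop convention)
#' unless `pop_labels` is given.
#'
#' @param path file path.
#' @param pop_labels optional character vector of labels, one per POP block.
#' @param quiet suppress the record-count message.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, pop_labels = NULL, quiet = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3L) stop("not a GenePop file: fewer than 3 non-blank lines")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP line found")
  loci_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in header")
  nloc <- length(loci)
  blocks <- cumsum(is_pop)
  rows <- which(!is_pop & seq_along(lines) > first_pop - 1L)
  rows <- rows[blocks[rows] >= 1L]
  if (!length(rows)) stop("no genotype rows found")
  n_blocks <- max(blocks)
  counts <- tabulate(blocks[rows], n_blocks)
  if (any(counts == 0L)) stop("empty POP block (block ", which(counts == 0L)[1L], ")")

  ids <- character(length(rows)); popb <- blocks[rows]
  a1 <- matrix(NA_integer_, length(rows), nloc)
  a2 <- matrix(NA_integer_, length(rows), nloc)
  for (r in seq_along(rows)) {
    ln <- lines[rows[r]]
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L) stop("line ", rows[r], ": no comma after individual id")
    ids[r] <- trimws(parts[1L])
    gts <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(gts) != nloc)
      stop("line ", rows[r], ": expected ", nloc, " genotypes, found ", length(gts))
    w <- nchar(gts)
    if (any(w %% 2L != 0L) || length(unique(w)) != 1L)
      stop("line ", rows[r], ": odd or inconsistent allele-code width")
    d <- w[1L] / 2L
    if (!d %in% c(2L, 3L))
      stop("line ", rows[r], ": allele coding must be 2- or 3-digit, got ", d)
    x1 <- suppressWarnings(as.integer(substr(gts, 1L, d)))
    x2 <- suppressWarnings(as.integer(substr(gts, d + 1L, 2L * d)))
    if (anyNA(x1) || anyNA(x2)) stop("line ", rows[r], ": non-numeric allele code")
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    a1[r, ] <- x1; a2[r, ] <- x2
  }
  if (is.null(pop_labels)) {
    last_of_block <- vapply(seq_len(n_blocks), function(b) max(which(popb == b)), 0L)
    pop_labels <- ids[last_of_block]
  }
  if (length(pop_labels) != n_blocks)
    stop("need ", n_blocks, " population labels, got ", length(pop_labels))
  if (!quiet)
    message("read_genepop: ", length(rows), " individuals, ", nloc, " loci, ",
            n_blocks, " populations")
  genotype_matrix(a1, a2, pop = pop_labels[popb], loci = loci, ind = ids)
}

#' Write a GenePop file
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param digits 2 or 3; allele-code width. All allele labels must be
#'   `< 10^digits`.
#' @param title first line of the file.
#' @return `path`, invisibly. `read_genepop(write_genepop(gm))` round-trips
#'   the genotype content exactly.
#' @export
write_genepop <- function(gm, path, digits = 3L, title = "guavapop export") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  mx <- suppressWarnings(max(c(gm$a1, gm$a2), na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop("allele label ", mx, " does not fit in ", digits, "-digit coding")
  fmt <- function(a) {
    out <- formatC(ifelse(is.na(a), 0L, a), width = digits, flag = "0")
    matrix(out, nrow = nrow(gm$a1))
  }
  s1 <- fmt(gm$a1); s2 <- fmt(gm$a2)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, gm$loci), con)
  pops <- unique(gm$pop)
  for (p in pops) {
    writeLines("POP", con)
    idx <- which(gm$pop == p)
    # last individual of the block carries the population label on re-read
    ids <- gm$ind[idx]; ids[length(ids)] <- p
    for (j in seq_along(idx)) {
      i <- idx[j]
      writeLines(paste0(ids[j], " ,  ",
                        paste0(s1[i, ], s2[i, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a delimited genotype table
#'
#' One row per individual: `id, pop, region, lat, lon`, then two columns per
#' locus named `<locus>.1`, `<locus>.2`. Empty cells or `NA` are missing.
#'
#' @param path file path.
#' @param sep field separator.
#' @param quiet suppress the record-count message.
#' @return A [genotype_matrix()].
#' @export
read_genotype_table <- function(path, sep = "\t", quiet = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  fixed <- c("id", "pop", "region", "lat", "lon")
  gcols <- setdiff(names(df), fixed)
  if (length(gcols) %% 2L != 0L) stop("odd number of allele columns")
  loci <- unique(sub("\\.[12]$", "", gcols))
  a1 <- as.matrix(df[, paste0(loci, ".1"), drop = FALSE])
  a2 <- as.matrix(df[, paste0(loci, ".2"), drop = FALSE])
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  coords <- if (all(c("lat", "lon") %in% names(df)))
    cbind(lat = df$lat, lon = df$lon) else NULL
  if (!quiet)
    message("read_genotype_table: ", nrow(df), " individuals, ", length(loci), " loci")
  genotype_matrix(a1, a2, pop = df$pop, loci = loci, ind = as.character(df$id),
                  region = if ("region" %in% names(df)) df$region else NULL,
                  coords = coords)
}

#' Write the delimited genotype table dialect
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gm, path, sep = "\t") {
  df <- data.frame(id = gm$ind, pop = gm$pop, stringsAsFactors = FALSE)
  if (!is.null(gm$region)) df$region <- gm$region
  if (!is.null(gm$coords)) { df$lat <- gm$coords[, 1]; df$lon <- gm$coords[, 2] }
  for (l in seq_along(gm$loci)) {
    df[[paste0(gm$loci[l], ".1")]] <- gm$a1[, l]
    df[[paste0(gm$loci[l], ".2")]] <- gm$a2[, l]
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-group allele frequencies
#'
#' Counts gene copies per (locus, group) cell, excluding missing genotypes,
#' and normalizes to frequencies. A cell with zero non-missing calls yields an
#' empty frequency vector with `n = 0` (downstream statistics must handle it).
#'
#' @param gm a [genotype_matrix()].
#' @param partition `"pop"`, `"region"`, or `"all"`.
#' @return An `allele_freq_table`: list with `freq[[locus]][[group]]` (named
#'   numeric vectors summing to 1), integer matrix `n` (loci x groups of
#'   gene-copy counts), `groups`, `loci`.
#' @export
allele_frequencies <- function(gm, partition = c("pop", "region", "all")) {
  partition <- match.arg(partition)
  grp <- switch(partition,
                pop = gm$pop,
                region = {
                  if (is.null(gm$region)) stop("no region labels present")
                  gm$region
                },
                all = rep("all", length(gm$ind)))
  groups <- unique(grp)
  nloc <- length(gm$loci)
  n <- matrix(0L, nloc, length(groups), dimnames = list(gm$loci, groups))
  freq <- vector("list", nloc); names(freq) <- gm$loci
  for (l in seq_len(nloc)) {
    freq[[l]] <- vector("list", length(groups)); names(freq[[l]]) <- groups
    for (g in seq_along(groups)) {
      idx <- which(grp == groups[g])
      copies <- c(gm$a1[idx, l], gm$a2[idx, l])
      copies <- copies[!is.na(copies)]
      n[l, g] <- length(copies)
      if (length(copies)) {
        tab <- table(copies)
        f <- as.numeric(tab) / length(copies)
        names(f) <- names(tab)
        freq[[l]][[g]] <- f
      } else freq[[l]][[g]] <- numeric(0)
    }
  }
  structure(list(freq = freq, n = n, groups = groups, loci = gm$loci),
            class = "allele_freq_table")
}
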