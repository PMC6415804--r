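#' Total and frequent allele counts per population
#'
#' Counts, summed across loci, the number of distinct alleles observed in a
#' population and the number whose within-population frequency exceeds a
#' threshold (the classic "frequent allele" count at > 0.05).
#'
#' @param aft an [allele_frequencies()] table.
#' @param pop group label; must be one of `aft$groups`.
#' @param freq_threshold frequency strictly above which an allele counts as
#'   frequent; default 0.05.
#' @return `c(A = ..., A_freq = ...)`.
#' @export
count_alleles <- function(aft, pop, freq_threshold = 0.05) {
  stopifnot(freq_threshold >= 0, freq_threshold < 1)
  if (!pop %in% aft$groups) stop("unknown group: ", pop)
  A <- 0L; Af <- 0L
  for (l in seq_along(aft$loci)) {
    f <- aft$freq[[l]][[pop]]
    A <- A + length(f)
    Af <- Af + sum(f > freq_threshold)
  }
  c(A = A, A_freq = Af)
}

#' Private alleles per population
#'
#' An allele is private to a population when its frequency is positive there
#' and zero in every other population; counts are totals across loci.
#'
#' @param aft an [allele_frequencies()] table with at least two groups.
#' @param freq_threshold threshold for the frequent-private count.
#' @return data.frame with columns `pop`, `PA`, `PA_freq`.
#' @export
private_alleles <- function(aft, freq_threshold = 0.05) {
  if (length(aft$groups) < 2L) stop("private alleles undefined for a single population")
  out <- data.frame(pop = aft$groups, PA = 0L, PA_freq = 0L,
                    stringsAsFactors = FALSE)
  for (l in seq_along(aft$loci)) {
    fl <- aft$freq[[l]]
    alleles <- unique(unlist(lapply(fl, names)))
    for (a in alleles) {
      present <- vapply(aft$groups, function(g) {
        f <- fl[[g]]; !is.na(f[a]) && !is.null(f[a]) && isTRUE(f[a] > 0)
      }, logical(1))
      if (sum(present) == 1L) {
        g <- which(present)
        out$PA[g] <- out$PA[g] + 1L
        if (fl[[g]][a] > freq_threshold) out$PA_freq[g] <- out$PA_freq[g] + 1L
      }
    }
  }
  out
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g_copies`
#' gene copies, by hypergeometric rarefaction:
#' `AR = sum_i [1 - choose(n - n_i, g) / choose(n, g)]` with `n_i` the copy
#' count of allele i. Cells whose gene-copy count is below `g_copies` are
#' returned as `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param g_copies standardized number of gene copies; default is the minimum
#'   (locus, population) gene-copy count, the largest value valid everywhere.
#' @return list with `per_cell` (loci x pops matrix) and `per_pop` (means
#'   across loci).
#' @export
allelic_richness <- function(gm, g_copies = NULL) {
  aft <- allele_frequencies(gm, "pop")
  if (is.null(g_copies)) g_copies <- min(aft$n)
  if (g_copies < 1L) stop("g_copies must be >= 1")
  if (g_copies > min(aft$n))
    stop("g_copies exceeds the smallest (locus, population) gene-copy count (",
         min(aft$n), ")")
  ar <- matrix(NA_real_, length(aft$loci), length(aft$groups),
               dimnames = list(aft$loci, aft$groups))
  for (l in seq_along(aft$loci)) for (g in seq_along(aft$groups)) {
    n <- aft$n[l, g]
    if (n < g_copies || n == 0L) next
    ni <- round(aft$freq[[l]][[g]] * n)
    # 1 - C(n - ni, g)/C(n, g); combinations with n - ni < g contribute 1
    ar[l, g] <- sum(1 - exp(lchoose(n - ni, g_copies) - lchoose(n, g_copies)))
  }
  list(per_cell = ar, per_pop = colMeans(ar, na.rm = TRUE), g_copies = g_copies)
}

#' Observed heterozygosity
#'
#' Fraction of non-missing individuals carrying two distinct alleles, per
#' locus, with the across-locus mean.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @return list with `per_locus` and `mean`. All-missing cells are `NA` and
#'   excluded from the mean with a warning.
#' @export
observed_heterozygosity <- function(gm, pop) {
  idx <- which(gm$pop == pop)
  het <- vapply(seq_along(gm$loci), function(l) {
    a1 <- gm$a1[idx, l]; a2 <- gm$a2[idx, l]
    ok <- !is.na(a1)
    if (!any(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, 0)
  names(het) <- gm$loci
  if (anyNA(het)) warning("all-missing locus cell(s) excluded from mean H_O")
  list(per_locus = het, mean = mean(het, na.rm = TRUE))
}

#' Gene diversity (expected heterozygosity)
#'
#' Nei's unbiased estimator `H_E = n/(n-1) * (1 - sum p_i^2)` per locus with
#' `n` the gene-copy count, plus the across-locus mean. Set
#' `unbiased = FALSE` for the plug-in estimator `1 - sum p_i^2`.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @param unbiased apply the small-sample `n/(n-1)` correction (default).
#' @return list with `per_locus` and `mean`; cells with fewer than 2 gene
#'   copies are `NA`.
#' @export
gene_diversity <- function(gm, pop, unbiased = TRUE) {
  aft <- allele_frequencies(gm, "pop")
  if (!pop %in% aft$groups) stop("unknown population: ", pop)
  he <- vapply(seq_along(aft$loci), function(l) {
    n <- aft$n[l, pop]
    if (n < 2L) return(NA_real_)
    h <- 1 - sum(aft$freq[[l]][[pop]]^2)
    if (unbiased) h * n / (n - 1) else h
  }, 0)
  names(he) <- aft$loci
  list(per_locus = he, mean = mean(he, na.rm = TRUE))
}

#' Multilocus inbreeding coefficient
#'
#' `F_IS = 1 - mean_loci(H_O) / mean_loci(H_E)` — the ratio of across-locus
#' means, the basic-statistics convention (not the mean of per-locus ratios).
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @return scalar F_IS; `NA` if mean H_E is zero (no polymorphism).
#' @export
fis <- function(gm, pop) {
  he <- gene_diversity(gm, pop)$mean
  ho <- observed_heterozygosity(gm, pop)$mean
  if (is.na(he) || he == 0) return(NA_real_)
  1 - ho / he
}

#' Per-individual inbreeding coefficient by maximum likelihood
#'
#' Maximizes over a grid F in {0, 0.01, ..., 1} the product over loci of the
#' genotype probability given the individual's population allele frequencies:
#' heterozygote i/j contributes `(1-F) * 2 p_i p_j`, homozygote i/i
#' contributes `F * p_i + (1-F) * p_i^2`.
#'
#' @param gm a [genotype_matrix()].
#' @param individual identifier or row index.
#' @param grid_step grid resolution; default 0.01.
#' @return list with `F` (the grid maximizer) and `loglik` at the maximum.
#' @export
individual_inbreeding <- function(gm, individual, grid_step = 0.01) {
  i <- if (is.character(individual)) match(individual, gm$ind) else individual
  if (is.na(i)) stop("unknown individual: ", individual)
  aft <- allele_frequencies(gm, "pop")
  p <- gm$pop[i]
  Fgrid <- seq(0, 1, by = grid_step)
  ll <- numeric(length(Fgrid))
  used <- 0L
  for (l in seq_along(gm$loci)) {
    a1 <- gm$a1[i, l]; a2 <- gm$a2[i, l]
    if (is.na(a1)) next
    f <- aft$freq[[l]][[p]]
    p1 <- f[as.character(a1)]
    if (a1 == a2) {
      ll <- ll + log(Fgrid * p1 + (1 - Fgrid) * p1^2)
    } else {
      p2 <- f[as.character(a2)]
      ll <- ll + log((1 - Fgrid) * 2 * p1 * p2)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("individual has no non-missing genotypes")
  k <- which.max(ll)
  list(F = Fgrid[k], loglik = ll[k])
}

# multinomial (Levene) probability of a genotype table given allele counts,
# on the log scale: log[ n! * prod(a_u!) * 2^h / ( (2n)! * prod(n_gt!) ) ]
log_table_prob <- function(gt_counts, allele_counts) {
  n <- sum(gt_counts)
  h <- sum(gt_counts[attr(gt_counts, "het")])
  lgamma(n + 1) + sum(lgamma(allele_counts + 1)) + h * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(gt_counts + 1))
}

genotype_table_counts <- function(a1, a2) {
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  tab <- table(key)
  counts <- as.integer(tab)
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  attr(counts, "het") <- vapply(parts, function(x) x[1] != x[2], logical(1))
  counts
}

#' Monte-Carlo exact Hardy-Weinberg test
#'
#' Exact-test statistic is the conditional (Levene) probability of the
#' observed genotype table given the allele counts; the null distribution is
#' generated by randomly re-pairing the observed gene copies. The p-value is
#' the proportion of tables at most as probable as the observed one, with the
#' observed table included in numerator and denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param locus locus name.
#' @param pop population label.
#' @param n_perm number of Monte-Carlo tables (>= 100).
#' @return p-value in (0, 1]; 1 for a monomorphic locus.
#' @export
hwe_test <- function(gm, locus, pop, n_perm = 10000L) {
  stopifnot(n_perm >= 100L)
  l <- match(locus, gm$loci)
  idx <- which(gm$pop == pop)
  a1 <- gm$a1[idx, l]; a2 <- gm$a2[idx, l]
  ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
  copies <- c(a1, a2)
  if (length(unique(copies)) < 2L) return(1)
  allele_counts <- as.integer(table(copies))
  obs <- log_table_prob(genotype_table_counts(a1, a2), allele_counts)
  n <- length(a1)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(copies)
    lp <- log_table_prob(genotype_table_counts(perm[1:n], perm[(n + 1):(2 * n)]),
                         allele_counts)
    if (lp <= obs + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

g_statistic <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  i <- tab > 0
  2 * sum(tab[i] * log(tab[i] / e[i]))
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' G-statistic of the two-locus genotype contingency table; the null
#' distribution is obtained by permuting individuals' genotypes at the second
#' locus. This is a permutation stand-in for the likelihood-ratio LD test of
#' standard toolchains (which do not document their exact variant).
#'
#' @param gm a [genotype_matrix()].
#' @param locusA,locusB locus names.
#' @param pop population label.
#' @param n_perm number of permutations.
#' @return p-value `(1 + #(G_perm >= G_obs)) / (1 + n_perm)`; 1 if either
#'   locus is monomorphic in the population.
#' @export
ld_test <- function(gm, locusA, locusB, pop, n_perm = 10000L) {
  la <- match(locusA, gm$loci); lb <- match(locusB, gm$loci)
  idx <- which(gm$pop == pop)
  ga <- paste(gm$a1[idx, la], gm$a2[idx, la])
  gb <- paste(gm$a1[idx, lb], gm$a2[idx, lb])
  ok <- !is.na(gm$a1[idx, la]) & !is.na(gm$a1[idx, lb])
  ga <- factor(ga[ok]); gb <- factor(gb[ok])
  if (nlevels(ga) < 2L || nlevels(gb) < 2L) return(1)
  obs <- g_statistic(table(ga, gb))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (g_statistic(table(ga, sample(gb))) >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Monte-Carlo test of a gene-diversity difference between populations
#'
#' Statistic: absolute difference of across-locus mean H_E between the two
#' populations; the null is generated by randomly reassigning individuals to
#' the two populations, preserving sizes.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @param n_perm number of permutations.
#' @return p-value.
#' @export
he_difference_test <- function(gm, popA, popB, n_perm = 1000L) {
  ia <- which(gm$pop == popA); ib <- which(gm$pop == popB)
  if (!length(ia) || !length(ib)) stop("empty population")
  rows <- c(ia, ib)
  nA <- length(ia); nt <- length(rows)
  # pre-index alleles per locus so each permutation is a pair of tabulate()s
  loc <- lapply(seq_along(gm$loci), function(l) {
    al <- sort(unique(c(gm$a1[rows, l], gm$a2[rows, l])))
    al <- al[!is.na(al)]
    cbind(match(gm$a1[rows, l], al), match(gm$a2[rows, l], al))
  })
  nall <- vapply(loc, function(x) max(x, na.rm = TRUE), 0)
  mean_he <- function(sel) {
    he <- vapply(seq_along(loc), function(l) {
      idx <- c(loc[[l]][sel, 1], loc[[l]][sel, 2])
      idx <- idx[!is.na(idx)]
      n <- length(idx)
      if (n < 2L) return(NA_real_)
      p <- tabulate(idx, nall[l]) / n
      (1 - sum(p^2)) * n / (n - 1)
    }, 0)
    mean(he, na.rm = TRUE)
  }
  obs <- abs(mean_he(seq_len(nA)) - mean_he((nA + 1):nt))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nt)
    d <- abs(mean_he(perm[seq_len(nA)]) - mean_he(perm[(nA + 1):nt]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector.
#' @param m number of tests corrected for (defaults to `length(p_values)`).
#' @param alpha family-wise error rate.
#' @return data.frame with `p`, `threshold` (`alpha/m`) and `significant`
#'   (`p < alpha/m`).
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  if (!length(p_values)) {
    return(data.frame(p = numeric(0), threshold = numeric(0),
                      significant = logical(0)))
  }
  if (m < length(p_values)) stop("m must be >= number of tests")
  data.frame(p = p_values, threshold = alpha / m,
             significant = p_values < alpha / m)
}

#' Per-population diversity summary table
#'
#' One row per population plus an `overall` row: sample size N, total and
#' frequent allele counts (A), private alleles (PA), mean rarefied allelic
#' richness (AR), observed heterozygosity (H_O), gene diversity (H_E) and
#' inbreeding coefficient (F_IS). A and PA are totals across loci; AR, H_O
#' and H_E are across-locus means.
#'
#' @param gm a [genotype_matrix()].
#' @param g_copies rarefaction size for AR (see [allelic_richness()]).
#' @param freq_threshold the "frequent allele" cutoff.
#' @return data.frame mirroring the conventional diversity-table layout.
#' @export
diversity_table <- function(gm, g_copies = NULL, freq_threshold = 0.05) {
  aft <- allele_frequencies(gm, "pop")
  pops <- aft$groups
  ar <- allelic_richness(gm, g_copies)
  pa <- private_alleles(aft, freq_threshold)
  rows <- lapply(pops, function(p) {
    ca <- count_alleles(aft, p, freq_threshold)
    data.frame(pop = p, N = sum(gm$pop == p), A = ca["A"], A_freq = ca["A_freq"],
               PA = pa$PA[pa$pop == p], PA_freq = pa$PA_freq[pa$pop == p],
               AR = ar$per_pop[p],
               H_O = observed_heterozygosity(gm, p)$mean,
               H_E = gene_diversity(gm, p)$mean,
               F_IS = fis(gm, p), row.names = NULL)
  })
  all_gm <- genotype_matrix(gm$a1, gm$a2, pop = rep("overall", length(gm$ind)),
                            loci = gm$loci, ind = gm$ind)
  aft_all <- allele_frequencies(all_gm, "pop")
  ca <- count_alleles(aft_all, "overall", freq_threshold)
  overall <- data.frame(pop = "overall", N = length(gm$ind),
                        A = ca["A"], A_freq = ca["A_freq"],
                        PA = NA_integer_, PA_freq = NA_integer_,
                        AR = allelic_richness(all_gm, ar$g_copies)$per_pop["overall"],
                        H_O = observed_heterozygosity(all_gm, "overall")$mean,
                        H_E = gene_diversity(all_gm, "overall")$mean,
                        F_IS = fis(all_gm, "overall"), row.names = NULL)
  out <- rbind(do.call(rbind, rows), overall)
  rownames(out) <- NULL
  out
}
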