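#' EM estimate of the null-allele frequency at one locus in one population
#'
#' Model: a null allele of frequency `r` segregates with the visible alleles
#' under Hardy-Weinberg proportions. A visible homozygote class i/i pools true
#' i/i genotypes and i/null heterozygotes; null/null individuals do not
#' amplify (blanks). Two blank conventions are supported:
#'
#' * `blanks = <count>`: blanks are known null homozygotes and enter the
#'   complete-data gene counting directly.
#' * `blanks = NULL` (default): non-amplifying individuals are
#'   indistinguishable from failed PCR, so the likelihood conditions on a
#'   visible genotype; the E-step imputes the expected number of unobserved
#'   null homozygotes `n * r^2 / (1 - r^2)`.
#'
#' The E-step splits each visible homozygote class by
#' `p_i / (p_i + 2r)`; the M-step re-estimates all frequencies by gene
#' counting. Iteration stops when `|delta r| < tol`.
#'
#' @param a1,a2 integer vectors of visible allele pairs (missing genotypes
#'   must already be removed).
#' @param blanks count of blank (non-amplifying) individuals, or `NULL` to
#'   marginalize blanks out.
#' @param tol convergence tolerance on r.
#' @param max_iter iteration cap.
#' @return list with `r`, `p_visible` (named, sums to `1 - r`), `iterations`,
#'   `converged`, and `loglik` (observed-data log-likelihood trace).
#' @export
em_null_frequency <- function(a1, a2, blanks = NULL, tol = 1e-8,
                              max_iter = 10000L) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n_vis <- length(a1)
  known_blanks <- !is.null(blanks)
  B <- if (known_blanks) as.integer(blanks) else 0L
  if (n_vis == 0L) {
    if (B > 0L)  # every individual blank: boundary estimate
      return(list(r = 1, p_visible = numeric(0), iterations = 0L,
                  converged = FALSE, loglik = numeric(0)))
    stop("no genotypes supplied")
  }
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  hom <- i1 == i2
  n_hom <- tabulate(i1[hom], k)                # per-allele homozygote counts
  het_copies <- tabulate(c(i1[!hom], i2[!hom]), k)
  if (sum(n_hom) == 0L && B == 0L) {
    p <- tabulate(c(i1, i2), k) / (2 * n_vis)
    names(p) <- alleles
    return(list(r = 0, p_visible = p, iterations = 0L, converged = TRUE,
                loglik = numeric(0)))
  }

  p <- tabulate(c(i1, i2), k) / (2 * n_vis) * 0.95
  r <- 0.05
  ll_obs <- function(p, r) {
    ll <- sum(n_hom * log(pmax(p^2 + 2 * p * r, 1e-300))) +
      sum(het_copies * log(pmax(p, 1e-300))) + sum(!hom) * log(2)
    if (known_blanks) ll + 2 * B * log(max(r, 1e-300))
    else ll - n_vis * log(max(1 - r^2, 1e-300))
  }
  trace <- numeric(0)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    B_eff <- if (known_blanks) B else n_vis * r^2 / max(1 - r^2, 1e-12)
    # E-step: split visible homozygote classes into true hom vs het-with-null
    denom <- p + 2 * r
    e_hom <- ifelse(denom > 0, n_hom * p / denom, n_hom)
    e_het_null <- n_hom - e_hom
    copies <- 2 * e_hom + e_het_null + het_copies
    copies_null <- sum(e_het_null) + 2 * B_eff
    tot <- sum(copies) + copies_null
    p_new <- copies / tot
    r_new <- copies_null / tot
    trace <- c(trace, ll_obs(p_new, r_new))
    done <- abs(r_new - r) < tol
    p <- p_new; r <- r_new
    if (done) { converged <- TRUE; break }
  }
  names(p) <- alleles
  list(r = r, p_visible = p, iterations = it, converged = converged,
       loglik = trace)
}

#' Null-allele estimates for every (locus, population) cell
#'
#' @param gm a [genotype_matrix()].
#' @param blanks_as_null treat missing genotypes as blank null homozygotes
#'   (`TRUE`) or marginalize them out as unknowns (default `FALSE`).
#' @param ... forwarded to [em_null_frequency()].
#' @return long-format data.frame (`locus`, `pop`, `r`, `iterations`,
#'   `converged`) with the per-cell estimates attached as attribute
#'   `"estimates"` (a locus x pop list matrix).
#' @export
null_allele_table <- function(gm, blanks_as_null = FALSE, ...) {
  pops <- unique(gm$pop)
  est <- matrix(vector("list", length(gm$loci) * length(pops)),
                length(gm$loci), length(pops),
                dimnames = list(gm$loci, pops))
  rows <- list()
  for (l in seq_along(gm$loci)) for (p in pops) {
    idx <- which(gm$pop == p)
    a1 <- gm$a1[idx, l]; a2 <- gm$a2[idx, l]
    nb <- if (blanks_as_null) sum(is.na(a1)) else NULL
    e <- em_null_frequency(a1, a2, blanks = nb, ...)
    est[[l, p]] <- e
    rows[[length(rows) + 1L]] <-
      data.frame(locus = gm$loci[l], pop = p, r = e$r,
                 iterations = e$iterations, converged = e$converged,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- est
  out
}

#' Pairwise F_ST corrected for null alleles (ENA)
#'
#' Recomputes Weir-Cockerham pairwise F_ST treating the null as an additional
#' allele with its EM-estimated frequency in each population, then excluding
#' the null-allele class from the numerator and denominator component sums
#' (the "excluding null alleles" correction). With every estimated r of 0
#' the result equals the uncorrected F_ST exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param nulls output of [null_allele_table()]; computed if omitted.
#' @return a `dist_matrix` (see [pairwise_fst()]) of corrected multilocus
#'   theta values. Loci whose estimated null frequency reaches 0.9 in any
#'   population of a pair are
#'   excluded from that pair with a warning.
#' @export
fst_ena <- function(gm, nulls = NULL) {
  if (is.null(nulls)) nulls <- null_allele_table(gm)
  est <- attr(nulls, "estimates")
  pops <- unique(gm$pop)
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    num <- 0; den <- 0
    for (l in seq_along(gm$loci)) {
      cells <- list(est[[l, pops[i]]], est[[l, pops[j]]])
      if (any(vapply(cells, function(e) e$r >= 0.9, logical(1)))) {
        warning("locus ", gm$loci[l], " excluded for pair ", pops[i], "-",
                pops[j], ": null frequency >= 0.9")
        next
      }
      ls <- wc_locus_input(gm, c(pops[i], pops[j]), l)
      if (is.null(ls)) next
      # adjusted frequencies: EM visible frequencies plus the null class
      alleles <- ls$alleles
      p_adj <- ls$p; h_adj <- ls$h
      for (g in 1:2) {
        pv <- cells[[g]]$p_visible
        p_adj[g, ] <- ifelse(is.na(pv[as.character(alleles)]), 0,
                             pv[as.character(alleles)])
      }
      p_adj <- rbind(cbind(p_adj, c(cells[[1]]$r, cells[[2]]$r)))
      h_adj <- cbind(h_adj, c(0, 0))  # null heterozygotes are never seen
      comp <- wc_components(ls$n, p_adj, h_adj)
      keep <- seq_along(alleles)      # ENA: drop the null column from sums
      num <- num + sum(comp$a[keep])
      den <- den + sum(comp$a[keep] + comp$b[keep] + comp$c[keep])
    }
    m[i, j] <- m[j, i] <- if (den > 0) num / den else NA_real_
  }
  structure(list(labels = pops, matrix = m, kind = "F_ST_ENA"),
            class = "dist_matrix")
}
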