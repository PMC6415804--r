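#' @title Distance matrices
#' @description Symmetric labelled distance matrices with a kind tag. F_ST
#'   entries may be small negatives (sampling noise); they are preserved and
#'   flagged rather than truncated.
#' @param labels character labels.
#' @param m symmetric numeric matrix.
#' @param kind tag, e.g. `"F_ST"`, `"Nei1972"`, `"Euclidean-individual"`,
#'   `"geographic-km"`.
#' @return A `dist_matrix` object.
#' @export
dist_matrix <- function(labels, m, kind = "distance") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("distance matrix must be square and symmetric")
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m, kind = kind,
                 negative = any(m < 0, na.rm = TRUE)),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$kind, "), ", length(x$labels), " labels\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

# Per-locus input to the Weir-Cockerham estimator for a set of populations:
# n (individuals with data), allele frequencies p and observed-heterozygote
# proportions h per population x allele. NULL when fewer than 2 populations
# have data (the locus is dropped for that comparison).
wc_locus_input <- function(gm, pops, l) {
  idx <- lapply(pops, function(p) which(gm$pop == p))
  a1 <- lapply(idx, function(i) gm$a1[i, l])
  a2 <- lapply(idx, function(i) gm$a2[i, l])
  ok <- lapply(a1, function(x) !is.na(x))
  n <- vapply(ok, sum, 0L)
  if (sum(n > 0) < 2L) return(NULL)
  alleles <- sort(unique(c(unlist(a1), unlist(a2))))
  alleles <- alleles[!is.na(alleles)]
  p <- matrix(0, length(pops), length(alleles))
  h <- matrix(0, length(pops), length(alleles))
  for (g in seq_along(pops)) {
    x1 <- a1[[g]][ok[[g]]]; x2 <- a2[[g]][ok[[g]]]
    if (!length(x1)) next
    cnt <- tabulate(match(c(x1, x2), alleles), length(alleles))
    p[g, ] <- cnt / (2 * n[g])
    het <- x1 != x2
    for (u in seq_along(alleles)) {
      h[g, u] <- sum(het & (x1 == alleles[u] | x2 == alleles[u])) / n[g]
    }
  }
  list(n = n, p = p, h = h, alleles = alleles)
}

# Weir-Cockerham (1984) variance components per allele: a (among pops),
# b (among individuals within pops), c (within individuals). n in
# individuals; p, h are pops x alleles matrices.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- numeric(ncol(p))
  for (u in seq_len(ncol(p))) {
    pbar <- sum(n * p[, u]) / (r * nbar)
    s2 <- sum(n * (p[, u] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h[, u]) / (r * nbar)
    a[u] <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[u] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[u] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

# Multilocus Weir-Cockerham theta for a set of populations (ratio of summed
# components across alleles and loci).
wc_theta <- function(gm, pops) {
  num <- 0; den <- 0
  for (l in seq_along(gm$loci)) {
    ls <- wc_locus_input(gm, pops, l)
    if (is.null(ls)) next
    comp <- wc_components(ls$n, ls$p, ls$h)
    num <- num + sum(comp$a)
    den <- den + sum(comp$a + comp$b + comp$c)
  }
  if (den == 0) NA_real_ else num / den
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Multilocus theta for every pair of groups: per-locus, per-allele variance
#' components a (among populations), b (among individuals within
#' populations) and c (within individuals), combined as
#' `theta = sum(a) / sum(a + b + c)` across alleles and loci. Loci with no
#' data in one member of a pair are dropped for that pair.
#'
#' @param gm a [genotype_matrix()].
#' @param partition `"pop"` or `"region"`.
#' @return A `dist_matrix` of kind `"F_ST"` (small negative entries are
#'   preserved).
#' @export
pairwise_fst <- function(gm, partition = c("pop", "region")) {
  partition <- match.arg(partition)
  grp <- if (partition == "pop") gm$pop else {
    if (is.null(gm$region)) stop("no region labels present")
    gm$region
  }
  groups <- unique(grp)
  if (length(groups) < 2L) stop("need >= 2 groups")
  gm2 <- gm; gm2$pop <- grp
  m <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (i in seq_along(groups)[-length(groups)]) for (j in (i + 1):length(groups)) {
    m[i, j] <- m[j, i] <- wc_theta(gm2, c(groups[i], groups[j]))
  }
  dist_matrix(groups, m, "F_ST")
}

#' Nei's (1972) standard genetic distance
#'
#' `D = -ln( J_xy / sqrt(J_x * J_y) )` where the gene identities
#' `J_xy = sum_l sum_i x_i y_i` etc. are aggregated over loci by the
#' ratio-of-sums convention before taking the logarithm.
#'
#' @param aft an [allele_frequencies()] table.
#' @param popA,popB group labels.
#' @return list with `D` and `infinite` (TRUE when no alleles are shared at
#'   any locus, so the distance is infinite).
#' @export
nei_distance <- function(aft, popA, popB) {
  jxy <- jx <- jy <- 0
  for (l in seq_along(aft$loci)) {
    fa <- aft$freq[[l]][[popA]]; fb <- aft$freq[[l]][[popB]]
    alleles <- union(names(fa), names(fb))
    xa <- ifelse(is.na(fa[alleles]), 0, fa[alleles])
    xb <- ifelse(is.na(fb[alleles]), 0, fb[alleles])
    jxy <- jxy + sum(xa * xb)
    jx <- jx + sum(xa^2); jy <- jy + sum(xb^2)
  }
  if (jxy == 0) return(list(D = Inf, infinite = TRUE))
  list(D = -log(jxy / sqrt(jx * jy)), infinite = FALSE)
}

#' Nei distance matrix between all groups
#' @param gm a [genotype_matrix()].
#' @param partition `"pop"` or `"region"`.
#' @return A `dist_matrix` of kind `"Nei1972"`.
#' @export
nei_distance_matrix <- function(gm, partition = c("pop", "region")) {
  partition <- match.arg(partition)
  aft <- allele_frequencies(gm, partition)
  g <- aft$groups
  m <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)[-length(g)]) for (j in (i + 1):length(g)) {
    m[i, j] <- m[j, i] <- nei_distance(aft, g[i], g[j])$D
  }
  dist_matrix(g, m, "Nei1972")
}

# ---------------------------------------------------------------------------
# AMOVA

# Per-locus sums of squared 0/1 distances between gene copies for an
# arbitrary grouping of copies: SS = (1/N) * sum_{i<j} d^2, computed from
# allele counts as (N^2 - sum c_u^2) / (2N).
ss_copies <- function(copies) {
  N <- length(copies)
  if (N < 2L) return(0)
  cu <- table(copies)
  (N^2 - sum(cu^2)) / (2 * N)
}

# variance components for one locus given copy-level data
amova_locus <- function(alleles, ind, pop, grp = NULL) {
  # alleles: copy allele labels; ind/pop/grp: copy-level unit labels
  I <- length(unique(ind)); P <- length(unique(pop))
  ss_tot <- ss_copies(alleles)
  ss_wp <- sum(vapply(split(alleles, pop), ss_copies, 0))
  ss_wi <- sum(vapply(split(alleles, ind), ss_copies, 0))
  ip <- tapply(ind, pop, function(x) length(unique(x)))  # individuals per pop
  if (is.null(grp)) {
    ssd <- c(ss_tot - ss_wp, ss_wp - ss_wi, ss_wi)
    df <- c(P - 1, I - P, I)
    ms <- ifelse(df > 0, ssd / df, NA_real_)
    ncoef <- (I - sum(ip^2) / I) / (P - 1)
    sc <- ms[3]
    sb <- (ms[2] - sc) / 2
    sa <- (ms[1] - sc - 2 * sb) / (2 * ncoef)
    list(ssd = ssd, df = df, sigma = c(sa, sb, sc),
         levels = c("among_pops", "among_ind_within_pops", "within_ind"))
  } else {
    G <- length(unique(grp))
    ss_wg <- sum(vapply(split(alleles, grp), ss_copies, 0))
    ssd <- c(ss_tot - ss_wg, ss_wg - ss_wp, ss_wp - ss_wi, ss_wi)
    df <- c(G - 1, P - G, I - P, I)
    ms <- ifelse(df > 0, ssd / df, NA_real_)
    pop_grp <- tapply(as.character(grp), pop, `[`, 1L)        # group of each pop
    ig <- tapply(ind, grp, function(x) length(unique(x)))     # individuals per group
    s_pg <- sum(ip^2 / ig[as.character(pop_grp[names(ip)])])  # sum_p I_p^2 / I_g(p)
    n1 <- (I - s_pg) / (P - G)
    n2 <- (s_pg - sum(ip^2) / I) / (G - 1)
    n3 <- (I - sum(ig^2) / I) / (G - 1)
    sd_ <- ms[4]
    sc <- (ms[3] - sd_) / 2
    sb <- (ms[2] - sd_ - 2 * sc) / (2 * n1)
    sa <- (ms[1] - sd_ - 2 * sc - 2 * n2 * sb) / (2 * n3)
    list(ssd = ssd, df = df, sigma = c(sa, sb, sc, sd_),
         levels = c("among_groups", "among_pops_within_groups",
                    "among_ind_within_pops", "within_ind"))
  }
}

amova_components <- function(gm, grp_of_ind = NULL) {
  nlev <- if (is.null(grp_of_ind)) 3L else 4L
  ssd <- df <- sigma <- rep(0, nlev)
  for (l in seq_along(gm$loci)) {
    ok <- which(!is.na(gm$a1[, l]))
    if (length(ok) < 2L) next
    alleles <- c(gm$a1[ok, l], gm$a2[ok, l])
    ind <- rep(ok, 2L)
    pop <- rep(gm$pop[ok], 2L)
    grp <- if (is.null(grp_of_ind)) NULL else rep(grp_of_ind[ok], 2L)
    al <- amova_locus(alleles, ind, pop, grp)
    ssd <- ssd + al$ssd; df <- df + al$df; sigma <- sigma + al$sigma
    levels <- al$levels
  }
  list(ssd = ssd, df = df, sigma = sigma, levels = levels)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions gene-copy variance across a nesting of levels. The gene-copy
#' distance defaults to identity/non-identity (0/1, the F_ST analogue); sums
#' of squares are computed per locus from the squared inter-copy distances,
#' variance components are obtained by equating observed and expected mean
#' squares, then summed across loci. Negative components are retained and
#' reported, never silently truncated. Percentages are computed on the raw
#' components and sum to 100.
#'
#' With `hierarchy = "pop"` the levels are among populations / among
#' individuals within populations / within individuals. With
#' `hierarchy = c("pop", "region")` populations become groups and regions the
#' nested populations (four levels).
#'
#' Permutation p-values use the level-appropriate scheme: whole individuals
#' are permuted among populations (and among regions within populations for
#' the 4-level design), and gene copies are permuted among individuals within
#' populations for the within-individual level.
#'
#' @param gm a [genotype_matrix()].
#' @param hierarchy `"pop"` or `c("pop", "region")`.
#' @param n_perm number of permutations for the p-values (0 to skip).
#' @return An `amova_result`: data.frame with df, SSD, variance component
#'   `sigma2`, `percent`, `p`; plus `phi` statistics.
#' @export
amova <- function(gm, hierarchy = "pop", n_perm = 999L) {
  four <- length(hierarchy) == 2L
  if (four && is.null(gm$region)) stop("4-level hierarchy requires region labels")
  gm2 <- gm
  grp_of_ind <- NULL
  if (four) {          # islands are groups, regions are the nested pops
    grp_of_ind <- gm$pop
    gm2$pop <- paste(gm$pop, gm$region, sep = ":")
  }
  obs <- amova_components(gm2, grp_of_ind)
  sigma <- obs$sigma
  tot <- sum(sigma)
  percent <- 100 * sigma / tot
  nlev <- length(sigma)

  pvals <- rep(NA_real_, nlev)
  if (n_perm > 0L) {
    hits <- rep(0L, nlev)
    n <- length(gm2$ind)
    for (b in seq_len(n_perm)) {
      # level 1 (and 2 in the 4-level design): permute individuals among units
      perm <- sample.int(n)
      g_ind <- gm2
      g_ind$pop <- gm2$pop[perm]
      grp_perm <- if (four) grp_of_ind[perm] else NULL
      s_ind <- amova_components(g_ind, grp_perm)$sigma
      hits[1] <- hits[1] + (s_ind[1] >= sigma[1] - 1e-12)
      if (four) hits[2] <- hits[2] + (s_ind[2] >= sigma[2] - 1e-12)
      # within-individual levels: permute gene copies among individuals
      # within populations (breaks the inbreeding signal only)
      g_cp <- gm2
      for (p in unique(gm2$pop)) {
        idx <- which(gm2$pop == p)
        for (l in seq_along(gm2$loci)) {
          okl <- idx[!is.na(gm2$a1[idx, l])]
          if (length(okl) < 2L) next
          copies <- sample(c(gm2$a1[okl, l], gm2$a2[okl, l]))
          k <- length(okl)
          g_cp$a1[okl, l] <- copies[seq_len(k)]
          g_cp$a2[okl, l] <- copies[k + seq_len(k)]
        }
      }
      s_cp <- amova_components(g_cp, grp_of_ind)$sigma
      j <- nlev - 1L   # among-individual component under copy permutation
      hits[j] <- hits[j] + (s_cp[j] >= sigma[j] - 1e-12)
      hits[nlev] <- hits[nlev] + (s_cp[nlev] <= sigma[nlev] + 1e-12)
    }
    pvals <- (1 + hits) / (1 + n_perm)
  }

  tab <- data.frame(level = obs$levels, df = obs$df, SSD = obs$ssd,
                    sigma2 = sigma, percent = percent, p = pvals,
                    stringsAsFactors = FALSE)
  phi <- if (nlev == 3L) {
    c(phi_ST = sigma[1] / tot,
      phi_IS = sigma[2] / (sigma[2] + sigma[3]),
      phi_IT = (sigma[1] + sigma[2]) / tot)
  } else {
    c(phi_CT = sigma[1] / tot,
      phi_SC = sigma[2] / (sigma[2] + sigma[3] + sigma[4]),
      phi_ST = (sigma[1] + sigma[2]) / tot,
      phi_IS = sigma[3] / (sigma[3] + sigma[4]))
  }
  structure(list(table = tab, phi = phi), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n"); print(x$table, row.names = FALSE)
  cat("Phi statistics:\n"); print(round(x$phi, 4))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Individual allele-dosage distance
#'
#' Euclidean distance between individuals' allele-dosage vectors (0/1/2
#' copies of each allele at each locus); missing genotypes are imputed to the
#' locus mean dosage.
#'
#' @param gm a [genotype_matrix()].
#' @return A `dist_matrix` of kind `"Euclidean-individual"`.
#' @export
dosage_distance <- function(gm) {
  cols <- list()
  for (l in seq_along(gm$loci)) {
    alleles <- sort(unique(c(gm$a1[, l], gm$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    for (a in alleles) {
      d <- (gm$a1[, l] == a) + (gm$a2[, l] == a)
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      cols[[paste0(gm$loci[l], ".", a)]] <- d
    }
  }
  X <- do.call(cbind, cols)
  dist_matrix(gm$ind, as.matrix(stats::dist(X)), "Euclidean-individual")
}

#' Principal coordinate analysis
#'
#' Double-centers `-0.5 * D^2`, eigen-decomposes, and returns coordinates
#' ordered by eigenvalue. Negative eigenvalues (non-Euclidean input) are
#' reported, not silently dropped; percent variance is relative to the sum of
#' positive eigenvalues.
#'
#' @param dm a `dist_matrix` (or square symmetric matrix).
#' @return list with `coords`, `eigenvalues`, `percent` (per positive axis).
#' @export
pcoa <- function(dm) {
  D <- if (inherits(dm, "dist_matrix")) dm$matrix else as.matrix(dm)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("pcoa needs a square symmetric matrix")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = e$values,
       percent = 100 * e$values[pos] / sum(e$values[pos]))
}

#' Mantel test
#'
#' Pearson correlation of the lower triangles of two distance matrices; the
#' null distribution is generated by simultaneous row/column permutation of
#' the second matrix. One-sided (positive association).
#'
#' @param dmA,dmB `dist_matrix` objects or square matrices with identical
#'   labels.
#' @param n_perm number of permutations (default 10000).
#' @return list with `r`, `r2`, `p`.
#' @export
mantel <- function(dmA, dmB, n_perm = 10000L) {
  A <- if (inherits(dmA, "dist_matrix")) dmA$matrix else as.matrix(dmA)
  B <- if (inherits(dmB, "dist_matrix")) dmB$matrix else as.matrix(dmB)
  n <- nrow(A)
  if (n < 3L) stop("mantel needs >= 3 labels")
  if (!all(dim(B) == n)) stop("matrices must share labels")
  lt <- lower.tri(A)
  r_obs <- stats::cor(A[lt], B[lt])
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    if (stats::cor(A[lt], B[perm, perm][lt]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, r2 = r_obs^2, p = (1 + hits) / (1 + n_perm))
}

#' Great-circle distances between labelled coordinates
#'
#' Haversine distances in kilometres (mean Earth radius 6371 km).
#'
#' @param coords two-column matrix (lat, lon) in decimal degrees with
#'   rownames as labels.
#' @return A `dist_matrix` of kind `"geographic-km"`.
#' @export
geographic_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (anyNA(coords)) {
    bad <- rownames(coords)[apply(is.na(coords), 1, any)]
    stop("missing coordinates for: ", paste(bad, collapse = ", "))
  }
  # geosphere expects (lon, lat)
  m <- geosphere::distm(coords[, c(2, 1), drop = FALSE],
                        fun = function(x, y) geosphere::distHaversine(x, y, r = 6371000))
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(coords)))
  dist_matrix(labels, m / 1000, "geographic-km")
}

#' Region-centroid coordinates
#'
#' @param gm a [genotype_matrix()] with coords and region labels.
#' @param by `"region"` or `"pop"`.
#' @return matrix of centroid (lat, lon) per label.
#' @export
centroid_coords <- function(gm, by = c("region", "pop")) {
  by <- match.arg(by)
  if (is.null(gm$coords)) stop("no coordinates present")
  lab <- if (by == "region") gm$region else gm$pop
  if (is.null(lab)) stop("no ", by, " labels present")
  lat <- tapply(gm$coords[, 1], lab, mean)
  lon <- tapply(gm$coords[, 2], lab, mean)
  cbind(lat = lat, lon = lon)
}
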