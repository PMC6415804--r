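# Independent brute-force oracles used to cross-check the package's
# estimators. These deliberately re-derive every quantity from first
# principles (explicit loops, O(n^2) distance sums) and share no code with
# the implementation.

toy_gm <- function(a1, a2, pop) {
  genotype_matrix(matrix(as.integer(a1), nrow = length(pop)),
                  matrix(as.integer(a2), nrow = length(pop)),
                  pop = pop)
}

# random small genotype matrix with optional missing calls
random_gm <- function(n = 5, L = 3, pops = c("A", "B"), n_alleles = 4,
                      miss = 0.1) {
  ntot <- n * length(pops)
  a1 <- matrix(sample.int(n_alleles, ntot * L, TRUE), ntot, L)
  a2 <- matrix(sample.int(n_alleles, ntot * L, TRUE), ntot, L)
  drop <- matrix(runif(ntot * L) < miss, ntot, L)
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  genotype_matrix(a1, a2, pop = rep(pops, each = n))
}

bf_ho <- function(gm, pop, l) {
  idx <- which(gm$pop == pop)
  num <- 0; den <- 0
  for (i in idx) {
    if (is.na(gm$a1[i, l])) next
    den <- den + 1
    if (gm$a1[i, l] != gm$a2[i, l]) num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

bf_he <- function(gm, pop, l) {
  idx <- which(gm$pop == pop)
  copies <- c()
  for (i in idx) if (!is.na(gm$a1[i, l]))
    copies <- c(copies, gm$a1[i, l], gm$a2[i, l])
  n <- length(copies)
  if (n < 2) return(NA_real_)
  p <- as.numeric(table(copies)) / n
  n / (n - 1) * (1 - sum(p^2))
}

bf_fis <- function(gm, pop) {
  ho <- he <- c()
  for (l in seq_along(gm$loci)) {
    ho <- c(ho, bf_ho(gm, pop, l)); he <- c(he, bf_he(gm, pop, l))
  }
  1 - mean(ho, na.rm = TRUE) / mean(he, na.rm = TRUE)
}

# Weir & Cockerham (1984) per-locus components, written directly from the
# published estimator with explicit per-allele loops
bf_wc_locus <- function(gm, pops, l) {
  r <- length(pops)
  n <- p_list <- h_list <- list()
  for (g in seq_len(r)) {
    idx <- which(gm$pop == pops[g])
    x1 <- gm$a1[idx, l]; x2 <- gm$a2[idx, l]
    keep <- !is.na(x1)
    x1 <- x1[keep]; x2 <- x2[keep]
    n[[g]] <- length(x1)
    p_list[[g]] <- c(x1, x2)
    h_list[[g]] <- cbind(x1, x2)
  }
  alleles <- sort(unique(unlist(p_list)))
  A <- B <- C <- 0
  ni <- unlist(n)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  for (u in alleles) {
    p <- vapply(seq_len(r), function(g) mean(p_list[[g]] == u), 0)
    h <- vapply(seq_len(r), function(g)
      mean(apply(h_list[[g]], 1, function(z) sum(z == u) == 1)), 0)
    pbar <- sum(ni * p) / (r * nbar)
    s2 <- sum(ni * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(a = A, b = B, c = C)
}

bf_wc_theta <- function(gm, pops) {
  comp <- rowSums(vapply(seq_along(gm$loci),
                         function(l) bf_wc_locus(gm, pops, l), numeric(3)))
  comp["a"] / sum(comp)
}

# AMOVA oracle: sums of squares by explicit O(n^2) loops over gene copies
# (0/1 distance), components solved from the expected-mean-square equations
bf_amova3 <- function(gm) {
  tot_ssd <- c(0, 0, 0); tot_df <- c(0, 0, 0); tot_sig <- c(0, 0, 0)
  for (l in seq_along(gm$loci)) {
    ok <- which(!is.na(gm$a1[, l]))
    copies <- c(gm$a1[ok, l], gm$a2[ok, l])
    ind <- rep(ok, 2); pop <- rep(gm$pop[ok], 2)
    N <- length(copies)
    ss <- function(sel) {
      s <- 0; idx <- which(sel)
      for (i in idx) for (j in idx) if (i < j)
        s <- s + (copies[i] != copies[j])
      s / sum(sel)
    }
    ss_tot <- ss(rep(TRUE, N))
    ss_wp <- sum(vapply(unique(pop), function(p) ss(pop == p), 0))
    ss_wi <- sum(vapply(unique(ind), function(i) ss(ind == i), 0))
    P <- length(unique(pop)); I <- length(unique(ind))
    ssd <- c(ss_tot - ss_wp, ss_wp - ss_wi, ss_wi)
    df <- c(P - 1, I - P, I)
    ms <- ssd / df
    ip <- vapply(unique(pop), function(p) length(unique(ind[pop == p])), 0)
    ncoef <- (I - sum(ip^2) / I) / (P - 1)
    # E[MS_wi]=sc ; E[MS_ai]=sc+2sb ; E[MS_ap]=sc+2sb+2*ncoef*sa
    sc <- ms[3]
    sb <- (ms[2] - sc) / 2
    sa <- (ms[1] - sc - 2 * sb) / (2 * ncoef)
    tot_ssd <- tot_ssd + unname(ssd); tot_df <- tot_df + unname(df)
    tot_sig <- tot_sig + unname(c(sa, sb, sc))
  }
  list(ssd = unname(tot_ssd), df = unname(tot_df), sigma = unname(tot_sig))
}

# exhaustive signed-rank null: p-value over all 2^n sign patterns
bf_signrank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  pats <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(pats) %*% r
  switch(alternative,
         excess = mean(w_all >= w_obs),
         deficiency = mean(w_all <= w_obs),
         two_sided = min(1, 2 * min(mean(w_all >= w_obs),
                                    mean(w_all <= w_obs))))
}

# Monte-Carlo rarefaction oracle: expected allele count in subsamples of g
bf_ar_mc <- function(counts, g, reps = 20000) {
  pool <- rep(seq_along(counts), counts)
  mean(replicate(reps, length(unique(sample(pool, g)))))
}
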