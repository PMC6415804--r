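#' Admixture-model clustering by MCMC
#'
#' Gibbs sampler for the classic Bayesian admixture model: gene-copy cluster
#' assignments are sampled proportional to `q_ik * p_kla`; cluster allele
#' frequencies get a Dirichlet(lambda = 1) prior (uncorrelated-frequencies
#' model); individual admixture proportions get a symmetric
#' Dirichlet(alpha) prior with alpha updated by a Metropolis random walk
#' under a uniform prior on (0, 10]. Missing genotypes are skipped in the
#' assignment step. Returns posterior means over the post-burn-in sweeps and
#' the per-sweep data log-likelihood.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters (>= 1).
#' @param sweeps,burn_in MCMC lengths (full-scale analyses conventionally use
#'   1e6/1e5; the package tests use 5e3/1e3).
#' @param seed optional integer; sets the R RNG.
#' @param alpha_init initial Dirichlet concentration.
#' @param update_alpha sample alpha (default) or keep it fixed.
#' @return A `cluster_run`: `Q` (individuals x K, rows sum to 1), `P` (per
#'   locus a K x alleles frequency matrix), `lnP` (mean post-burn-in data
#'   log-likelihood), `loglik` (trace), `alpha`, `K`, `sweeps`, `burn_in`.
#' @export
run_admixture_mcmc <- function(gm, K, sweeps = 5000L, burn_in = 1000L,
                               seed = NULL, alpha_init = 1,
                               update_alpha = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$ind); L <- length(gm$loci)
  g1 <- matrix(NA_integer_, n, L); g2 <- matrix(NA_integer_, n, L)
  alleles <- vector("list", L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(gm$a1[, l], gm$a2[, l])))
    al <- al[!is.na(al)]
    alleles[[l]] <- al
    g1[, l] <- match(gm$a1[, l], al) - 1L
    g2[, l] <- match(gm$a2[, l], al) - 1L
  }
  nall <- vapply(alleles, length, 0L)
  res <- cpp_admixture_gibbs(g1, g2, nall, as.integer(K), as.integer(sweeps),
                             as.integer(burn_in), alpha_init, update_alpha,
                             1.0, 10.0, 0.25)
  Q <- res$Q
  rownames(Q) <- gm$ind
  P <- res$P
  for (l in seq_len(L)) colnames(P[[l]]) <- alleles[[l]]
  names(P) <- gm$loci
  structure(list(Q = Q, P = P, lnP = mean(res$loglik), loglik = res$loglik,
                 alpha = res$alpha, K = K, sweeps = sweeps, burn_in = burn_in,
                 seed = seed, pop = gm$pop),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat("cluster_run: K =", x$K, " lnP =", round(x$lnP, 2),
      " alpha =", round(x$alpha, 3), "\n")
  invisible(x)
}

#' Evanno Delta-K table
#'
#' Second-order rate of change of the clustering log-likelihood across K:
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`, defined
#' only for interior K with at least two runs.
#'
#' @param lnP_by_K named list: element `"K"` holds the per-run lnP values at
#'   that K (>= 2 runs each, >= 3 consecutive K).
#' @return data.frame with `K`, `n_runs`, `mean_lnP`, `sd_lnP`, `L1` (first
#'   difference), `L2` (second difference), `deltaK` (`Inf` flagged when
#'   sd = 0; `NA` at the endpoints).
#' @export
evanno <- function(lnP_by_K) {
  Ks <- sort(as.integer(names(lnP_by_K)))
  if (length(Ks) < 3L || any(diff(Ks) != 1L))
    stop("need >= 3 consecutive K values")
  if (any(vapply(lnP_by_K, length, 0L) < 2L))
    stop("need >= 2 runs per K")
  mean_l <- vapply(as.character(Ks), function(k) mean(lnP_by_K[[k]]), 0)
  sd_l <- vapply(as.character(Ks), function(k) stats::sd(lnP_by_K[[k]]), 0)
  m <- length(Ks)
  L1 <- c(NA, diff(mean_l))
  L2 <- c(NA, abs(diff(mean_l, differences = 2)), NA)
  dK <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    dK[i] <- if (sd_l[i] == 0) Inf else L2[i] / sd_l[i]
  }
  data.frame(K = Ks, n_runs = vapply(lnP_by_K[as.character(Ks)], length, 0L),
             mean_lnP = mean_l, sd_lnP = sd_l, L1 = L1, L2 = L2, deltaK = dK,
             row.names = NULL)
}

# column matching of Q2 onto Q1 maximizing the similarity sum(Q1 * Q2[, perm]):
# exhaustive over the K! permutations for K <= 6 (exact), greedy beyond
greedy_permutation <- function(Q1, Q2) {
  K <- ncol(Q1)
  S <- crossprod(Q1, Q2)         # K x K similarity
  if (K <= 6L) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p) sum(S[cbind(seq_len(K), p)]), 0)
    return(perms[[which.max(scores)]])
  }
  perm <- integer(K)
  used_r <- used_c <- logical(K)
  for (step in seq_len(K)) {
    S2 <- S
    S2[used_r, ] <- -Inf; S2[, used_c] <- -Inf
    ij <- arrayInd(which.max(S2), dim(S2))
    perm[ij[1]] <- ij[2]
    used_r[ij[1]] <- TRUE; used_c[ij[2]] <- TRUE
  }
  perm                           # Q2[, perm] aligns with Q1
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Align replicate cluster runs and build a consensus
#'
#' Cluster labels are arbitrary, so independent runs at the same K differ by
#' column permutations. Each run is aligned to the first by a greedy search
#' over column permutations maximizing the similarity
#' `sum_ik Q1[i,k] * Q2[i,perm(k)]` (exact for small K, checked against
#' exhaustive search in the tests); the consensus is the mean of the aligned
#' Q matrices.
#'
#' @param runs list of `cluster_run` objects sharing K and individuals.
#' @return list with `Q` (consensus), `aligned` (list of permuted Q), and
#'   `permutations`.
#' @export
align_runs <- function(runs) {
  if (!length(runs)) stop("no runs supplied")
  Ks <- vapply(runs, function(r) as.integer(r$K), 0L)
  if (length(unique(Ks)) != 1L) stop("runs have mixed K")
  Q1 <- runs[[1]]$Q
  aligned <- list(Q1)
  perms <- list(seq_len(ncol(Q1)))
  if (length(runs) > 1L) for (j in 2:length(runs)) {
    perm <- greedy_permutation(Q1, runs[[j]]$Q)
    aligned[[j]] <- runs[[j]]$Q[, perm, drop = FALSE]
    perms[[j]] <- perm
  }
  Qc <- Reduce(`+`, aligned) / length(aligned)
  list(Q = Qc, aligned = aligned, permutations = perms)
}

#' Run the clustering across a K range with replicate runs
#'
#' @param gm a [genotype_matrix()].
#' @param K_range integer vector of K values.
#' @param n_runs replicate runs per K.
#' @param sweeps,burn_in MCMC lengths.
#' @param seed base seed; run r at K uses `seed + 1000*K + r`.
#' @return list with `runs` (nested list), `evanno` table, `best_K`
#'   (arg max Delta-K), and `consensus` (aligned consensus Q at `best_K`).
#' @export
cluster_k_scan <- function(gm, K_range = 1:5, n_runs = 3L, sweeps = 5000L,
                           burn_in = 1000L, seed = 1L) {
  runs <- list()
  lnP <- list()
  for (K in K_range) {
    rk <- lapply(seq_len(n_runs), function(r)
      run_admixture_mcmc(gm, K, sweeps, burn_in, seed = seed + 1000L * K + r))
    runs[[as.character(K)]] <- rk
    lnP[[as.character(K)]] <- vapply(rk, function(x) x$lnP, 0)
  }
  ev <- evanno(lnP)
  best <- ev$K[which.max(ev$deltaK)]
  cons <- align_runs(runs[[as.character(best)]])
  list(runs = runs, evanno = ev, best_K = best, consensus = cons$Q)
}
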