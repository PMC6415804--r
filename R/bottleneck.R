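#' Equilibrium gene-diversity distribution conditional on allele count
#'
#' Simulates single-population constant-size coalescent genealogies with
#' microsatellite mutation, tuning theta by bisection until the mean realized
#' allele count matches `k_alleles`, then retains replicates whose allele
#' count equals `k_alleles` exactly and returns the moments of their
#' (unbiased) gene diversity. This is the "coalescent conditioned on k"
#' construction underlying heterozygosity-excess bottleneck tests.
#'
#' @param k_alleles observed allele count (2 <= k <= n_copies).
#' @param n_copies gene copies in the observed sample.
#' @param mut_model a [mutation_model()] (`"SMM"` or `"TPM"`); the rate field
#'   is irrelevant here, only theta matters.
#' @param n_reps retained replicates required (>= 500 recommended).
#' @param max_batches cap on simulation batches before giving up.
#' @return list with `mean`, `sd`, `theta` (tuned), `acceptance`, `draws`.
#' @export
heq_distribution <- function(k_alleles, n_copies, mut_model = mutation_model("SMM"),
                             n_reps = 1000L, max_batches = 400L) {
  if (k_alleles < 2L || k_alleles > n_copies)
    stop("need 2 <= k_alleles <= n_copies")
  batch_k <- function(theta, B) {
    st <- sim_equilibrium_loci(n_copies, theta, B, mut_model)
    k <- apply(st, 2, function(x) length(unique(x)))
    h <- apply(st, 2, function(x) {
      p <- tabulate(factor(x)) / length(x)
      (1 - sum(p^2)) * length(x) / (length(x) - 1)
    })
    list(k = k, h = h)
  }
  # bisection on log10(theta): mean allele count is monotone in theta
  lo <- -2; hi <- 3
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    mk <- mean(batch_k(10^mid, 200L)$k)
    if (mk < k_alleles) lo <- mid else hi <- mid
  }
  theta <- 10^((lo + hi) / 2)
  draws <- numeric(0)
  tried <- 0L; hit <- 0L
  for (b in seq_len(max_batches)) {
    bt <- batch_k(theta, 500L)
    tried <- tried + 500L
    sel <- bt$h[bt$k == k_alleles]
    hit <- hit + length(sel)
    draws <- c(draws, sel)
    if (length(draws) >= n_reps) break
  }
  if (hit / tried < 0.001)
    stop("acceptance below 0.1% when conditioning on k = ", k_alleles,
         "; widen the theta search")
  draws <- draws[seq_len(min(length(draws), n_reps))]
  list(mean = mean(draws), sd = stats::sd(draws), theta = theta,
       acceptance = hit / tried, draws = draws)
}

#' Wilcoxon signed-rank test for heterozygosity excess or deficiency
#'
#' Exact null distribution for up to 25 non-zero differences, normal
#' approximation with continuity correction beyond; zero differences are
#' dropped. `"excess"` tests for systematically positive differences
#' (observed H above equilibrium: the population-reduction signal),
#' `"deficiency"` for negative ones (the expansion signal).
#'
#' @param differences per-locus `H_obs - mean H_eq` values.
#' @param alternative `"two_sided"`, `"excess"` or `"deficiency"`.
#' @return p-value in (0, 1].
#' @export
wilcoxon_signrank <- function(differences,
                              alternative = c("two_sided", "excess",
                                              "deficiency")) {
  alternative <- match.arg(alternative)
  d <- differences[differences != 0]
  if (!length(d)) return(1)
  if (length(d) < 5L) stop("need >= 5 non-zero differences")
  alt <- switch(alternative, two_sided = "two.sided", excess = "greater",
                deficiency = "less")
  p <- suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = alt,
                                           exact = length(d) <= 25L,
                                           correct = TRUE)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Heterozygosity-excess / deficiency bottleneck report
#'
#' For each population and mutation model: per polymorphic locus, the
#' observed gene diversity is compared to the simulated equilibrium
#' distribution conditional on the observed allele count; the per-locus
#' differences feed one-tailed (deficiency = expansion signal; excess =
#' reduction signal) and two-tailed Wilcoxon signed-rank tests, mirroring
#' the conventional report layout of 3 tests x 2 models per population.
#'
#' @param gm a [genotype_matrix()].
#' @param models subset of `c("SMM", "TPM")`.
#' @param n_reps retained equilibrium replicates per locus.
#' @param tpm_p_single,tpm_mean_multi two-phase model settings (defaults 0.9
#'   and 2.8; always reported because standard practice leaves them
#'   implicit).
#' @param cache optional environment memoizing `heq_distribution` calls by
#'   (model, k, n); share one across calls to amortize the conditioning.
#' @return A `bottleneck_result`: `loci` (per locus/pop/model observed H,
#'   equilibrium mean/sd, standardized difference DH) and `tests`
#'   (pop x model x tail p-values). Monomorphic loci are excluded with a
#'   message.
#' @export
bottleneck_report <- function(gm, models = c("SMM", "TPM"), n_reps = 1000L,
                              tpm_p_single = 0.9, tpm_mean_multi = 2.8,
                              cache = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  pops <- unique(gm$pop)
  loci_rows <- list(); test_rows <- list()
  for (p in pops) {
    idx <- which(gm$pop == p)
    for (model in models) {
      mm <- if (model == "SMM") mutation_model("SMM")
            else mutation_model("TPM", p_single = tpm_p_single,
                                mean_multi = tpm_mean_multi)
      diffs <- c()
      for (l in seq_along(gm$loci)) {
        a1 <- gm$a1[idx, l]; a2 <- gm$a2[idx, l]
        ok <- !is.na(a1)
        copies <- c(a1[ok], a2[ok])
        n <- length(copies)
        k <- length(unique(copies))
        if (k < 2L) {
          message("bottleneck_report: locus ", gm$loci[l], " monomorphic in ",
                  p, " (", model, "), excluded")
          next
        }
        h_obs <- (1 - sum((tabulate(factor(copies)) / n)^2)) * n / (n - 1)
        key <- paste(model, k, n, sep = ":")
        if (is.null(cache[[key]]))
          cache[[key]] <- heq_distribution(k, n, mm, n_reps)
        hq <- cache[[key]]
        dh <- if (hq$sd > 0) (h_obs - hq$mean) / hq$sd else NA_real_
        diffs <- c(diffs, h_obs - hq$mean)
        loci_rows[[length(loci_rows) + 1L]] <-
          data.frame(pop = p, model = model, locus = gm$loci[l], k = k, n = n,
                     H_obs = h_obs, H_eq_mean = hq$mean, H_eq_sd = hq$sd,
                     DH = dh, stringsAsFactors = FALSE)
      }
      if (sum(diffs != 0) >= 5L) {
        pvals <- c(wilcoxon_signrank(diffs, "deficiency"),
                   wilcoxon_signrank(diffs, "excess"),
                   wilcoxon_signrank(diffs, "two_sided"))
      } else {
        warning("fewer than 5 informative loci in ", p, " (", model,
                "); Wilcoxon tests undefined")
        pvals <- rep(NA_real_, 3)
      }
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        pop = p, model = model,
        p_deficiency = pvals[1], p_excess = pvals[2], p_two_sided = pvals[3],
        n_loci = length(diffs), stringsAsFactors = FALSE)
    }
  }
  structure(list(loci = do.call(rbind, loci_rows),
                 tests = do.call(rbind, test_rows),
                 tpm = c(p_single = tpm_p_single, mean_multi = tpm_mean_multi)),
            class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat("Heterozygosity excess/deficiency tests (alpha = 0.05 flags)\n")
  t <- x$tests
  t$sig <- ifelse(pmin(t$p_deficiency, t$p_excess) < 0.05, "*", "")
  print(t, row.names = FALSE)
  invisible(x)
}
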