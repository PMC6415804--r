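test_that("allele counting applies the frequent-allele threshold", {
  # one locus engineered to frequencies 0.9 / 0.06 / 0.04 over 50 copies
  a <- c(rep(1, 45), rep(2, 3), rep(3, 2))
  gm <- toy_gm(a[seq(1, 49, 2)], a[seq(2, 50, 2)], rep("A", 25))
  aft <- allele_frequencies(gm)
  expect_equal(unname(count_alleles(aft, "A")), c(3L, 2L))
  expect_equal(unname(count_alleles(aft, "A", 0)["A_freq"]), 3L)
  expect_error(count_alleles(aft, "Z"), "unknown group")
})

test_that("allele counts equal a brute-force recount on random fixtures", {
  set.seed(10)
  gm <- random_gm(n = 10, L = 11, miss = 0.1, n_alleles = 6)
  aft <- allele_frequencies(gm)
  for (p in c("A", "B")) {
    idx <- which(gm$pop == p)
    A <- Af <- 0
    for (l in 1:11) {
      copies <- c(gm$a1[idx, l], gm$a2[idx, l])
      copies <- copies[!is.na(copies)]
      tab <- table(copies) / length(copies)
      A <- A + length(tab); Af <- Af + sum(tab > 0.05)
    }
    expect_equal(unname(count_alleles(aft, p)), c(A, Af))
  }
})

test_that("private alleles are those present in exactly one population", {
  gm <- toy_gm(c(1, 2, 5), c(3, 3, 6), c("A", "A", "B"))
  pa <- private_alleles(allele_frequencies(gm))
  expect_equal(pa$PA[pa$pop == "A"], 3L)  # alleles 1, 2, 3 only in A
  expect_equal(pa$PA[pa$pop == "B"], 2L)  # alleles 5, 6 only in B
  gm2 <- toy_gm(c(1, 1), c(2, 2), c("A", "B"))
  pa2 <- private_alleles(allele_frequencies(gm2))
  expect_equal(pa2$PA, c(0L, 0L))  # both alleles shared
  expect_error(private_alleles(allele_frequencies(toy_gm(1, 1, "A"))),
               "single population")
})

test_that("planted private-allele counts are recovered", {
  # pop A gets 15 private alleles across loci, 4 of them frequent
  set.seed(11)
  nA <- 40; nB <- 40
  L <- 5
  a1 <- matrix(sample(10:14, (nA + nB) * L, TRUE), nA + nB, L)
  a2 <- matrix(sample(10:14, (nA + nB) * L, TRUE), nA + nB, L)
  # plant 15 rare private alleles (single copies, labels 100+) in pop A
  slots <- cbind(sample(nA, 15, TRUE), sample(L, 15, TRUE))
  slots <- slots[!duplicated(slots), ][1:11, ]           # unique cells
  for (i in seq_len(nrow(slots))) a1[slots[i, 1], slots[i, 2]] <- 100L + i
  # plant 4 frequent private alleles: 20 copies each of labels 200+
  for (j in 1:4) a2[(1:20) + (j %% 2) * 20, j] <- 200L + j
  gm <- genotype_matrix(a1, a2, pop = rep(c("A", "B"), c(nA, nB)))
  pa <- private_alleles(allele_frequencies(gm))
  expect_equal(pa$PA[pa$pop == "A"], nrow(slots) + 4L)
  expect_equal(pa$PA_freq[pa$pop == "A"], 4L)
})

test_that("rarefied allelic richness matches closed form and Monte Carlo", {
  # n = 6 copies, counts (3, 2, 1), g = 4
  gm <- toy_gm(c(1, 1, 2), c(1, 2, 3), rep("A", 3))
  ar <- allelic_richness(gm, g_copies = 4)
  exact <- (1 - choose(3, 4) / choose(6, 4)) +
    (1 - choose(4, 4) / choose(6, 4)) + (1 - choose(5, 4) / choose(6, 4))
  expect_equal(ar$per_cell[1, "A"], exact, tolerance = 1e-12)
  set.seed(12)
  expect_equal(ar$per_cell[1, "A"], bf_ar_mc(c(3, 2, 1), 4), tolerance = 0.02)
  # g = n returns the observed allele count; g = 1 returns 1
  expect_equal(allelic_richness(gm, 6)$per_cell[1, "A"], 3)
  expect_equal(allelic_richness(gm, 1)$per_cell[1, "A"], 1)
  expect_error(allelic_richness(gm, 0), "g_copies")
  expect_error(allelic_richness(gm, 7), "exceeds")
})

test_that("allelic richness is monotone non-decreasing in g", {
  set.seed(13)
  gm <- random_gm(n = 12, L = 4, miss = 0.05)
  gs <- 1:min(allele_frequencies(gm)$n)
  ar <- vapply(gs, function(g) allelic_richness(gm, g)$per_pop[["A"]], 0)
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("observed heterozygosity and gene diversity match closed forms", {
  gm <- toy_gm(c(1, 1), c(2, 1), c("A", "A"))
  expect_equal(observed_heterozygosity(gm, "A")$per_locus[[1]], 0.5)
  hom <- toy_gm(c(1, 2), c(1, 2), c("A", "A"))
  expect_equal(observed_heterozygosity(hom, "A")$per_locus[[1]], 0)
  expect_equal(gene_diversity(hom, "A")$per_locus[[1]],
               4 / 3 * 0.5)  # n=4 copies at 0.5/0.5
  mono <- toy_gm(c(1, 1), c(1, 1), c("A", "A"))
  expect_equal(gene_diversity(mono, "A")$per_locus[[1]], 0)
  # two alleles at 0.5, n = 200 copies
  g200 <- toy_gm(rep(1, 100), rep(2, 100), rep("A", 100))
  expect_equal(gene_diversity(g200, "A")$per_locus[[1]], 200 / 199 * 0.5)
})

test_that("H_O, H_E and F_IS equal brute-force recomputations", {
  set.seed(14)
  for (rep in 1:5) {
    gm <- random_gm(n = 5, L = 3, miss = 0.15)
    for (p in c("A", "B")) {
      expect_equal(unname(observed_heterozygosity(gm, p)$per_locus),
                   vapply(1:3, function(l) bf_ho(gm, p, l), 0),
                   tolerance = 1e-10)
      expect_equal(unname(gene_diversity(gm, p)$per_locus),
                   vapply(1:3, function(l) bf_he(gm, p, l), 0),
                   tolerance = 1e-10)
      expect_equal(fis(gm, p), bf_fis(gm, p), tolerance = 1e-10)
    }
  }
})

test_that("gene diversity estimator is unbiased", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  truth <- 1 - sum(p^2)
  set.seed(15)
  est <- replicate(2000, {
    copies <- sample(4, 10, TRUE, p)
    f <- tabulate(copies, 4) / 10
    10 / 9 * (1 - sum(f^2))
  })
  expect_lt(abs(mean(est) - truth), 3 * sd(est) / sqrt(2000))
})

test_that("F_IS hits its closed-form anchors", {
  # H_O == H_E impossible exactly; construct H_O = 0 with H_E > 0
  gm <- toy_gm(c(1, 2), c(1, 2), c("A", "A"))
  expect_equal(fis(gm, "A"), 1)
  mono <- toy_gm(c(1, 1), c(1, 1), c("A", "A"))
  expect_true(is.na(fis(mono, "A")))
})

test_that("F_IS reaches the mixed-mating equilibrium s/(2-s)", {
  set.seed(16)
  g0 <- generate_bn_data(200, 1, 11, 8, fst = 0)
  expect_lt(abs(fis(g0, "P1")), 0.05)          # random mating: F_IS ~ 0
  g6 <- apply_selfing(g0, 0.6, generations = 15)
  expect_lt(abs(fis(g6, "P1") - 0.6 / 1.4), 0.05)
})

test_that("individual inbreeding likelihood behaves at its boundaries", {
  set.seed(17)
  gm <- generate_bn_data(50, 1, 11, 6, fst = 0)
  # force individual 1 fully heterozygous, individual 2 fully homozygous
  gm$a1[1, ] <- 101L; gm$a2[1, ] <- 102L
  gm$a1[2, ] <- 103L; gm$a2[2, ] <- 103L
  expect_equal(individual_inbreeding(gm, 1)$F, 0)
  expect_gt(individual_inbreeding(gm, 2)$F, 0.8)
  # grid maximum agrees with a dense optimizer within one grid step
  i <- 10
  aft <- allele_frequencies(gm)
  ll <- function(F) {
    s <- 0
    for (l in 1:11) {
      x1 <- gm$a1[i, l]; x2 <- gm$a2[i, l]
      f <- aft$freq[[l]][["P1"]]
      s <- s + if (x1 == x2) log(F * f[as.character(x1)] +
                                   (1 - F) * f[as.character(x1)]^2)
      else log((1 - F) * 2 * f[as.character(x1)] * f[as.character(x2)])
    }
    s
  }
  opt <- optimize(ll, c(0, 0.999), maximum = TRUE)$maximum
  expect_lt(abs(individual_inbreeding(gm, i)$F - opt), 0.011)
})

test_that("HWE Monte-Carlo exact test separates equilibrium from excess", {
  set.seed(18)
  gm <- generate_bn_data(150, 1, 1, 4, fst = 0)   # HW proportions by design
  expect_gt(hwe_test(gm, "L1", "P1", n_perm = 2000), 0.2)
  allhet <- toy_gm(rep(1, 50), rep(2, 50), rep("A", 50))
  expect_lt(hwe_test(allhet, "L1", "A", n_perm = 2000), 0.01)
  mono <- toy_gm(rep(1, 10), rep(1, 10), rep("A", 10))
  expect_equal(hwe_test(mono, "L1", "A"), 1)
  expect_error(hwe_test(gm, "L1", "P1", n_perm = 10), "n_perm")
})

test_that("LD permutation test flags perfect association only", {
  set.seed(19)
  gm <- generate_bn_data(60, 1, 2, 6, fst = 0)
  gm$a1[, 2] <- gm$a1[, 1]; gm$a2[, 2] <- gm$a2[, 1]   # locus B = locus A
  expect_lte(ld_test(gm, "L1", "L2", "P1", n_perm = 199), 1 / 200)
  mono <- genotype_matrix(cbind(c(1L, 1L, 2L), c(7L, 7L, 7L)),
                          cbind(c(1L, 1L, 2L), c(7L, 7L, 7L)),
                          pop = c("A", "A", "A"))
  expect_equal(ld_test(mono, "L1", "L2", "A"), 1)
})

test_that("H_E difference test returns 1 for identical populations", {
  set.seed(20)
  g <- generate_bn_data(30, 2, 5, 6, fst = 0)
  g$a1[31:60, ] <- g$a1[1:30, ]; g$a2[31:60, ] <- g$a2[1:30, ]
  expect_equal(he_difference_test(g, "P1", "P2", n_perm = 99), 1)
  expect_error(he_difference_test(g, "P1", "nope"), "empty population")
})

test_that("H_E difference test detects a planted diversity gap", {
  set.seed(21)
  hits <- replicate(20, {
    gA <- matrix(sample(1:3, 80 * 2 * 5, TRUE), 160, 5)     # low diversity
    gB <- matrix(sample(1:12, 80 * 2 * 5, TRUE), 160, 5)    # high diversity
    gm <- genotype_matrix(rbind(gA[1:80, ], gB[1:80, ]),
                          rbind(gA[81:160, ], gB[81:160, ]),
                          pop = rep(c("A", "B"), each = 80))
    he_difference_test(gm, "A", "B", n_perm = 199) < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Bonferroni correction reproduces the paired-comparison decisions", {
  b <- bonferroni(c(0.037, 0.001, 0.005), m = 3)
  expect_equal(b$threshold, rep(0.05 / 3, 3))
  expect_equal(b$significant, c(FALSE, TRUE, TRUE))
  expect_equal(bonferroni(0.04, m = 1)$significant, TRUE)
  expect_equal(nrow(bonferroni(numeric(0))), 0)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})

test_that("diversity table mirrors the conventional layout and invariants", {
  set.seed(22)
  gm <- generate_bn_data(30, 3, 6, 6, fst = 0.1)
  dt <- diversity_table(gm)
  expect_equal(dt$pop, c("P1", "P2", "P3", "overall"))
  expect_true(all(dt$A_freq <= dt$A))
  expect_true(all(dt$PA[1:3] <= dt$A[1:3]))
  expect_true(all(dt$H_O >= 0 & dt$H_O <= 1))
  expect_true(all(dt$H_E >= 0 & dt$H_E <= 1))
  expect_true(all(dt$AR[1:3] <= dt$A[1:3]))
  expect_equal(dt$N, c(30, 30, 30, 90))
})
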