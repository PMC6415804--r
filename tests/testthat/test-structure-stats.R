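test_that("Weir-Cockerham theta hits its anchors", {
  # fixation: theta = 1
  g <- toy_gm(c(1, 1, 1, 2, 2, 2), c(1, 1, 1, 2, 2, 2),
              rep(c("A", "B"), each = 3))
  expect_equal(pairwise_fst(g)$matrix["A", "B"], 1)
  # panmixia: |theta| small at n = 100 per pop
  set.seed(40)
  g0 <- generate_bn_data(100, 2, 20, 8, fst = 0)
  expect_lt(abs(pairwise_fst(g0)$matrix[1, 2]), 0.02)
})

test_that("per-pair theta equals the independent component-sum oracle", {
  set.seed(41)
  for (rep in 1:5) {
    gm <- random_gm(n = 4, L = 3, pops = c("A", "B"), miss = 0.1)
    expect_equal(pairwise_fst(gm)$matrix["A", "B"],
                 unname(bf_wc_theta(gm, c("A", "B"))), tolerance = 1e-10)
  }
  gm3 <- random_gm(n = 4, L = 2, pops = c("A", "B", "C"), miss = 0)
  m <- pairwise_fst(gm3)$matrix
  for (pr in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_equal(m[pr[1], pr[2]], unname(bf_wc_theta(gm3, pr)),
                 tolerance = 1e-10)
})

test_that("Nei (1972) distance follows the ratio-of-sums convention", {
  gm <- toy_gm(c(1, 1, 1, 1), c(2, 2, 2, 2), rep(c("A", "B"), each = 2))
  aft <- allele_frequencies(gm)
  expect_equal(nei_distance(aft, "A", "B")$D, 0)   # identical frequencies
  # disjoint allele sets: infinite, flagged
  gm2 <- toy_gm(c(1, 1, 3, 3), c(2, 2, 4, 4), rep(c("A", "B"), each = 2))
  nd <- nei_distance(allele_frequencies(gm2), "A", "B")
  expect_true(nd$infinite)
  expect_equal(nd$D, Inf)
  # toy case against the direct formula
  set.seed(42)
  gm3 <- random_gm(n = 6, L = 3, miss = 0)
  aft3 <- allele_frequencies(gm3)
  jxy <- jx <- jy <- 0
  for (l in 1:3) {
    fa <- aft3$freq[[l]]$A; fb <- aft3$freq[[l]]$B
    al <- union(names(fa), names(fb))
    xa <- ifelse(is.na(fa[al]), 0, fa[al]); xb <- ifelse(is.na(fb[al]), 0, fb[al])
    jxy <- jxy + sum(xa * xb); jx <- jx + sum(xa^2); jy <- jy + sum(xb^2)
  }
  expect_equal(nei_distance(aft3, "A", "B")$D, -log(jxy / sqrt(jx * jy)),
               tolerance = 1e-12)
})

test_that("AMOVA components equal the explicit O(n^2) oracle", {
  set.seed(43)
  for (rep in 1:4) {
    gm <- random_gm(n = 3, L = 2, pops = c("A", "B"), miss = 0.1)
    got <- amova(gm, n_perm = 0)
    want <- bf_amova3(gm)
    expect_equal(got$table$SSD, want$ssd, tolerance = 1e-10)
    expect_equal(got$table$df, want$df)
    expect_equal(got$table$sigma2, want$sigma, tolerance = 1e-10)
    expect_equal(sum(got$table$percent), 100, tolerance = 0.01)
  }
})

test_that("AMOVA percentages respond to structure as expected", {
  # fixed differences: among-population share near 100
  g <- toy_gm(c(rep(1, 6), rep(2, 6)), c(rep(1, 6), rep(2, 6)),
              rep(c("A", "B"), each = 6))
  expect_gt(amova(g, n_perm = 49)$table$percent[1], 95)
  # one panmictic pool split in two: among share ~ 0 on average
  set.seed(44)
  among <- replicate(60, {
    g0 <- generate_bn_data(40, 2, 6, 6, fst = 0)
    amova(g0, n_perm = 0)$table$percent[1]
  })
  expect_lt(abs(mean(among)), 3)
})

test_that("permuting population labels destroys the among-group signal", {
  set.seed(45)
  gm <- generate_bn_data(50, 2, 8, 6, fst = 0.2)
  obs <- amova(gm, n_perm = 0)$table$sigma2[1]
  perm <- replicate(30, {
    g2 <- gm; g2$pop <- sample(g2$pop)
    amova(g2, n_perm = 0)$table$sigma2[1]
  })
  expect_gt(obs, max(perm))
  expect_lt(abs(mean(perm)) / obs, 0.1)
})

test_that("four-level AMOVA partitions regions within groups", {
  set.seed(46)
  gm <- generate_bn_data(24, 4, 6, 6, fst = 0.15)
  gm$region <- gm$pop                       # regions = the 4 demes
  gm$pop <- rep(c("G1", "G2"), each = 48)   # two islands of two regions
  r <- amova(gm, hierarchy = c("pop", "region"), n_perm = 19)
  expect_equal(r$table$level,
               c("among_groups", "among_pops_within_groups",
                 "among_ind_within_pops", "within_ind"))
  expect_equal(sum(r$table$percent), 100, tolerance = 0.01)
  expect_equal(length(r$phi), 4)
})

test_that("PCoA reproduces planar configurations and flags asymmetry", {
  D3 <- matrix(1, 3, 3) - diag(3)           # three equidistant points
  p3 <- pcoa(dist_matrix(letters[1:3], D3, "t"))
  ev <- p3$eigenvalues[p3$eigenvalues > 1e-9]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  set.seed(47)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X))
  pc <- pcoa(dist_matrix(rownames(D), D, "t"))
  expect_lt(max(abs(as.matrix(dist(pc$coords[, 1:2])) - D)), 1e-8)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-8)
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("dosage distance feeds an individual-level PCoA", {
  set.seed(48)
  gm <- generate_bn_data(20, 2, 6, 5, fst = 0.3)
  dd <- dosage_distance(gm)
  expect_equal(dd$kind, "Euclidean-individual")
  expect_equal(diag(dd$matrix), setNames(rep(0, 40), gm$ind))
  pc <- pcoa(dd)
  expect_true(all(pc$percent >= 0))
})

test_that("Mantel test statistics and permutation p behave", {
  set.seed(49)
  A <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  m <- mantel(A, A, n_perm = 199)
  expect_equal(m$r, 1)
  expect_lte(m$p, 1 / 200)
  noise <- as.matrix(dist(matrix(rnorm(20, sd = 0.01), 10, 2)))
  m2 <- mantel(A, 2 * A + noise, n_perm = 99)
  expect_gt(m2$r, 0.99)
  expect_error(mantel(A[1:2, 1:2], A[1:2, 1:2]), ">= 3")
})

test_that("geographic distances are symmetric haversine kilometres", {
  co <- rbind(p1 = c(0, -90), p2 = c(0, -90), p3 = c(1, -90))
  d <- geographic_distances(co)
  expect_equal(d$matrix["p1", "p2"], 0)
  expect_equal(d$matrix["p1", "p3"], 111.2, tolerance = 0.002)
  expect_equal(d$matrix, t(d$matrix))
  expect_error(geographic_distances(rbind(a = c(NA, 1))), "missing coordinates")
})

test_that("region centroids average member coordinates", {
  gm <- toy_gm(c(1, 1, 2, 2), c(1, 2, 2, 2), rep("A", 4))
  gm$region <- c("r1", "r1", "r2", "r2")
  gm$coords <- cbind(lat = c(0, 2, 10, 10), lon = c(-90, -92, -80, -80))
  ce <- centroid_coords(gm, "region")
  expect_equal(ce["r1", "lat"], 1)
  expect_equal(ce["r1", "lon"], -91)
})
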