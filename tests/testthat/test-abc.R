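test_that("the summary vector has its fixed 9-number layout", {
  set.seed(80)
  gm <- generate_bn_data(20, 3, 5, 6, fst = 0.15)
  s <- summarize_dataset(gm)
  expect_length(s, 9)
  expect_equal(names(s)[1:3], paste0("nal.", c("P1", "P2", "P3")))
  expect_equal(names(s)[7:9], c("fst.P1.P2", "fst.P1.P3", "fst.P2.P3"))
  # monomorphic data: allele counts 1, diversities 0, F_ST 0/undefined
  mono <- genotype_matrix(matrix(1L, 9, 2), matrix(1L, 9, 2),
                          pop = rep(c("A", "B", "C"), each = 3))
  sm <- summarize_dataset(mono)
  expect_equal(unname(sm[1:6]), c(1, 1, 1, 0, 0, 0))
  # permutation invariance
  gm2 <- subset_individuals(gm, sample(nrow(gm$a1)))
  expect_equal(summarize_dataset(gm2), s)
  # independent recomputation
  expect_equal(unname(s["het.P1"]), gene_diversity(gm, "P1")$mean)
  expect_equal(unname(s["fst.P1.P3"]), unname(bf_wc_theta(gm, c("P1", "P3"))),
               tolerance = 1e-10)
})

test_that("reference tables are complete, reproducible, and scenario-tagged", {
  space <- build_scenario_space()
  ref <- build_reference_table(space, n_per_scenario = 6,
                               sample_sizes = c(10, 10, 10), n_loci = 3,
                               seed = 42)
  expect_equal(nrow(ref), 84)
  expect_equal(sort(unique(ref$scenario)), 1:14)
  expect_true(all(is.finite(as.matrix(ref[, guavapop:::summary_cols(ref)]))))
  ref2 <- build_reference_table(space, n_per_scenario = 6,
                                sample_sizes = c(10, 10, 10), n_loci = 3,
                                seed = 42)
  expect_identical(ref, ref2)
})

test_that("founder bottlenecks depress simulated allele counts", {
  space <- build_scenario_space()
  s <- space[[10]]
  harsh <- s; harsh$priors <- prior_spec(founder_range = c(10, 30),
                                         time_range = c(20, 200))
  free <- s; free$no_bottleneck <- TRUE
  free$priors <- prior_spec(time_range = c(20, 200))
  ref <- build_reference_table(list(harsh, free), n_per_scenario = 40,
                               sample_sizes = c(15, 15, 15), n_loci = 5,
                               seed = 7)
  nal <- rowMeans(ref[, c("nal.Isabela", "nal.SantaCruz")])
  p <- t.test(nal[ref$scenario == harsh$id & seq_len(80) <= 40],
              nal[41:80], alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("rejection keeps the closest rows under MAD normalization", {
  set.seed(81)
  space <- build_scenario_space()
  ref <- build_reference_table(space[1:3], n_per_scenario = 20,
                               sample_sizes = c(8, 8, 8), n_loci = 3,
                               seed = 3)
  sc <- guavapop:::summary_cols(ref)
  obs <- unlist(ref[17, sc])
  ret <- abc_rejection(ref, obs, tolerance = 1, floor_retain = 1)
  expect_equal(nrow(ret), nrow(ref))          # tolerance 1 keeps everything
  expect_equal(ret$dist[1], 0)                # the matching row ranks first
  # brute-force sort oracle
  mads <- apply(as.matrix(ref[, sc]), 2, mad)
  mads[mads == 0] <- 1
  d <- sqrt(colSums(((t(as.matrix(ref[, sc])) - obs) / mads)^2))
  ret10 <- abc_rejection(ref, obs, tolerance = 10 / nrow(ref), floor_retain = 1)
  expect_equal(ret10$dist, sort(d)[1:10], tolerance = 1e-12)
})

test_that("logistic model choice is symmetric for identical simulators", {
  space <- build_scenario_space()
  twin <- space[[1]]; twin$id <- 99L
  set.seed(82)
  ref <- build_reference_table(list(space[[1]], twin), n_per_scenario = 150,
                               sample_sizes = c(10, 10, 10), n_loci = 4,
                               seed = 11)
  par <- sample_priors(space[[1]])
  gm <- simulate_dataset(space[[1]], par, c(10, 10, 10), 4)
  obs <- summarize_dataset(gm)
  ret <- abc_rejection(ref, obs, tolerance = 0.5, floor_retain = 50)
  post <- model_posterior_logistic(ret, obs)
  expect_equal(sum(post$posterior$prob), 1, tolerance = 1e-9)
  expect_lt(abs(post$posterior$prob[1] - 0.5), 0.25)
  # single-scenario degenerate case
  only <- ret[ret$scenario == 1, ]
  attr(only, "scale") <- attr(ret, "scale")
  expect_warning(p1 <- model_posterior_logistic(only, obs), "single scenario")
  expect_equal(p1$posterior$prob, 1)
})

test_that("separable scenarios are recovered by the logistic posterior", {
  # strong founder bottlenecks versus none: the classic identifiable pair
  space <- build_scenario_space()
  s <- space[[10]]
  harsh <- s
  harsh$priors <- prior_spec(founder_range = c(10, 40),
                             time_range = c(20, 300), db_range = c(10, 50))
  free <- s; free$id <- 15L; free$no_bottleneck <- TRUE
  free$priors <- prior_spec(time_range = c(20, 300), db_range = c(10, 50))
  ref <- build_reference_table(list(harsh, free), n_per_scenario = 250,
                               sample_sizes = c(20, 20, 20), n_loci = 8,
                               seed = 13)
  set.seed(83)
  hits <- replicate(20, {
    par <- sample_priors(harsh, harsh$priors)
    gm <- simulate_dataset(harsh, par, c(20, 20, 20), 8)
    obs <- summarize_dataset(gm)
    ret <- abc_rejection(ref, obs, tolerance = 0.2, floor_retain = 100)
    post <- suppressWarnings(model_posterior_logistic(ret, obs))
    post$posterior$scenario[which.max(post$posterior$prob)] == harsh$id
  })
  expect_gte(mean(hits), 0.7)
})

test_that("posteriors are stable under duplication of the reference table", {
  space <- build_scenario_space()
  set.seed(84)
  ref <- build_reference_table(space[c(1, 8)], n_per_scenario = 120,
                               sample_sizes = c(10, 10, 10), n_loci = 4,
                               seed = 21)
  par <- sample_priors(space[[1]])
  gm <- simulate_dataset(space[[1]], par, c(10, 10, 10), 4)
  obs <- summarize_dataset(gm)
  p1 <- model_posterior_logistic(abc_rejection(ref, obs, 0.5, 10), obs)
  ref2 <- rbind(ref, ref)
  attr(ref2, "mut_model") <- attr(ref, "mut_model")
  p2 <- model_posterior_logistic(abc_rejection(ref2, obs, 0.5, 10), obs)
  expect_lt(max(abs(p1$posterior$prob - p2$posterior$prob)), 0.1)
})

test_that("local-linear adjustment concentrates the posterior", {
  space <- build_scenario_space()
  s <- space[[10]]
  s$priors <- prior_spec(time_range = c(20, 2000))
  ref <- build_reference_table(list(s), n_per_scenario = 600,
                               sample_sizes = c(15, 15, 15), n_loci = 6,
                               seed = 31)
  set.seed(85)
  # observed = one simulated row's summaries: posterior should beat the prior
  sc <- guavapop:::summary_cols(ref)
  obs <- unlist(ref[100, sc])
  ret <- abc_rejection(ref, obs, tolerance = 0.2, floor_retain = 50)
  post <- param_posterior_loclinear(ret, obs)
  expect_true(post$t2$adjusted)
  ratios <- vapply(names(post), function(p)
    var(log(post[[p]]$draws)) / var(log(ref[[p]])), 0)
  expect_lt(mean(ratios), 1)   # concentration relative to the prior
  expect_true(all(c("mean", "median", "q025", "q975") %in% names(post$t1)))
  # zero-signal limit: if the regression slope is 0 the draws equal rejection
  flat <- ret; flat[, sc] <- 0
  attr(flat, "scale") <- attr(ret, "scale")
  p0 <- param_posterior_loclinear(flat, setNames(rep(0, 9), sc))
  expect_equal(sort(p0$t2$draws), sort(flat$t2), tolerance = 1e-8)
})

test_that("credible intervals cover planted introduction times", {
  space <- build_scenario_space()
  s <- space[[10]]
  s$priors <- prior_spec(size_range = c(50, 5000), founder_range = c(10, 100),
                         time_range = c(10, 1000), db_range = c(5, 50))
  ref <- build_reference_table(list(s), n_per_scenario = 1500,
                               sample_sizes = c(20, 20, 20), n_loci = 8,
                               seed = 41)
  set.seed(86)
  cover <- replicate(15, {
    par <- c(N1 = 300, N2 = 800, N3 = 1000, N1b = 25, N2b = 40, N3b = 40,
             t1 = 50, t2 = 500, db = 10)
    gm <- simulate_dataset(s, par, c(20, 20, 20), 8)
    obs <- summarize_dataset(gm)
    ret <- abc_rejection(ref, obs, 0.1, 150)
    post <- param_posterior_loclinear(ret, obs, c("t1", "t2"))
    q1 <- quantile(post$t1$draws, c(0.05, 0.95))
    q2 <- quantile(post$t2$draws, c(0.05, 0.95))
    c(q1[1] <= 50 & 50 <= q1[2], q2[1] <= 500 & 500 <= q2[2])
  })
  expect_gte(mean(cover[1, ]), 0.7)
  expect_gte(mean(cover[2, ]), 0.7)
})

test_that("calendar-to-generation conversion floors correctly", {
  expect_equal(generations_since(1890, 2016, 2), 63L)
  expect_equal(generations_since(2000, 2000 + 2 * 17, 2), 17L)
  expect_equal(generations_since(1890, 2016, 1), 126L)
  expect_error(generations_since(2016, 1890, 2), "exceed")
  expect_error(generations_since(1890, 2016, 0), "positive")
})
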