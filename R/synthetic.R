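#' Configuration for study-like synthetic datasets
#'
#' Defaults emulate the three-island sampling design the package targets:
#' 95/80/94 diploid individuals (Isabela, Santa Cruz, San Cristobal), 11
#' polymorphic SSR loci, a serial-introduction scenario with the outermost
#' island ancestral (San Cristobal -> Isabela at t2, Santa Cruz founded from
#' Isabela at t1), founder bottlenecks of a few tens of plants, partial
#' selfing strong enough to push F_IS into the 0.3-0.6 band, per-locus null
#' alleles up to ~0.25, and a small missing-data rate.
#'
#' @param sample_sizes diploid sizes per island.
#' @param n_loci number of loci.
#' @param N present-day effective sizes (N1, N2, N3).
#' @param Nb founder (bottleneck) sizes (N1b, N2b, N3b).
#' @param t1,t2 introduction times in generations before present (t2 >= t1).
#' @param db bottleneck duration in generations.
#' @param selfing per-island selfing probabilities.
#' @param selfing_generations mating rounds applied after the coalescent.
#' @param null_rate_range per-locus null-allele frequency range (uniform).
#' @param missing_rate independent genotype dropout probability.
#' @param mut_model a [mutation_model()].
#' @param seed RNG seed.
#' @return A `study_config` list.
#' @export
study_config <- function(sample_sizes = c(95, 80, 94), n_loci = 11,
                         N = c(75, 800, 1000), Nb = c(20, 50, 50),
                         t1 = 35, t2 = 120, db = 5,
                         selfing = c(0.75, 0.55, 0.65),
                         selfing_generations = 8L,
                         null_rate_range = c(0, 0.25),
                         missing_rate = 0.02,
                         mut_model = mutation_model("SMM", rate = c(1e-4, 1e-3)),
                         seed = 1L) {
  stopifnot(all(sample_sizes >= 2), t2 >= t1,
            all(selfing >= 0 & selfing < 1),
            missing_rate >= 0, missing_rate < 1)
  structure(list(sample_sizes = sample_sizes, n_loci = n_loci, N = N, Nb = Nb,
                 t1 = t1, t2 = t2, db = db, selfing = selfing,
                 selfing_generations = selfing_generations,
                 null_rate_range = null_rate_range,
                 missing_rate = missing_rate, mut_model = mut_model,
                 seed = seed), class = "study_config")
}

#' Partial-selfing mating generations
#'
#' Each generation replaces the population by offspring: with probability
#' `rate[pop]` an offspring is produced by selfing a random parent (both
#' gametes from the same individual), otherwise by outcrossing two random
#' distinct parents of the same population. Repeated generations drive F_IS
#' toward the mixed-mating equilibrium `s / (2 - s)` without altering allele
#' frequencies in expectation.
#'
#' @param gm a [genotype_matrix()].
#' @param rate selfing probability per population (recycled across the
#'   populations in order of first appearance).
#' @param generations mating rounds.
#' @return A new [genotype_matrix()].
#' @export
apply_selfing <- function(gm, rate, generations = 8L) {
  pops <- unique(gm$pop)
  rate <- rep(rate, length.out = length(pops))
  a1 <- gm$a1; a2 <- gm$a2
  for (g in seq_len(generations)) {
    new1 <- a1; new2 <- a2
    for (pi in seq_along(pops)) {
      idx <- which(gm$pop == pops[pi])
      n <- length(idx)
      p1 <- idx[sample.int(n, n, replace = TRUE)]
      self <- stats::runif(n) < rate[pi]
      p2 <- ifelse(self, p1, idx[sample.int(n, n, replace = TRUE)])
      pick1 <- stats::runif(n * ncol(a1)) < 0.5
      pick2 <- stats::runif(n * ncol(a1)) < 0.5
      g1 <- ifelse(pick1, a1[p1, ], a2[p1, ])
      g2 <- ifelse(pick2, a1[p2, ], a2[p2, ])
      miss <- is.na(g1) | is.na(g2)
      g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
      new1[idx, ] <- g1; new2[idx, ] <- g2
    }
    a1 <- new1; a2 <- new2
  }
  genotype_matrix(a1, a2, pop = gm$pop, loci = gm$loci, ind = gm$ind,
                  region = gm$region, coords = gm$coords)
}

#' Inject null alleles
#'
#' Per locus, a randomly chosen set of allele types with total frequency
#' close to the requested rate is relabelled as a null lineage: a
#' visible/null heterozygote appears as a visible homozygote, a null/null
#' genotype becomes missing. Because whole allele lineages are silenced, the
#' null segregates like a real allele and the EM estimator's model holds.
#'
#' @param gm a [genotype_matrix()].
#' @param rates per-locus target null frequencies (recycled).
#' @return list with `gm` (modified matrix) and `achieved` (realized overall
#'   null frequency per locus). Rates >= 0.5 trigger a warning (EM
#'   identifiability degrades).
#' @export
inject_null_alleles <- function(gm, rates) {
  rates <- rep(rates, length.out = length(gm$loci))
  if (any(rates >= 0.5))
    warning("null-allele rate >= 0.5: EM identifiability degrades")
  a1 <- gm$a1; a2 <- gm$a2
  achieved <- numeric(length(gm$loci))
  for (l in seq_along(gm$loci)) {
    if (rates[l] <= 0) next
    copies <- c(a1[, l], a2[, l])
    tab <- table(copies)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    ord <- sample(names(f))
    cum <- 0; nulls <- character(0)
    for (a in ord) {
      if (abs(cum + f[a] - rates[l]) < abs(cum - rates[l])) {
        nulls <- c(nulls, a); cum <- cum + f[a]
      }
    }
    if (!length(nulls)) next
    achieved[l] <- cum
    n1 <- a1[, l] %in% as.integer(nulls)
    n2 <- a2[, l] %in% as.integer(nulls)
    # one null copy: apparent homozygote for the visible allele
    a1[n1 & !n2, l] <- a2[n1 & !n2, l]
    a2[!n1 & n2, l] <- a1[!n1 & n2, l]
    # two null copies: blank (missing)
    a1[n1 & n2, l] <- NA_integer_
    a2[n1 & n2, l] <- NA_integer_
  }
  list(gm = genotype_matrix(a1, a2, pop = gm$pop, loci = gm$loci,
                            ind = gm$ind, region = gm$region,
                            coords = gm$coords),
       achieved = achieved)
}

#' Inject missing genotypes
#'
#' @param gm a [genotype_matrix()].
#' @param rate independent dropout probability per genotype, in [0, 1).
#' @return A new [genotype_matrix()].
#' @export
inject_missing <- function(gm, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(gm)
  a1 <- gm$a1; a2 <- gm$a2
  drop <- matrix(stats::runif(length(a1)) < rate, nrow(a1))
  a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  genotype_matrix(a1, a2, pop = gm$pop, loci = gm$loci, ind = gm$ind,
                  region = gm$region, coords = gm$coords)
}

#' Generate a study-like dataset with known ground truth
#'
#' Simulates the configured demographic scenario, applies partial-selfing
#' mating generations, silences null-allele lineages and injects missing
#' data. The returned ground truth records everything needed to score
#' recovery experiments: the scenario, the demographic parameters, the
#' achieved per-locus null frequencies and the selfing rates.
#'
#' @param config a [study_config()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth`.
#' @export
generate_study_like <- function(config = study_config()) {
  set.seed(config$seed)
  space <- build_scenario_space()
  scenario <- match_scenario(space, ancestral = 3, first = 1,
                             second_source = 1)
  params <- c(N1 = config$N[1], N2 = config$N[2], N3 = config$N[3],
              N1b = config$Nb[1], N2b = config$Nb[2], N3b = config$Nb[3],
              t1 = config$t1, t2 = config$t2, db = config$db)
  gm <- simulate_dataset(scenario, params, config$sample_sizes,
                         config$n_loci, config$mut_model)
  gm <- apply_selfing(gm, config$selfing, config$selfing_generations)
  null_rates <- stats::runif(config$n_loci, config$null_rate_range[1],
                             config$null_rate_range[2])
  inj <- inject_null_alleles(gm, null_rates)
  gm <- inject_missing(inj$gm, config$missing_rate)
  list(gm = gm,
       truth = list(scenario = scenario, params = params,
                    null_rates_target = null_rates,
                    null_rates_achieved = inj$achieved,
                    selfing = config$selfing, config = config))
}

#' Two-population Balding-Nichols data with known structure
#'
#' A lightweight generator for clustering and permutation-test calibration:
#' per locus, ancestral allele frequencies are drawn from a symmetric
#' Dirichlet, each population's frequencies from
#' Dirichlet(p * (1 - F)/F) (so the among-population fixation index is ~F),
#' and genotypes by random union of gametes within populations.
#'
#' @param n_per_pop diploid individuals per population.
#' @param n_pops number of populations.
#' @param n_loci loci.
#' @param n_alleles alleles per locus.
#' @param fst target differentiation (Balding-Nichols F).
#' @return A [genotype_matrix()] with populations `P1..`, plus attribute
#'   `"pop_freqs"`.
#' @export
generate_bn_data <- function(n_per_pop = 100, n_pops = 2, n_loci = 11,
                             n_alleles = 8, fst = 0.2) {
  rdir <- function(shape) { x <- stats::rgamma(length(shape), shape); x / sum(x) }
  pops <- paste0("P", seq_len(n_pops))
  n <- n_per_pop * n_pops
  a1 <- matrix(NA_integer_, n, n_loci); a2 <- matrix(NA_integer_, n, n_loci)
  freqs <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    anc <- rdir(rep(1, n_alleles))
    pf <- lapply(seq_len(n_pops), function(p) {
      if (fst <= 0) anc else rdir(anc * (1 - fst) / fst)
    })
    freqs[[l]] <- pf
    for (p in seq_len(n_pops)) {
      rows <- (p - 1) * n_per_pop + seq_len(n_per_pop)
      a1[rows, l] <- sample.int(n_alleles, n_per_pop, TRUE, prob = pf[[p]]) + 100L
      a2[rows, l] <- sample.int(n_alleles, n_per_pop, TRUE, prob = pf[[p]]) + 100L
    }
  }
  gm <- genotype_matrix(a1, a2, pop = rep(pops, each = n_per_pop),
                        loci = paste0("L", seq_len(n_loci)),
                        ind = paste0("i", seq_len(n)))
  attr(gm, "pop_freqs") <- freqs
  gm
}
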