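#' Microsatellite mutation model
#'
#' @param kind `"SMM"` (strict stepwise: every mutation is +-1 repeat unit)
#'   or `"TPM"` (two-phase: single steps with probability `p_single`,
#'   otherwise a geometric number of steps with mean `mean_multi`).
#' @param rate per-locus mutation rate per generation: a single value, or a
#'   range `c(lo, hi)` from which each locus draws its own rate uniformly.
#' @param p_single probability a mutation is a single step (TPM); forced to 1
#'   under SMM.
#' @param mean_multi mean multi-step jump size (TPM), geometric on 1, 2, ...
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(kind = c("SMM", "TPM"), rate = c(1e-4, 1e-3),
                           p_single = 0.9, mean_multi = 2.8) {
  kind <- match.arg(kind)
  if (kind == "SMM") p_single <- 1
  stopifnot(all(rate >= 0), all(rate < 1), p_single > 0, p_single <= 1,
            mean_multi >= 1)
  structure(list(kind = kind, rate = rate, p_single = p_single,
                 mean_multi = mean_multi), class = "mutation_model")
}

locus_rates <- function(mm, n_loci) {
  if (length(mm$rate) == 2L) stats::runif(n_loci, mm$rate[1], mm$rate[2])
  else rep(mm$rate, n_loci)
}

#' Colonization scenario space for a three-island system
#'
#' Enumerates the 14 demographic scenarios of a three-island invasion:
#' twelve "serial/parallel introduction" scenarios (3 choices of ancestral
#' island x 2 orderings of the two introduced islands x 2 sources for the
#' second introduction — the ancestral island or the first-introduced one),
#' plus two admixture scenarios in which the middle island (Santa Cruz) is
#' founded jointly by the other two, the source history differing between the
#' two. Every introduction carries a founder bottleneck (size `N_b` for
#' `d_b` generations after founding). The first introduction happens `t2`
#' generations ago, the second `t1`, with `t2 >= t1`.
#'
#' @param pop_names island names in the fixed order (Isabela, Santa Cruz,
#'   San Cristobal).
#' @return list of `demographic_scenario` objects, each with `id`,
#'   `ancestral`, `events` and a canonical `description` string (all 14 are
#'   pairwise distinct).
#' @export
build_scenario_space <- function(pop_names = c("Isabela", "SantaCruz",
                                               "SanCristobal")) {
  scenarios <- list()
  mk_split <- function(target, source, time) {
    list(type = "split", target = target, source = source, time = time)
  }
  for (anc in 1:3) {
    rem <- setdiff(1:3, anc)
    for (first in rem) {
      second <- setdiff(rem, first)
      for (src2 in c(anc, first)) {
        scenarios[[length(scenarios) + 1L]] <- list(
          ancestral = anc,
          events = list(mk_split(first, anc, "t2"),
                        mk_split(second, src2, "t1")))
      }
    }
  }
  # Santa Cruz (pop 2) of admixed origin; the two differ in which of the
  # outer islands is ancestral
  for (anc in c(3L, 1L)) {
    other <- setdiff(c(1L, 3L), anc)
    scenarios[[length(scenarios) + 1L]] <- list(
      ancestral = anc,
      events = list(mk_split(other, anc, "t2"),
                    list(type = "admix", target = 2L, sourceA = other,
                         sourceB = anc, time = "t1")))
  }
  lapply(seq_along(scenarios), function(i) {
    s <- scenarios[[i]]
    s$id <- i
    s$pop_names <- pop_names
    desc <- vapply(s$events, function(e) {
      if (e$type == "split")
        sprintf("%s: %d<-%d", e$time, e$target, e$source)
      else
        sprintf("%s: %d<-admix(%d,%d;r_a)", e$time, e$target, e$sourceA,
                e$sourceB)
    }, "")
    s$description <- paste0("anc=", s$ancestral, "; ",
                            paste(desc, collapse = "; "))
    class(s) <- "demographic_scenario"
    s
  })
}

#' Locate a scenario by its topology
#'
#' @param space output of [build_scenario_space()].
#' @param ancestral ancestral island index.
#' @param first island introduced first (at `t2`).
#' @param second_source source of the second introduction (split scenarios),
#'   or `"admix"` for the admixture scenarios.
#' @return the matching `demographic_scenario`.
#' @export
match_scenario <- function(space, ancestral, first, second_source) {
  for (s in space) {
    e1 <- s$events[[1]]; e2 <- s$events[[2]]
    if (s$ancestral != ancestral || e1$target != first) next
    if (identical(second_source, "admix")) {
      if (e2$type == "admix") return(s)
    } else if (e2$type == "split" && e2$source == second_source) return(s)
  }
  stop("no scenario with that topology")
}

#' Uniform prior specification for the demographic parameters
#'
#' Defaults: every population size (N1-N3, N1b-N3b), time (t1, t2) and
#' bottleneck duration (d_b) uniform on 10.0-10000.0; the admixture rate
#' r_a uniform on 0.001-0.999. Draws enforce `t2 >= t1`; one `d_b` is shared
#' by all bottlenecks of a draw.
#'
#' @param size_range,time_range,db_range,ra_range `c(lower, upper)` pairs.
#' @param founder_range range for the post-bottleneck founder sizes
#'   (N1b-N3b); defaults to `size_range`.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(size_range = c(10, 10000), time_range = c(10, 10000),
                       db_range = c(10, 10000), ra_range = c(0.001, 0.999),
                       founder_range = size_range) {
  chk <- function(x) stopifnot(length(x) == 2L, x[1] < x[2], all(x > 0))
  chk(size_range); chk(time_range); chk(db_range); chk(ra_range)
  chk(founder_range)
  structure(list(size = size_range, time = time_range, db = db_range,
                 ra = ra_range, founder = founder_range),
            class = "prior_spec")
}

#' Draw one parameter set from the priors
#'
#' @param scenario a `demographic_scenario` (admixture scenarios get `ra`).
#' @param priors a [prior_spec()].
#' @return named numeric vector `N1, N2, N3, N1b, N2b, N3b, t1, t2, db`
#'   (+ `ra` for admixture scenarios).
#' @export
sample_priors <- function(scenario, priors = prior_spec()) {
  u <- function(rg) stats::runif(1, rg[1], rg[2])
  repeat {
    t1 <- u(priors$time); t2 <- u(priors$time)
    if (t2 >= t1) break
  }
  fr <- if (is.null(priors$founder)) priors$size else priors$founder
  par <- c(N1 = u(priors$size), N2 = u(priors$size), N3 = u(priors$size),
           N1b = u(fr), N2b = u(fr), N3b = u(fr),
           t1 = t1, t2 = t2, db = u(priors$db))
  if (any(vapply(scenario$events, function(e) e$type == "admix", logical(1))))
    par <- c(par, ra = u(priors$ra))
  par
}

# Translate a scenario + parameter draw into the piecewise size schedule and
# lineage-movement table consumed by the C++ simulator.
scenario_plumbing <- function(scenario, params) {
  sizes <- params[c("N1", "N2", "N3")]
  bsizes <- params[c("N1b", "N2b", "N3b")]
  db <- params[["db"]]
  epochs <- cbind(pop = 1:3, t_start = 0, N = as.numeric(sizes))
  moves <- NULL
  # most-recent event first so that coincident move times resolve targets
  # before their sources move on
  no_btl <- isTRUE(scenario$no_bottleneck)
  for (e in rev(scenario$events)) {
    t <- params[[e$time]]
    tgt <- e$target
    if (bsizes[tgt] <= 0 || sizes[tgt] <= 0)
      stop("zero-size population on event '", e$time, "' (target ", tgt, ")")
    t_move <- if (no_btl) t else t + db
    if (!no_btl) epochs <- rbind(epochs, c(tgt, t, bsizes[tgt]))
    if (e$type == "split") {
      moves <- rbind(moves, c(t_move, tgt, e$source, 0, 1))
    } else {
      moves <- rbind(moves, c(t_move, tgt, e$sourceA, e$sourceB,
                              params[["ra"]]))
    }
  }
  colnames(moves) <- c("time", "target", "srcA", "srcB", "rA")
  list(epochs = epochs, moves = moves)
}

#' Simulate a microsatellite dataset under a demographic scenario
#'
#' Runs an independent structured coalescent per locus backward in time with
#' piecewise-constant sizes (the founder bottleneck `N_b` occupies the
#' interval `[t, t + d_b]` looking backward, after which the target's
#' lineages move into the source), places Poisson mutations on branches and
#' applies them as stepwise (or two-phase geometric) changes from ancestral
#' repeat count 100, then pairs gene copies at random into diploid
#' genotypes.
#'
#' @param scenario a `demographic_scenario`.
#' @param params a draw from [sample_priors()] (or any named vector with the
#'   same elements).
#' @param sample_sizes diploid sample sizes per population (study design:
#'   95/80/94).
#' @param n_loci number of independent loci.
#' @param mut_model a [mutation_model()].
#' @return A [genotype_matrix()] with the scenario's population names.
#' @export
simulate_dataset <- function(scenario, params, sample_sizes = c(95, 80, 94),
                             n_loci = 11, mut_model = mutation_model("SMM")) {
  pl <- scenario_plumbing(scenario, params)
  mu <- locus_rates(mut_model, n_loci)
  states <- cpp_sim_loci(as.integer(2 * sample_sizes), pl$epochs, pl$moves,
                         as.integer(n_loci), mu, mut_model$p_single,
                         mut_model$mean_multi, 100L)
  states_to_gm(states, sample_sizes, scenario$pop_names)
}

# pair consecutive gene copies into diploids (copies within a population are
# exchangeable, so consecutive pairing is random pairing); shift any locus
# whose mutational walk went non-positive so labels stay valid
states_to_gm <- function(states, sample_sizes, pop_names) {
  for (l in seq_len(ncol(states))) {
    mn <- min(states[, l])
    if (mn < 1L) states[, l] <- states[, l] + (1L - mn)
  }
  odd <- seq(1, nrow(states), by = 2)
  a1 <- states[odd, , drop = FALSE]
  a2 <- states[odd + 1, , drop = FALSE]
  pop <- rep(pop_names, sample_sizes)
  genotype_matrix(a1, a2, pop = pop,
                  loci = paste0("L", seq_len(ncol(states))),
                  ind = paste0(pop, ".", unlist(lapply(sample_sizes, seq_len))))
}

#' Simulate single-population equilibrium loci
#'
#' Constant-size coalescent at mutation-drift equilibrium, used by the
#' heterozygosity-excess machinery and for checking the simulator against
#' the stepwise-model equilibrium gene diversity `1 - 1/sqrt(1 + 2*theta)`.
#'
#' @param n_copies gene copies sampled.
#' @param theta scaled mutation rate `4*N*mu`.
#' @param n_loci independent loci to simulate.
#' @param mut_model a [mutation_model()]; its `rate` field is ignored (only
#'   `theta` matters at equilibrium).
#' @return integer matrix of allele states, `n_copies` x `n_loci`.
#' @export
sim_equilibrium_loci <- function(n_copies, theta, n_loci,
                                 mut_model = mutation_model("SMM")) {
  N <- 1000
  mu <- theta / (4 * N)
  cpp_sim_loci(as.integer(n_copies), cbind(1, 0, N),
               matrix(numeric(0), 0, 5), as.integer(n_loci),
               rep(mu, n_loci), mut_model$p_single, mut_model$mean_multi, 100L)
}
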