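#' Summary-statistic vector for ABC
#'
#' Nine numbers in fixed order for a three-population dataset: per population
#' the mean number of alleles across loci and the mean (unbiased) gene
#' diversity across loci, then the three pairwise Weir-Cockerham F_ST values
#' (pair order 1-2, 1-3, 2-3 in the order populations first appear).
#'
#' @param gm a [genotype_matrix()] with 3 populations.
#' @return named numeric vector
#'   `nal.<p1..3>, het.<p1..3>, fst.<p1p2>, fst.<p1p3>, fst.<p2p3>`.
#' @export
summarize_dataset <- function(gm) {
  pops <- unique(gm$pop)
  if (length(pops) < 2L) stop("need >= 2 populations")
  aft <- allele_frequencies(gm, "pop")
  nal <- vapply(pops, function(p)
    mean(vapply(seq_along(aft$loci), function(l)
      length(aft$freq[[l]][[p]]), 0L)), 0)
  het <- vapply(pops, function(p) gene_diversity(gm, p)$mean, 0)
  prs <- utils::combn(seq_along(pops), 2)
  fst <- apply(prs, 2, function(ij) wc_theta(gm, pops[ij]))
  names(nal) <- paste0("nal.", pops)
  names(het) <- paste0("het.", pops)
  names(fst) <- paste0("fst.", apply(prs, 2, function(ij)
    paste(pops[ij], collapse = ".")))
  c(nal, het, fst)
}

#' Build an ABC reference table
#'
#' For each scenario draws `n_per_scenario` parameter sets from the priors,
#' simulates a dataset of the study's design, and records the summary
#' statistics. Rows with non-finite summaries are dropped with a log entry.
#' Fully reproducible from `seed`; optionally checkpoints partial tables.
#'
#' @param scenarios list from [build_scenario_space()] (or a subset). A
#'   scenario may carry its own `priors` element, overriding the global one;
#'   a scenario with `no_bottleneck = TRUE` skips the founder-size epochs.
#' @param priors a [prior_spec()].
#' @param n_per_scenario simulations per scenario (>= 100 for real use;
#'   smaller is accepted for toy runs).
#' @param sample_sizes,n_loci,mut_model forwarded to [simulate_dataset()].
#' @param seed integer seed governing all randomness.
#' @param checkpoint_path optional CSV path; the accumulated table is written
#'   every `checkpoint_every` rows.
#' @param checkpoint_every rows between checkpoints.
#' @return A `reference_table` data.frame: `scenario`, the parameter columns,
#'   and the 9 summary columns; attributes `mut_model`, `priors`, `seed`.
#' @export
build_reference_table <- function(scenarios, priors = prior_spec(),
                                  n_per_scenario = 500L,
                                  sample_sizes = c(95, 80, 94), n_loci = 11,
                                  mut_model = mutation_model("SMM"),
                                  seed = 1L, checkpoint_path = NULL,
                                  checkpoint_every = 1000L) {
  set.seed(seed)
  rows <- vector("list", length(scenarios) * n_per_scenario)
  k <- 0L; dropped <- 0L
  for (s in scenarios) {
    for (j in seq_len(n_per_scenario)) {
      par <- sample_priors(s, if (is.null(s$priors)) priors else s$priors)
      gm <- simulate_dataset(s, par, sample_sizes, n_loci, mut_model)
      ss <- summarize_dataset(gm)
      if (any(!is.finite(ss))) { dropped <- dropped + 1L; next }
      full <- c(N1 = NA_real_, N2 = NA_real_, N3 = NA_real_, N1b = NA_real_,
                N2b = NA_real_, N3b = NA_real_, t1 = NA_real_, t2 = NA_real_,
                db = NA_real_, ra = NA_real_)
      full[names(par)] <- par
      k <- k + 1L
      rows[[k]] <- c(scenario = s$id, full, ss)
      if (!is.null(checkpoint_path) && k %% checkpoint_every == 0L) {
        utils::write.csv(as.data.frame(do.call(rbind, rows[seq_len(k)])),
                         checkpoint_path, row.names = FALSE)
      }
    }
  }
  if (dropped > 0L) message("build_reference_table: dropped ", dropped,
                            " non-finite row(s)")
  out <- as.data.frame(do.call(rbind, rows[seq_len(k)]))
  attr(out, "mut_model") <- mut_model
  attr(out, "priors") <- priors
  attr(out, "seed") <- seed
  class(out) <- c("reference_table", class(out))
  out
}

summary_cols <- function(ref) grep("^(nal|het|fst)\\.", names(ref), value = TRUE)

#' ABC rejection step
#'
#' Euclidean distance on summaries normalized by their reference-table
#' median absolute deviation; retains the closest `ceiling(tolerance * rows)`
#' rows, subject to a floor.
#'
#' @param ref a reference table.
#' @param observed named summary vector (same names as the table's summary
#'   columns).
#' @param tolerance fraction of rows to retain, in (0, 1].
#' @param floor_retain minimum retained rows (capped at the table size).
#' @return the retained rows with a `dist` column, ordered by distance;
#'   attribute `"scale"` holds the MAD used.
#' @export
abc_rejection <- function(ref, observed, tolerance = 0.01, floor_retain = 500L) {
  stopifnot(tolerance > 0, tolerance <= 1)
  sc <- summary_cols(ref)
  X <- as.matrix(ref[, sc])
  obs <- observed[sc]
  mads <- apply(X, 2, stats::mad)
  mads[mads == 0 | !is.finite(mads)] <- 1
  Z <- sweep(sweep(X, 2, obs), 2, mads, "/")
  d <- sqrt(rowSums(Z^2))
  if (all(!is.finite(d))) stop("all distances non-finite")
  keep <- min(nrow(ref), max(ceiling(tolerance * nrow(ref)), floor_retain))
  ord <- order(d)[seq_len(keep)]
  out <- ref[ord, , drop = FALSE]
  out$dist <- d[ord]
  attr(out, "scale") <- mads
  out
}

epanechnikov_weights <- function(d) {
  dmax <- max(d) * (1 + 1e-9)
  1 - (d / dmax)^2
}

#' Scenario posterior probabilities by weighted multinomial logistic regression
#'
#' Regresses the scenario indicator of the retained simulations on their
#' MAD-normalized summary deviations from the observed data, weighting by an
#' Epanechnikov kernel in the rejection distance, and reads the fitted class
#' probabilities at deviation zero. Falls back to retained-count proportions
#' (flagged) when the regression is degenerate.
#'
#' @param retained output of [abc_rejection()].
#' @param observed the observed summary vector.
#' @return list with `posterior` (data.frame scenario/prob, summing to 1),
#'   `counts`, `method` (`"logistic"` or `"rejection"`).
#' @export
model_posterior_logistic <- function(retained, observed) {
  sc <- summary_cols(retained)
  scen <- factor(retained$scenario)
  counts <- table(scen)
  if (nlevels(scen) < 2L) {
    warning("single scenario among retained rows; posterior probability 1")
    return(list(posterior = data.frame(scenario = as.integer(levels(scen)),
                                       prob = 1),
                counts = counts, method = "rejection"))
  }
  mads <- attr(retained, "scale")
  Z <- sweep(sweep(as.matrix(retained[, sc]), 2, observed[sc]), 2, mads, "/")
  w <- epanechnikov_weights(retained$dist)
  df <- data.frame(scen = scen, Z)
  fit <- tryCatch(
    nnet::multinom(scen ~ ., data = df, weights = w, trace = FALSE,
                   maxit = 200),
    error = function(e) NULL)
  if (is.null(fit)) {
    prob <- as.numeric(counts) / sum(counts)
    method <- "rejection"
  } else {
    nd <- as.data.frame(matrix(0, 1, ncol(Z)))
    names(nd) <- colnames(Z)
    pr <- stats::predict(fit, newdata = nd, type = "probs")
    prob <- if (is.matrix(pr)) pr[1, ] else pr
    if (nlevels(scen) == 2L) prob <- c(1 - prob, prob)  # binomial shortcut
    method <- "logistic"
  }
  post <- data.frame(scenario = as.integer(levels(scen)),
                     prob = as.numeric(prob) / sum(prob))
  list(posterior = post, counts = counts, method = method)
}

#' Local-linear regression adjustment of parameter posteriors
#'
#' Beaumont-style adjustment: each parameter (log scale for sizes, times and
#' durations; logit scale for the admixture rate) is regressed on the
#' MAD-normalized summary deviations with Epanechnikov weights, and the
#' retained draws are shifted to the fitted value at deviation zero. A
#' rank-deficient regression returns the unadjusted rejection posterior,
#' flagged.
#'
#' @param retained output of [abc_rejection()], ideally restricted to rows
#'   of one scenario.
#' @param observed the observed summary vector.
#' @param parameter_names columns to adjust (default: the parameters the
#'   scenario actually uses, i.e. non-NA columns).
#' @return list of per-parameter results: `draws` (adjusted posterior
#'   sample), `mean`, `median`, `q025`, `q975`, `adjusted` flag.
#' @export
param_posterior_loclinear <- function(retained, observed,
                                      parameter_names = NULL) {
  sc <- summary_cols(retained)
  pcols <- c("N1", "N2", "N3", "N1b", "N2b", "N3b", "t1", "t2", "db", "ra")
  if (is.null(parameter_names))
    parameter_names <- pcols[vapply(pcols, function(p)
      p %in% names(retained) && !anyNA(retained[[p]]), logical(1))]
  mads <- attr(retained, "scale")
  Z <- sweep(sweep(as.matrix(retained[, sc]), 2, observed[sc]), 2, mads, "/")
  w <- epanechnikov_weights(retained$dist)
  out <- list()
  for (p in parameter_names) {
    y_raw <- retained[[p]]
    logit <- identical(p, "ra")
    y <- if (logit) stats::qlogis(pmin(pmax(y_raw, 1e-9), 1 - 1e-9)) else log(y_raw)
    fit <- stats::lm(y ~ Z, weights = w)
    beta <- stats::coef(fit)[-1]
    adjusted <- !anyNA(beta)
    adj <- if (adjusted) y - as.numeric(Z %*% beta) else y
    draws <- if (logit) stats::plogis(adj) else exp(adj)
    out[[p]] <- list(draws = draws, mean = mean(draws),
                     median = stats::median(draws),
                     q025 = stats::quantile(draws, 0.025, names = FALSE),
                     q975 = stats::quantile(draws, 0.975, names = FALSE),
                     adjusted = adjusted)
  }
  out
}

#' Generations elapsed between two calendar years
#'
#' @param year_start,year_end calendar years, `year_end > year_start`.
#' @param generation_time generation length in years (> 0).
#' @return integer `floor((year_end - year_start) / generation_time)` — e.g.
#'   63 generations between 1890 and 2016 at a 2-year generation time.
#' @export
generations_since <- function(year_start, year_end, generation_time = 2) {
  if (year_end <= year_start) stop("year_end must exceed year_start")
  if (generation_time <= 0) stop("generation_time must be positive")
  as.integer(floor((year_end - year_start) / generation_time))
}
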