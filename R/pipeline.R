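#' Pipeline configuration
#'
#' One global seed governs every stochastic stage; the configuration is
#' echoed verbatim into the output directory so a run is self-describing.
#'
#' @param input path to a GenePop file, a `genotype_matrix`, or `NULL` to
#'   generate the default synthetic dataset.
#' @param out_dir output directory (created if absent).
#' @param seed global RNG seed.
#' @param n_perm permutation count for the permutation tests.
#' @param K_range,cluster_runs,sweeps,burn_in clustering controls.
#' @param abc_n_per_scenario reference-table rows per scenario (0 disables
#'   the ABC stage).
#' @param abc_tolerance,abc_floor rejection controls.
#' @param bottleneck_models subset of `c("SMM","TPM")` (empty disables).
#' @param bottleneck_reps retained equilibrium replicates per locus.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, out_dir = "guavapop-out", seed = 1L,
                            n_perm = 999L, K_range = 1:4, cluster_runs = 3L,
                            sweeps = 2000L, burn_in = 500L,
                            abc_n_per_scenario = 0L, abc_tolerance = 0.01,
                            abc_floor = 500L,
                            bottleneck_models = c("SMM", "TPM"),
                            bottleneck_reps = 500L) {
  structure(list(input = input, out_dir = out_dir, seed = seed,
                 n_perm = n_perm, K_range = K_range,
                 cluster_runs = cluster_runs, sweeps = sweeps,
                 burn_in = burn_in, abc_n_per_scenario = abc_n_per_scenario,
                 abc_tolerance = abc_tolerance, abc_floor = abc_floor,
                 bottleneck_models = bottleneck_models,
                 bottleneck_reps = bottleneck_reps),
            class = "pipeline_config")
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes diversity -> null alleles -> population structure -> clustering
#' -> (optional) ABC -> bottleneck tests on one dataset, writing delimited
#' reports into the output directory. Input files are never modified. A
#' stage failure raises an error naming the stage; outputs of completed
#' stages remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return list of produced objects and file paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- list(config = config)
  cfg_echo <- utils::capture.output(utils::str(config))
  writeLines(cfg_echo, file.path(config$out_dir, "config.txt"))

  gm <- stage("input", {
    if (is.null(config$input)) {
      generate_study_like(study_config(seed = config$seed))$gm
    } else if (inherits(config$input, "genotype_matrix")) {
      config$input
    } else read_genepop(config$input, quiet = TRUE)
  })
  out$gm <- gm

  out$diversity <- stage("diversity", diversity_table(gm))
  write_stage(out$diversity, config$out_dir, "diversity_table.csv")

  out$nulls <- stage("null_alleles", null_allele_table(gm))
  write_stage(out$nulls, config$out_dir, "null_alleles.csv")

  out$fst <- stage("structure_stats", pairwise_fst(gm))
  out$fst_corrected <- stage("structure_stats", fst_ena(gm, out$nulls))
  utils::write.csv(out$fst$matrix,
                   file.path(config$out_dir, "fst_matrix.csv"))
  utils::write.csv(out$fst_corrected$matrix,
                   file.path(config$out_dir, "fst_matrix_ena.csv"))
  out$amova <- stage("structure_stats", amova(gm, n_perm = config$n_perm))
  write_stage(out$amova$table, config$out_dir, "amova.csv")
  out$pcoa <- stage("structure_stats", pcoa(dosage_distance(gm)))
  write_stage(data.frame(ind = rownames(out$pcoa$coords), pop = gm$pop,
                         out$pcoa$coords[, 1:min(4, ncol(out$pcoa$coords))]),
              config$out_dir, "pcoa_coords.csv")

  out$clustering <- stage("clustering",
    cluster_k_scan(gm, config$K_range, config$cluster_runs, config$sweeps,
                   config$burn_in, seed = config$seed))
  write_stage(out$clustering$evanno, config$out_dir, "evanno.csv")
  write_stage(data.frame(ind = gm$ind, pop = gm$pop, out$clustering$consensus),
              config$out_dir, "cluster_Q.csv")

  if (config$abc_n_per_scenario > 0L) {
    out$abc <- stage("abc", {
      space <- build_scenario_space()
      ref <- build_reference_table(space, n_per_scenario = config$abc_n_per_scenario,
                                   sample_sizes = as.integer(table(gm$pop)[unique(gm$pop)]),
                                   n_loci = length(gm$loci), seed = config$seed)
      obs <- summarize_dataset(gm)
      ret <- abc_rejection(ref, obs, config$abc_tolerance, config$abc_floor)
      list(reference = ref, posterior = model_posterior_logistic(ret, obs))
    })
    write_stage(out$abc$posterior$posterior, config$out_dir,
                "abc_posterior.csv")
  }

  if (length(config$bottleneck_models)) {
    out$bottleneck <- stage("bottleneck",
      bottleneck_report(gm, config$bottleneck_models,
                        n_reps = config$bottleneck_reps))
    write_stage(out$bottleneck$tests, config$out_dir, "bottleneck_tests.csv")
  }
  invisible(out)
}
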