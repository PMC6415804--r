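Package: guavapop
Title: Microsatellite Population Genetics and Demographic Inference for
    Island Invasions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing the introduction history of invasive
    plant populations from diploid microsatellite (SSR) genotypes.
    Implements GenePop input/output, per-population diversity and
    inbreeding statistics with permutation tests, EM estimation of null
    allele frequencies with ENA-corrected F_ST, Weir-Cockerham F-statistics,
    hierarchical AMOVA, principal coordinate analysis, Mantel tests, a
    Bayesian admixture-model clustering sampler with Evanno Delta-K model
    selection, a backward-time coalescent simulator of SSR data under
    stepwise and two-phase mutation with split, bottleneck and admixture
    events, approximate Bayesian computation for demographic scenario
    choice and parameter posteriors, and heterozygosity-excess bottleneck
    tests. A synthetic-data generator emulating a three-island sampling
    design with selfing, null alleles and missing data makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    nnet,
    geosphere,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
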