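# guavapop

Population-genetic reconstruction of island invasion histories from
microsatellite (SSR) genotypes.

Invasive plants typically reach an archipelago as a handful of founders,
then spread island to island. Their diploid SSR genotypes record that
history as reduced diversity, inbreeding, island differentiation and
transient heterozygosity excess. `guavapop` implements, in one tested R
package, the full inference chain a molecular-ecology study of this design
runs — exemplified by guava (*Psidium guajava*) sampled on Isabela, Santa
Cruz and San Cristóbal (95/80/94 individuals, 11 polymorphic loci):

* **Genotype handling** — GenePop (2/3-digit) and delimited-table IO,
  allele-frequency tables, missing-data rules.
* **Diversity** — allele counts, private alleles, rarefied allelic richness
  (`AR = Σᵢ [1 − C(n−nᵢ, g)/C(n, g)]`), observed heterozygosity, Nei's
  unbiased gene diversity `Hₑ = n/(n−1)·(1 − Σpᵢ²)`, multilocus
  `F_IS = 1 − H̄ₒ/H̄ₑ`, individual inbreeding by likelihood, Monte-Carlo
  Hardy–Weinberg and gene-diversity tests, permutation LD test, Bonferroni.
* **Null alleles** — EM estimation of per-locus null frequencies (both
  blank conventions) and ENA-corrected pairwise F_ST.
* **Structure** — Weir–Cockerham θ (`Σa / Σ(a+b+c)`), Nei (1972) distance,
  3- and 4-level AMOVA with permutation p-values, PCoA on allele-dosage
  distances, Mantel tests, haversine geography.
* **Clustering** — a Gibbs sampler for the Bayesian admixture model
  (z ∝ q·p, Dirichlet updates for P and Q, Metropolis α), Evanno
  ΔK = |L″(K)|/sd(L(K)), and alignment of replicate runs.
* **Demographic inference** — a backward-time coalescent simulator of SSR
  data (stepwise / two-phase mutation; splits, founder bottlenecks,
  admixture) over the canonical 14-scenario space of three-island
  colonizations; ABC with MAD-normalized rejection, logistic-regression
  scenario choice and local-linear parameter posteriors; and
  heterozygosity-excess bottleneck tests (equilibrium gene diversity
  conditioned on allele count, Wilcoxon signed-rank inference).
* **Synthetic data** — a generator that emulates the three-island study
  with known ground truth (demography, selfing, null alleles, missing
  data), so every stage is testable without any download.

## Worked example

```r
library(guavapop)

out <- generate_study_like(study_config(seed = 11))   # 269 x 11 SSR dataset
diversity_table(out$gm)[, c("N","A","PA","AR","H_O","H_E","F_IS")]
#>    N  A PA    AR   H_O   H_E  F_IS
#> 1  95 18  0 1.636 0.069 0.243 0.717     # Isabela
#> 2  80 19  0 1.724 0.151 0.258 0.416     # Santa Cruz
#> 3  94 25  6 2.272 0.148 0.368 0.597     # San Cristobal
#> 4 269 25 NA 2.236 0.121 0.352 0.657     # overall

round(pairwise_fst(out$gm)$matrix, 3)
#>              Isabela SantaCruz SanCristobal
#> Isabela        0.000     0.281        0.306
#> SantaCruz      0.281     0.000        0.111
#> SanCristobal   0.306     0.111        0.000

amova(out$gm, n_perm = 199)
#>                  level   df      SSD    sigma2  percent     p
#>             among_pops   22 172.3827 0.5157146 24.40563 0.005
#>  among_ind_within_pops 2696 631.0918 0.9327463 44.14120 0.005
#>             within_ind 2729 169.0000 0.6646358 31.45317 0.005
```

Reading the output: the generator planted a serial introduction (ancestral
San Cristóbal → Isabela → Santa Cruz) with founder bottlenecks and strong
partial selfing. Accordingly the ancestral island keeps the most alleles
and private alleles, every island shows a large heterozygote deficit
(F_IS 0.4–0.7, from selfing plus null alleles), the most-distant pair
(Isabela–San Cristóbal) is the most differentiated, and roughly a quarter of
the molecular variance lies between islands — the same qualitative anatomy
such field studies report.

Downstream stages follow the same pattern, e.g.

```r
scan <- cluster_k_scan(out$gm, K_range = 1:5, n_runs = 3)   # Evanno Delta-K
space <- build_scenario_space()                             # 14 scenarios
ref   <- build_reference_table(space, n_per_scenario = 357, seed = 1)
post  <- model_posterior_logistic(
           abc_rejection(ref, summarize_dataset(out$gm)),
           summarize_dataset(out$gm))
btl   <- bottleneck_report(out$gm, models = c("SMM", "TPM"))
```

or run everything at once with `run_pipeline(pipeline_config(...))`
(`inst/scripts/run-pipeline.R` is a shell wrapper).

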