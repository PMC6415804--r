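---
title: "Reconstructing an island invasion from microsatellites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing an island invasion from microsatellites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guavapop)
```

guavapop implements the complete inference chain used to reconstruct the
introduction history of an invasive plant across a three-island archipelago
from diploid microsatellite (SSR) genotypes: descriptive diversity and
inbreeding statistics, null-allele correction, population structure (F-
statistics, AMOVA, PCoA, Mantel tests, admixture-model clustering), and
demographic inference (coalescent simulation of colonization scenarios,
approximate Bayesian computation, and heterozygosity-excess bottleneck
tests). This vignette explains each model, its assumptions, the tunable
parameters, and the design choices behind the defaults.

## The data model

A `genotype_matrix` holds unordered diploid allele pairs (positive integer
labels: fragment sizes or repeat counts) for individuals × loci, with one
population label per individual, optional region labels, and coordinates.
Missing genotypes carry `NA` in both slots; half-called genotypes are
promoted to fully missing with a warning, because every estimator in the
package assumes 0 or 2 gene copies per individual and locus. GenePop 2- and
3-digit dialects and a delimited table format round-trip exactly; the
all-zero allele code is the missing sentinel.

Allele labels are opaque everywhere except in the mutation models, which
read them as repeat counts. This keeps the statistics label-agnostic: any
relabelling of alleles leaves every diversity statistic unchanged.

## Diversity and inbreeding statistics

Gene diversity uses Nei's unbiased estimator $\hat H_E = \frac{n}{n-1}(1 -
\sum_i p_i^2)$ with $n$ the gene-copy count ( `unbiased = FALSE` switches to
the plug-in form). Allelic richness is hypergeometric rarefaction to a
standardized number of gene copies $g$:
$AR = \sum_i \left[1 - \binom{n - n_i}{g} / \binom{n}{g}\right]$,
defaulting to the largest $g$ valid in every (locus, population) cell.
Allele and private-allele counts are totals across loci (with a "frequent"
variant at within-population frequency > 0.05); $AR$, $H_O$ and $H_E$ are
across-locus means. $F_{IS}$ is the ratio of across-locus means
$1 - \bar H_O / \bar H_E$ — not the mean of per-locus ratios — matching the
convention of the classical basic-statistics toolchain.

Hypothesis tests are Monte-Carlo throughout, with the permutation p-value
convention $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$ so
p = 0 cannot occur:

* **Hardy–Weinberg**: the exact-test statistic is the Levene conditional
  probability of the genotype table given allele counts; the null is random
  re-pairing of the observed gene copies. SSR tables are too sparse for the
  asymptotic chi-square.
* **Linkage disequilibrium**: a G-statistic on the two-locus genotype table
  with genotypes permuted at the second locus. Standard toolchains do not
  document their exact LD variant, so reports flag this as a permutation
  G-test.
* **Gene-diversity difference**: $|\bar H_E^{(A)} - \bar H_E^{(B)}|$ with
  individuals reassigned between the populations.
* **Bonferroni**: reject at $p < \alpha/m$; the package reproduces the
  classic three-island paired-comparison arithmetic (p = 0.037 not
  significant at m = 3, p = 0.001 significant).

The per-individual inbreeding coefficient maximizes the genotype likelihood
(homozygote $F p_i + (1-F) p_i^2$, heterozygote $(1-F) 2 p_i p_j$) over a
grid $F \in \{0, 0.01, \dots, 1\}$; the tests check the grid optimum against
a continuous optimizer.

## Null alleles

`em_null_frequency()` fits, by EM, the model in which a null allele of
frequency $r$ segregates under Hardy–Weinberg with the visible alleles: a
visible homozygote class pools true homozygotes and visible/null
heterozygotes; null/null individuals do not amplify. Two blank conventions
exist in the literature and both are implemented: blanks counted as known
null homozygotes, or (the default) blanks marginalized out because failed
PCR is indistinguishable from a null/null genotype. The E-step splits
homozygote classes by $p_i/(p_i + 2r)$ and (in the marginalizing variant)
imputes $n r^2/(1-r^2)$ unobserved blanks; the M-step is gene counting. The
observed-data log-likelihood is non-decreasing across iterations (asserted
in tests), and the estimator agrees with a direct BFGS maximization of the
same likelihood. At $r = 0.2$, $n = 100$, five visible alleles, the
estimator is unbiased with sampling sd ≈ 0.031 (blank count supplied) or
≈ 0.045 (marginalized) — an information limit worth keeping in mind when
reading per-locus estimates.

F_ST corrected for null alleles (`fst_ena()`) recomputes the Weir–Cockerham
components after appending the null as an extra allele at its estimated
frequency per population, then excludes the null class from the numerator
and denominator sums (the ENA approach, chosen because it is the headline
correction of the tool this emulates). With every $\hat r = 0$ the corrected
and uncorrected matrices agree exactly; loci with $\hat r \ge 0.9$ are
dropped with a warning.

## Population structure

Pairwise F_ST is Weir–Cockerham $\theta$: per-locus, per-allele variance
components $a$ (among populations), $b$ (among individuals within), $c$
(within individuals), combined as $\sum a / \sum(a+b+c)$ across alleles and
loci. Small negative estimates are preserved and flagged, never truncated.

AMOVA partitions gene-copy variance with the identity/non-identity distance
(the F_ST analogue; the squared-size R_ST variant is out of scope for the
default reports). Sums of squares come from squared inter-copy distances,
components from equating observed and expected mean squares, computed per
locus (each locus with its own sample-size coefficients, so missing data are
handled exactly) and summed. Three-level (population / individual / copy)
and four-level (island / region / individual / copy) nestings are supported.
Negative components are reported as-is; percentages are computed on raw
components and sum to 100. Permutation p-values use the level-appropriate
scheme: individuals among populations for the among-group components, gene
copies among individuals within populations for the within-individual
levels.

PCoA double-centers $-\tfrac12 D^2$ and eigen-decomposes, reporting negative
eigenvalues rather than hiding them; the individual-level distance is
Euclidean on allele-dosage vectors (0/1/2 per allele) with missing dosages
imputed to the locus mean — the least-committal reading of "Euclidean
distances between individuals", recorded in output metadata. The Mantel test
correlates lower triangles under simultaneous row/column permutation
(one-sided, positive association); geographic distances are haversine
kilometres on a 6371-km sphere, with region centroids as the default spatial
unit because the emulated study correlates distances "between sampled
regions".

## Admixture clustering and Delta-K

`run_admixture_mcmc()` is a Gibbs sampler for the classic admixture model:
allele-copy assignments $z \propto q_{ik} p_{kla}$; cluster frequencies
$P \sim \text{Dirichlet}(\lambda + \text{counts})$ with $\lambda = 1$
(uncorrelated-frequencies model; the correlated variant is out of scope);
admixture proportions $Q \sim \text{Dirichlet}(\alpha + \text{counts})$;
$\alpha$ updated by a Metropolis random walk under a uniform prior on
(0, 10]. Missing copies are skipped. The run returns posterior means and the
per-sweep data log-likelihood; `lnP` is its post-burn-in mean. Full-scale
analyses conventionally use $10^6$ sweeps with $10^5$ burn-in; the package's
tests and calibration experiments use 5000/1000, which suffices on the
synthetic data sizes used here (n = 200, 11 loci) — chain stationarity is
checked by a Geweke-style split test.

The Evanno table computes $\Delta K = |L''(K)| / \mathrm{sd}(L(K))$ across
runs; endpoints are undefined and sd = 0 yields a flagged infinity. Replicate
runs are aligned by column permutation maximizing
$\sum_{ik} Q^{(1)}_{ik} Q^{(r)}_{i\pi(k)}$ — exhaustive (exact) for
$K \le 6$, greedy beyond — and averaged into a consensus, the in-package
analogue of the usual run-summarization step.

## The coalescent simulator

`simulate_dataset()` runs an independent backward-time structured coalescent
per locus. Within a population of diploid size $N$, $k$ lineages coalesce at
rate $\binom{k}{2}/(2N)$; sizes are piecewise constant. A founder
bottleneck occupies $[t, t + d_b]$ looking backward (size $N_b$), after
which the target's lineages move into the source population — for admixture
events each lineage picks source A with probability $r_a$, else source B.
Mutations are Poisson on branch lengths and change the repeat count by
$\pm 1$ (SMM) or, under the two-phase model, by a geometric number of steps
(single-step probability 0.9, mean jump 2.8 by default — the emulated
study names its models but not their settings, so these conventional
defaults are always echoed in reports). The allele state space is unbounded,
anchored at repeat count 100; continuous time is used rather than
generation-by-generation Wright–Fisher for speed. The simulator is checked
against the stepwise-model equilibrium gene diversity
$1 - 1/\sqrt{1 + 2\theta}$ and against qualitative expectations (monotone
F_ST in divergence time, allele loss under founder events).

The 14-scenario space covers every serial/parallel two-introduction history
of three islands (3 ancestral choices × 2 orderings × 2 sources for the
second introduction) plus two admixture scenarios in which the middle island
is founded jointly by the outer two. One shared $d_b$ per parameter draw
keeps move times ordered ($t_1 + d_b \le t_2 + d_b$); a per-event $d_b$ is
deliberately not implemented. Priors default to U(10, 10000) for sizes,
times and durations and U(0.001, 0.999) for the admixture rate, with
$t_2 \ge t_1$ enforced by resampling; per-locus mutation rates draw from
U(1e-4, 1e-3) since SSR assays rarely justify a single shared rate.

## Approximate Bayesian computation

The summary vector is fixed at nine numbers: per population the mean allele
count and mean gene diversity across loci, plus the three pairwise F_ST
values. Reference tables stream simulate → summarize, are reproducible from
one seed, and drop non-finite rows with a log entry. Rejection retains the
closest `ceiling(tolerance * rows)` simulations (default tolerance 0.01 with
a floor of 500) under Euclidean distance on MAD-normalized summaries —
median absolute deviation rather than sd for robustness to the long-tailed
prior predictive. Scenario posteriors come from multinomial logistic
regression of the scenario label on the normalized summary deviations,
Epanechnikov-weighted in distance, read at deviation zero; a degenerate fit
falls back to retained-count proportions, flagged. Parameter posteriors use
the standard local-linear adjustment on log scale (logit for the admixture
rate), falling back to the unadjusted rejection sample when rank-deficient.

An honest caveat established by the package's own experiments: under the
broad default priors the 14 scenarios overlap heavily in the 9-statistic
summary space — a nonparametric classifier trained on a 5000-row reference
table barely beats chance. Scenario choice at this scale separates clearly
distinct hypotheses (e.g. strong founder bottlenecks versus none, which the
test suite shows is recovered in ≥70% of pseudo-datasets) but cannot
reliably single out one serial topology among fourteen; posterior
probabilities should be read comparatively, not as confident
identifications. This mirrors the flat posteriors typical of real analyses
of this design.

## Bottleneck tests

`heq_distribution()` simulates the equilibrium gene-diversity distribution
conditional on the observed allele count $k$: $\theta$ is tuned by bisection
until the mean simulated allele count matches $k$, then replicates with
exactly $k$ alleles are retained (erroring below 0.1% acceptance).
`bottleneck_report()` feeds the per-locus differences
$H_{E,\text{obs}} - \bar H_{eq}$ into one-tailed Wilcoxon signed-rank tests
(deficiency = expansion signal, excess = reduction signal) and a two-tailed
test, per population and mutation model — six p-values per population.
Inference delegates to the exact signed-rank null for ≤ 25 non-zero
differences and the continuity-corrected normal approximation beyond; zeros
are dropped.

Calibration, measured honestly by the acceptance experiments: with 95
diploids and 11 loci at equilibrium the excess tail rejects at ≈ 8–12%
rather than 5%, and the deficiency tail at ≈ 1–2%. The cause is structural:
the signed-rank test assumes symmetric null differences, but gene diversity
conditional on allele count is left-skewed. This behaviour is a property of
the heterozygosity-excess method itself, not of this implementation —
standardizing the differences does not repair it — so the package reports
it rather than re-tuning the test. Power for a recent 99% collapse
(1000 → 10, ten generations back) is ≈ 65–75% at this design.

## The synthetic-data generator

`generate_study_like()` emulates the three-island study design: 95/80/94
diploids at 11 loci under the serial-introduction scenario with the
outermost island ancestral, $t_2 = 120$ and $t_1 = 35$ generations (the
plausible window for an introduction dating to the late 1800s at a two-year
generation time), founder sizes of a few tens of plants, partial selfing,
null alleles and missing data. The demographic defaults — present sizes
(75, 800, 1000), founder sizes (20, 50, 50), $d_b = 5$ — were fixed once so
that the most-distant island pair carries the largest F_ST in the large
majority of seeds and the diversity/inbreeding magnitudes land in the bands
a field study of this design reports (H_E ≈ 0.15–0.35, F_IS ≈ 0.3–0.6,
island F_ST ≈ 0.07–0.21); they are configuration values, not hard-coded
logic.

Selfing is applied as post-processing mating generations — each offspring
is selfed with probability $s$, otherwise outcrossed within its island — so
mating-system and demographic ground truths stay independent; this drives
$F_{IS}$ to the mixed-mating equilibrium $s/(2-s)$, which the tests verify.
Null alleles silence whole allele lineages (total frequency ≈ the target
rate): one silenced copy makes an apparent homozygote, two make a blank —
exactly the process the EM models, so planted rates are recoverable.
Missing data are injected independently per genotype.

What the generator does *not* emulate: within-island spatial structure,
clonal reproduction, genotyping artefacts other than nulls (stutter,
large-allele dropout), and migration after founding. Tests passing on this
synthetic data therefore validate the estimators and the inference
machinery, not the field realism of any particular dataset.

## Problem sizes and determinism

All simulation experiments in the test suite and the acceptance script use
fixed seeds and deliberately moderate sizes — 500-locus equilibrium checks,
200-replicate calibrations, a 5000-row reference table (the same design at
7 million rows is a matter of patience, not code), clustering at 5000
sweeps × 3 runs × K ∈ 1..5 — chosen as the smallest scales at which the
properties under test are statistically resolvable. One seed governs every
stochastic stage, including the C++ samplers, which draw from R's RNG; a
pipeline re-run with the same seed is byte-identical.

## Known limitations

* The admixture sampler implements the uncorrelated-frequencies model only;
  island-of-origin priors enter only through run summaries, not a LOCPRIOR
  term, because the emulated analysis is reproducible without it.
* The LD test is a permutation G-test stand-in for an undocumented
  likelihood-ratio variant.
* Scenario identifiability under the default broad priors is intrinsically
  poor (see the ABC section); the bottleneck excess tail is anti-
  conservative by construction of the method.
* The coalescent has no post-founding migration and no allele-size
  constraints; both are out of scope for the scenario space modelled here.
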