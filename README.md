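# msatABC

Population-genetic analysis and coalescent ABC demographic inference for
diploid microsatellite data, built around the kind of study design used for
the seagrass *Cymodocea nodosa* in the Aegean Sea: shoots sampled from many
meadows, genotyped at a panel of microsatellite loci, screened for clonal
replicates, summarized by F-statistics and ordination, and finally compared
against explicit divergence scenarios by approximate Bayesian computation.

The package is aimed at population geneticists who want this whole chain —
from a genepop file to scenario posterior probabilities — as ordinary,
scriptable, seed-reproducible R functions.

## What it computes

**Clonality.** Samples with identical multilocus genotypes (MLGs) are
grouped; MLGs within a small allele-difference threshold are collapsed into
multilocus lineages (MLLs) by single linkage, absorbing somatic mutations
and scoring slips. One representative per MLL gives the genet-level data
set used for demographic inference.

**Diversity and structure.** Per population: observed heterozygosity,
unbiased gene diversity *H* = (2n/(2n−1))(1 − Σ p̂²), rarefied allelic
richness Σₐ [1 − C(N−Nₐ, g)/C(N, g)], and the Weir–Cockerham within-
population estimator *f* (F_IS). Between populations: the Weir–Cockerham
θ (F_ST) from variance components a, b, c, multilocus values always as
ratios of summed components. Significance comes from permutation tests
(alleles within populations for *f*; genotypes between populations for θ)
with the +1/(B+1) p-value estimator, flagged at Bonferroni-adjusted nominal
levels (α/number of tests). A factorial correspondence analysis of 0/1/2
allele counts (GENETIX-style) with population centroids summarizes
structure and guides the pooling of samples into regional demes.

**Demographic inference.** Divergence scenarios — population trees with
per-branch effective sizes, merge events and size changes at parameterized
times (in generations), and priors with order constraints — are written in
a small YAML grammar. A continuous-time coalescent simulator with a
generalized stepwise mutation model (mutation count per branch Poisson,
step sizes geometric, reflecting allele ladder) generates a reference table
of summary statistics (allele counts, gene diversity, pairwise θ) under
each scenario. ABC then proceeds classically: MAD-standardized Euclidean
rejection; scenario choice by the retained-set composition (direct) and by
ridge-penalized multinomial logistic regression evaluated at the observed
point; per-parameter posteriors by Beaumont-style local-linear adjustment
on logit-transformed parameters, reported as mode, median and 95% interval;
and posterior predictive checks. The shipped `scenario13()` encodes the
best-supported history for the four Aegean demes — a Pleistocene
trifurcation of the northern, north-eastern and north-western lineages
followed by a Holocene split of the central-western deme — and
`generations_to_years()` converts split times with the 3-year generation
interval of *C. nodosa*.

**Synthetic data with known truth.** `make_study_like()` simulates a
study-shaped data set (12 meadow labels nested in 4 demes at the design's
sample sizes, 18 loci) and injects known artifacts — clone pairs and null
alleles — with a machine-readable truth ledger, so every pipeline stage can
be validated end to end.

## Worked example

```r
library(msatABC)

# a study-shaped synthetic data set with 3 clone pairs and null alleles
b  <- make_study_like(seed = 1, scale = 0.25, clone_pairs = 3,
                      null_freq = 0.15)
gm <- b$corrupted

part <- collapse_mll(identify_mlg(gm), gm, threshold = 2)
part
#> mll_partition: 83 samples, 81 MLGs, 80 MLLs (threshold 2)

pooled <- pool_populations(gm, deme_pooling_map(), drop = "CYP")
round(summary_stats(pooled), 3)
#>     nal_N    nal_NE    nal_NW    nal_CW     het_N    het_NE    het_NW
#>     7.167     6.000     6.500     5.722     0.789     0.760     0.752
#>    het_CW  fst_N_NE  fst_N_NW  fst_CW_N fst_NE_NW fst_CW_NE fst_CW_NW
#>     0.662     0.089     0.082     0.144     0.087     0.146     0.118
```

The three injected ramet pairs collapse into exactly three lineages
(83 samples → 80 MLLs; two pairs were exact copies, one differed by a
single scoring slip), and pairwise θ between the regional demes spans
~0.08–0.15 — inside the study-like band — with the bottlenecked
central-western deme the most differentiated and the lowest diversity.
Null alleles show up as positive F_IS
(`multilocus_fis(pooled, "CW")` ≈ 0.29, permutation p < 0.01). Scenario choice against a topology-permuted
alternative then favours the generating history:

```r
scns <- list(scenario13 = scenario13(), alternative = scenario_alternative())
sizes <- table(pooled$pop)
ref <- build_reference_table(scns, sizes, n_per_scenario = 3000,
                             n_loci = 18, seed = 101)
ret <- abc_rejection(ref, summary_stats(pooled), 0.05)
model_posterior_direct(ret)
model_posterior_logistic(ret)
parameter_posterior(ret, "scenario13")   # mode/median/95% CI per parameter
```

`run_pipeline()` performs all stages (clonality report, diversity table,
θ matrix with significance mask, FCA coordinates, pooling, ABC) and writes
TSV/JSON outputs plus a manifest under one output directory, fully
determined by a single master seed.

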