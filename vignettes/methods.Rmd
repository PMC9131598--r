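---
title: "Models and methods: microsatellite population genetics and coalescent ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: microsatellite population genetics and coalescent ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery in `msatABC`: the
estimators, the coalescent simulator, the ABC procedure, the synthetic-data
generator, and the numerical and design choices behind them. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute themselves.

## Data model

A `genotypes` object holds `n` diploid samples typed at `L` microsatellite
loci. Each call is an unordered pair of positive integers — allele sizes or
repeat numbers on an additive scale, never binned, because stepwise-mutation
statistics (and the simulator) need arithmetic on repeat counts. Missing
data are handled everywhere by pairwise per-locus deletion: a genotype
missing at a locus contributes nothing to that locus in any estimator
(the behaviour of the classic Arlequin-style tools this mirrors).

Genepop is the interchange format (2- or 3-digit encodings read, 3-digit
written; `00`/`000` is missing), plus a long-format TSV for debuggability.

## Clonal lineages

Ramets of one genet should be genotypically identical, but somatic mutation
and scoring error blur this. We first group exact multilocus genotypes
(MLGs), then join MLGs whose allele distance — the number of unshared
allele copies summed over commonly-typed loci (`Aa` vs `AA` counts 1,
`AA` vs `BB` counts 2) — is at most a threshold, by single linkage
(connected components), giving multilocus lineages (MLLs). Single linkage
makes the result order-invariant and monotone in the threshold.

The default threshold is 2: up to one stepwise slip at each of two loci.
The MLG→MLL counts are the quantity of interest here; probability-of-sex
(p_sex) statistics are deliberately out of scope. Downstream analyses run
on the full sample set by default; the ABC stage reduces to one
representative per MLL (the lowest-sorted sample id, for determinism), the
genet-level data set demographic inference should see.

## Estimators

* Observed heterozygosity: heterozygote fraction among non-missing calls.
* Unbiased gene diversity: \( \hat H = \frac{2n}{2n-1}\bigl(1-\sum_a
  \hat p_a^2\bigr) \) — the small-sample-corrected probability that two
  gene copies differ.
* Rarefied allelic richness at `g` gene copies:
  \( \sum_a \bigl[1 - \binom{N_c-N_a}{g}\big/\binom{N_c}{g}\bigr] \); the
  default `g` is the smallest per-population non-missing copy count at
  each locus — no other size is canonical, and this one always exists.
* Weir–Cockerham variance components `a` (among populations), `b` (among
  individuals within), `c` (within individuals), computed per allele with
  the standard unequal-sample-size weights and summed over alleles.
  Multilocus θ = Σa / Σ(a+b+c) and f = 1 − Σc / Σ(b+c) are *ratios of
  sums* over informative loci, never means of per-locus ratios; loci
  monomorphic across the included populations are uninformative and
  excluded. Negative estimates are reported as computed, not truncated:
  the estimators are unbiased around zero, and a small negative value is
  informative (slight heterozygote excess).

Significance uses permutation schemes matched to the null being tested:
for f, gene copies are shuffled among individuals within the population,
per locus; for θ, whole genotypes are shuffled between the two
populations. p = (#{perm ≥ obs} + 1)/(B + 1), one-sided (heterozygote
deficit / excess structure), which can never report zero; B defaults to
10,000. Multiple comparisons use the Bonferroni-adjusted *nominal level*
α′ = α/n_tests — the convention of reporting which entries stay
significant at α′ rather than inflating p-values. The number of tests is
always passed explicitly; the 66 population pairs of a 12-population study
give α′ ≈ 0.000758.

## Ordination

The factorial correspondence analysis codes individuals as 0/1/2 counts of
each observed allele, then performs textbook CA: relative frequencies, row
and column masses, Pearson-residual matrix, SVD, principal coordinates for
individuals, axes sorted by eigenvalue. Three axes are retained by default.
Axis signs are arbitrary in CA, so each axis is canonicalized by making its
largest-magnitude column loading positive — plots become reproducible
across row orders. Individuals missing a locus keep zero mass on its
columns rather than being dropped, so all modules see identical sample
sets. Population centroids are mass-weighted means of member coordinates;
in practice the centroid clustering is what motivates pooling samples into
regional demes before ABC.

## Scenario grammar

A divergence scenario is: sampled demes, an effective-size parameter per
deme, events backward in time — `merge(t, from → to)` and
`size_change(t, deme, size)` — and a prior per parameter with order
constraints among times. Validation checks that every referenced parameter
has a prior, every deme exists, and that exactly one ancestral deme
survives all merges. Events are ordered by drawn time, with size changes
applied before merges at ties and a deme-name tie-break, so file order is
irrelevant.

Priors default to log-uniform over their stated ranges: when a broad
positive parameter is known only through its range, the log-uniform is the
reproducible choice, and a truncated-log-normal shape is available when a
location and scale are actually known. Draws violating order constraints
are rejected and redrawn, so marginals are the constrained versions of the
stated shapes.

The shipped `scenario13` encodes the best-supported history for four
Aegean demes (N, NE, NW, CW): backward in time, CW switches to the small
ancestral size at `t0` (a founding bottleneck after its Holocene split —
`t0` belongs to the scenario's parameter set but its demographic role is
ambiguous; we implement it as this size change on CW and flag the
interpretation unresolved rather than silently dropping the parameter),
CW merges into NW
at `t2`, and at `t3` NW and NE merge into N, which takes the ancestral
size — an effective trifurcation, the simplest topology consistent with a
single drawn Pleistocene divergence of three lineages. Whether that
three-way split is simultaneous or two close bifurcations is not stated;
we model it as simultaneous. `scenario_alternative()` permutes the
topology (NE becomes the recently-founded deme, CW the ancestral line) and
is the comparison scenario used for model-choice testing.

## Coalescent simulator

Within each deme, lineage pairs coalesce at rate k(k−1)/(4Nₑ) per
generation (diploid Nₑ), in continuous time — the standard approximation,
fast and matching the generation-scaled priors; no generation-by-generation
simulation. Merges move all lineages of a deme; size changes switch the
rate. The mutation model is the generalized stepwise model: per branch the
mutation count is Poisson(μ × length); each mutation moves the repeat
number ±k with k geometric(P) (P = 0 is the strict stepwise model),
directions symmetric, reflected at the ladder bounds. The ladder defaults
to 200 contiguous states (ancestral state at the midpoint) so emitted
alleles always fit the 3-digit genepop encoding; an unbounded ladder is
available for theory checks. Per-locus rates are drawn from a Gamma with
shape 2 around a mean rate whose prior is log-uniform on [1e-4, 1e-3] —
DIYABC-style locus heterogeneity; both the shape and the rate prior are
config-exposed rather than hard-wired. Gene copies are paired into diploids within demes at
random (genets are treated as outbred; no selfing parameter).

One numerical shortcut: with Nₑ priors reaching 10⁷, deep branches can
carry ~10⁵ mutations. When a branch's mutation count exceeds 50 × (ladder
width)² — far beyond the reflected walk's relaxation time of about
0.2 × width²/E[k²] — the end state is drawn from the walk's stationary
law, which is exactly uniform on the ladder (the reflected symmetric
kernel is doubly stochastic). Below the threshold every mutation is
stepped explicitly.

Moment checks anchor the engine: mean pairwise TMRCA = 2Nₑ generations;
under strict stepwise mutation the mean squared difference in mean repeat
number between two demes split τ generations ago is ≈ 2μτ; equilibrium
gene diversity in one deme matches 1 − 1/√(1 + 8Nₑμ).

## ABC

The summary panel is, per deme, the mean number of alleles per locus and
mean unbiased gene diversity, plus multilocus θ for every deme pair —
2K + K(K−1)/2 statistics for K demes, in a fixed, name-addressed order.
θ entries undefined for lack of polymorphism are set to 0 and masked out
of distances, keeping the vector length fixed. The default panel is
exactly allele number, gene diversity and F_ST; allele-size moments are
not included by default.

Reference tables simulate each scenario at prior draws; each row has its
own seed derived from the table seed, so batches are resumable and
bit-identical to a one-shot build. Rejection standardizes each statistic
by its median absolute deviation across the table and keeps the closest
fraction (default 0.01) by Euclidean distance. Scenario support:

* *direct* — scenario frequencies among the n_δ closest rows (default
  500, capped at the retained count);
* *logistic* — multinomial logistic regression of scenario id on the
  standardized deviations from the observed vector, Epanechnikov-weighted
  by distance, evaluated at zero deviation. The fit is ridge-penalized
  with weight decay 0.5. A tiny penalty (10⁻⁶-scale) turned out to be the
  wrong choice here: with a few hundred retained rows and ~14 covariates
  the unpenalized intercept is so variable that replicate pseudo-observed
  data sets swing the reported probability across most of [0, 1], while a
  moderate ridge gives stable estimates that agree with the direct
  estimate (the behaviour one wants from two views of the same retained
  set). The penalty only shrinks the local log-odds surface toward
  flatness, i.e. toward the direct estimate, so it trades a small bias for
  a large variance reduction. It is a config argument (`decay`).

Parameter posteriors use the local-linear (Beaumont) adjustment: each
parameter is mapped to the real line by a logit over its prior bounds (on
the log scale for log-uniform priors, so the adjustment cannot leave the
prior support), regressed on the standardized deviations with Epanechnikov
weights, adjusted to zero deviation, and back-transformed. Reported are
the weighted-kernel-density mode (bandwidth chosen on the unweighted
sample, since the usual selectors ignore weights), and weighted median and
2.5%/97.5% quantiles. A rank-deficient regression falls back to
unadjusted weighted quantiles with a flag. Posterior predictive checks
resimulate data at posterior draws (resampled by weight, order
constraints re-enforced by resampling) and report per statistic the
two-sided tail probability min(p, 1−p)×2, capped at 1.

Full-scale analyses of this kind run tens of millions of simulations on
clusters; desk-scale defaults here target minutes. The validation sizes,
chosen once
as this package's study conditions: scenario choice uses a 2 × 10,000-row
table at the 18-locus panel with 15 diploids per deme against
mid-prior pseudo-observed data; parameter recovery uses a 6,000-row
single-scenario table, coverage measured over 50 prior-drawn replicates
and rank-tracking over a 12-point log grid on (t2, t3) spanning their
priors with other parameters at mid-prior (a grid isolates the split-time
signal from Nₑ variation, which is what a rank-correlation check is
meant to probe).

## Synthetic data with known truth

`make_study_like()` simulates `scenario13` at fixed truth parameters
(all sampled-deme Nₑ 5000, ancestral 1000, t0 = 100, t2 = 600, t3 = 3000,
mean μ 5 × 10⁻⁴) — chosen once so that pairwise θ between demes falls in
the 0.02–0.30 band typical of moderately structured seagrass meadows — then dresses the four demes with the twelve
meadow labels of `meadow_design()` at their design sample sizes (scaled
by `scale`; 331 samples at scale 1). Meadows within a deme are drawn from the same
simulated gene pool: within-deme heterogeneity is deliberately absent so
the truth stays unambiguous. The small south-eastern (Cyprus-like) sample
is drawn from the NE deme's pool — its genetically closest cluster in this
design — and is drop-listed from the ABC stage, the treatment a sample
that small should get. Tests that need posterior intervals run at
scale 0.25 to keep runtimes low.

Artifacts are then injected with a full ledger: null alleles (each gene
copy silently fails with a per-locus frequency; null homozygotes become
missing, null heterozygotes apparent homozygotes — producing the classic
F_IS excess and a missing rate ≈ freq²) and clone pairs (a same-population
partner overwritten by a near-copy with at most `max_distance` stepwise
edits, never on missing calls). Nulls are injected before clones so ramet
pairs differ by exactly the controlled edits. What passing these tests
does *not* show: real meadows have spatial clonal architecture,
within-deme substructure, linkage, and allele-size homoplasy patterns the
generator does not emulate; the truth round-trip validates the machinery,
not the biology.

## Degenerate inputs and edge behaviour

Monomorphic loci are uninformative for θ/f and excluded from ratio-of-sums;
a data set with no informative locus raises an error rather than returning
NaN. Zero-inertia (constant) tables refuse CA. Populations with a single
typed genotype are excluded from that locus's components (n̄ > 1 is
required). Permutation p-values are bounded below by 1/(B+1). The
all-retained-from-one-scenario case returns the degenerate direct estimate
with a warning instead of a logistic fit. Adjusted posterior draws that
violate order constraints are resampled during posterior prediction.

## Known limitations

No migration after splits (the scenario space is pure divergence), no
admixture, no recombination or selection; exact Hardy–Weinberg tests,
linkage disequilibrium, null-allele frequency estimation and hierarchical
AMOVA are out of scope, as are model-based clustering and migration-rate
estimation, which are the territory of dedicated external tools. The
scenario grammar can express any divergence topology, but only
`scenario13` ships as a vetted config; alternative scenarios for
comparison are built programmatically by topology permutation
(`scenario_alternative()`), and users can write their own YAML configs
for larger scenario sets.
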