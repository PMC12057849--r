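---
title: "Methods: null models, networks and drivers for gradient microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: null models, networks and drivers for gradient microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micasm)
```

`micasm` implements the community-ecology inference stack used to study
soil bacterial communities sampled along a disturbance gradient: several
distance classes with replicated rhizosphere samples, an OTU/ASV table, a
rooted phylogeny of the taxa, and a table of nine soil covariates (TN, TP,
TK, salt, SOM, SUE, SALP, SSC, pH). This vignette explains the models, the
parameters that matter, the synthetic-data generator the tests rely on,
and the numerical choices made where the design was genuinely open.

## The data container

`CommunityExperiment` extends `SummarizedExperiment`: taxa are rows of the
`"counts"` assay, samples are columns, the mandatory `group` column of
`colData` holds the distance class, and the nine soil covariates ride
along as additional `colData` columns. A rooted `ape::phylo` can be
attached in the `tree` slot; validity demands non-negative abundances, no
all-zero sample, unique identifiers, and (when a tree is present) tips
covering the taxa. Sample and taxon order is canonicalised
lexicographically on construction, so every downstream table is
order-stable regardless of input order.

Counts are total-sum scaled (`toRelative()`), not rarefied: the statistics
downstream either work on relative abundances or, for the Raup–Crick null,
explicitly condition on each sample's observed depth. A seeded
`rarefyCommunity()` exists for users who want even depths, but it is off
by default in the pipeline.

## Abundant and rare taxa

Within each distance group, a taxon is *abundant* when its minimum
relative abundance over the group's samples exceeds 0.1%, and *rare* when
its maximum stays below 0.01%; both inequalities are strict, and
everything else is *intermediate*. The min/max reading (rather than a
group-mean reading) is the conventional abundant/rare framework and is the
implemented default; both thresholds are arguments. The combined tables
keep a sample's observed value where the taxon is abundant (rare) in that
sample's group and assign exactly 0 elsewhere, so a taxon may contribute
to the abundant table at one distance and to the rare table at another.
All-zero columns are dropped from the combined tables: a taxon absent from
every group it is "rare" in carries no signal and would distort richness.

Note the arithmetic constraint between thresholds and sequencing depth:
at depth `d` the smallest nonzero share is `1/d`, so the 0.01% ceiling can
only bind when `d > 10^4`. The survey defaults assume survey-scale depths
(tens of thousands of reads); analyses of shallower data should scale the
thresholds accordingly.

## Diversity

Shannon entropy is reported in natural log and Simpson as `1 - D`, the
vegan conventions; richness is the count of taxa with nonzero abundance.
Bray–Curtis dissimilarity is computed on relative abundances. NMDS
(`metaMDS`, Kruskal stress-1, 20 random restarts, seeded) ordains the
dissimilarity in `k = 2` dimensions — the dissimilarity and dimensionality
are the field-standard defaults, as the choice was open. PERMANOVA uses
`vegan::adonis2` (Gower-centred pseudo-F, permutation p). The ANOVA + LSD
report on alpha indices uses the pooled residual mean square for all
pairwise t tests without multiplicity correction, which is what the LSD
procedure means; an optional `log1p` transform accommodates skewed
indices.

## Assembly null models

The package's core is the two-null-model decomposition of community
assembly.

**beta-MNTD** between samples *j* and *m* is

$$\beta\mathrm{MNTD}_{jm} = \tfrac12\Big[\sum_{i \in j} f_{ij}
\min_{k \in m} d_{ik} + \sum_{k \in m} f_{km} \min_{i \in j} d_{ki}\Big]$$

with \(f\) the relative abundances renormalised over the taxa present in
each sample and \(d\) the patristic distance. It is computed for all pairs
at once as \(\tfrac12(B + B^\top)\) where \(B = W^\top M\), \(W\) the taxa
× samples weight matrix and \(M_{im}\) the distance from taxon *i* to its
nearest taxon in sample *m*; an exhaustive double-loop oracle and
`picante::comdistnt` verify it in the tests. The unweighted variant gives
each present taxon weight \(1/S\).

**beta-NTI** standardises the observed beta-MNTD against a null in which
the taxa swap positions on the phylogeny: a permutation of the taxon set
is applied to the rows/columns of the patristic matrix while abundances
stay put, `nNull` times (999 by default; the tests use 199). Pairs whose
null distribution has zero spread — identical communities, for which every
shuffle moves both communities jointly and beta-MNTD stays 0 — are
returned as `NA` with a warning rather than an arbitrary number. The
randomisation pool is the set of taxa present anywhere in the supplied
table (the regional pool across all distances), because the analysis is
one cross-distance null model viewed per group, not per-group null models.

**Raup–Crick (Bray–Curtis)** asks whether two communities are more or less
dissimilar than expected if they were assembled at random from the
regional pool. Each null community preserves the sample's observed
richness and total reads; which taxa occur is drawn (without replacement)
with probability proportional to regional occurrence frequency, each drawn
taxon receives one individual, and the remaining individuals are allocated
multinomially in proportion to regional relative abundance among the drawn
taxa. With `B` the Bray–Curtis value,

$$\mathrm{RC} = 2\left(\frac{\#\{B_\mathrm{null} < B_\mathrm{obs}\} +
\tfrac12\#\{\mathrm{ties}\}}{n_\mathrm{null}} - \tfrac12\right) \in [-1, 1],$$

ties taking half weight (the standard Raup–Crick treatment). The null
assembles individuals, so it requires raw integer counts.

**Classification.** A pair is assigned heterogeneous selection when
bNTI > 2, homogeneous selection when bNTI < −2; otherwise RC > 0.95 means
dispersal limitation, RC < −0.95 homogenizing dispersal, and |RC| ≤ 0.95
undominated. Contributions are summarised as percentages of pairs, over
all pairs or within groups.

## Co-occurrence networks

Per distance group, the 250 most abundant taxa (ties broken
lexicographically) are correlated pairwise by Spearman's rho over the
group's replicates; an edge requires |rho| > 0.8 *and* p < 0.01, with the
sign retained. The p-value uses the t approximation on rho with
average-rank ties; an exact full-permutation option exists for n ≤ 8
samples. No multiplicity correction is applied by default (a
Benjamini–Hochberg switch exists) because the edge rule is a raw
two-threshold screen. Zero-variance taxa cannot be ranked and are
excluded with a warning; isolated nodes are dropped. Both behaviours are
why realised node counts fall slightly below the number of selected taxa.

Topology reports average degree `2E/N`, density `2E/(N(N-1))`, average
path length and diameter over connected pairs of the unweighted graph,
mean local clustering (nodes of degree < 2 contribute 0), and the
modularity of the partition found by greedy modularity maximisation
(deterministic; Louvain by flag). Zi–Pi roles use the within-module degree
z-score and participation coefficient with the usual 2.5 / 0.62
thresholds; a module whose within-degrees have zero spread gives its
members Zi = 0, and isolated nodes take Pi = 0.

**Robustness** is the natural connectivity of the remaining graph,
\(\bar\lambda = \ln \frac1N \sum_i e^{\lambda_i}\) over adjacency
eigenvalues (isolated nodes included), after removing a growing fraction
of nodes. Random removal averages over seeded draws. Targeted removal is
an *adaptive* degree attack — the highest-degree node of the remaining
graph is removed at each step — rather than a static order computed once:
under a static order the curve can tick upward late in the attack, when
removing a node that contributes little to the spectrum shrinks the
denominator faster than the numerator, whereas the adaptive attack
dismantles fragments before isolates dominate and decays monotonically in
practice. Natural connectivity is provably non-increasing under *edge*
removal on a fixed node set, and the tests assert that invariant
separately.

## Environmental drivers

The multiple regression of an alpha-diversity index on the nine soil
factors is decomposed by the LMG method: factor *j*'s share is its
sequential increase in R² averaged over all orderings of the predictors.
This is computed *exactly* from the 2⁹ = 512 subset R² values (via the
correlation matrix, one linear solve per subset), not by sampling
orderings; the shares are non-negative and sum to the full-model R² to
machine precision, and under exactly orthogonal predictors each share
equals the factor's marginal R². Univariate OLS fits per factor supply the
sign and significance language ("significantly negatively correlated").

The "Monte Carlo test" of factors against community structure is an
envfit-style permutation test on a redundancy analysis: the community is
Hellinger-transformed (the standard transform for RDA on abundances;
`none` and `log1p` are switchable), the factors standardised, and each
factor's R² is its squared correlation with its best-fit direction in the
plane of the first two constrained axes, with p from permuting sample
rows. The variance explained by RDA1/RDA2 is reported alongside. A
marginal-term permutation alternative (`method = "margin"`) is available.

The bNTI-versus-environment regression pairs each sample pair's bNTI with
|env_i − env_j|. Because pairs share samples, the OLS t test is invalid;
significance comes from Mantel-type permutations that shuffle the
sample-to-environment assignment and recompute the pair differences.

## The synthetic-data generator

The generator emulates the survey design — 5 distance groups with
9/6/6/6/6 replicates (more at the most disturbed site), a few-thousand-tip
pure-birth phylogeny scaled to unit depth, 30 000 reads per sample — with
known ground truth. Niche optima evolve by Brownian motion on the tree
(`nicheSignal` is the BM standard deviation per unit branch length), the
regional pool is log-normal (σ = 1.0), and each sample's taxon weights are

$$w_{si} \propto (1-d)\, a_i\, e^{\eta_{si}}\,
e^{-(\mu_i - e_g)^2 / 2\sigma^2} + d\, a_i$$

— regional abundance × Gaussian environmental filter × per-sample
log-normal drift, blended with a mass-effect term `d` = `dispersalRate`.
Counts are multinomial at the configured depth (the simplest model that
exercises every stage; overdispersion beyond the drift term was left
out deliberately). The nine soil covariates load linearly on the single
latent disturbance axis with fixed loadings plus replicate noise — one
latent axis rather than nine independent filters, because distance is
treated as the master gradient.

Two points deserve emphasis:

* **The drift term is what makes the neutral regime meaningful.** Without
  it, replicate samples are i.i.d. multinomial draws from one weight
  vector and are far *more* similar than the Raup–Crick null expects
  (RC ≈ −1 everywhere), which is mass-effect homogenisation, not
  neutrality. With low dispersal each community must fluctuate
  independently around the pool. The default `driftSD = 0.26` (and pool
  σ = 1.0) is the *self-consistency point* at which neutral, weakly
  dispersing communities show the same assembly stochasticity as the null
  model itself — measured at the reference scale of 200 taxa and 1000
  reads — so the neutral regime sits mid-null (RC centred on 0, bNTI
  within ±2 for ~95% of pairs) rather than artificially homogenised or
  dispersed. At `dispersalRate = 1` the drift term vanishes and
  composition equals the regional pool exactly.
* **A selection filter can be too narrow to detect.** The
  `simRegimeSelection()` preset (σ = 0.7 against optima at ±2,
  `nicheSignal = 2`, dispersal 0.01) keeps whole clades in each group. A
  much narrower filter concentrates each community on one or two taxa,
  which destabilises nearest-taxon distances and *weakens* the bNTI
  signal it is meant to create.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomic structure (no names, no lineages beyond the tree), spatial
autocorrelation within groups, co-occurrence driven by biotic interaction
(network edges in simulated data arise from shared environmental
responses and compositional coupling only), and nine independently acting
soil factors. Passing tests therefore demonstrate the *statistical
machinery* — calibration of the nulls, recovery of planted regimes,
exactness of the arithmetic — not that any particular real-world dataset
will show these effects.

## Problem sizes and numerical choices

The test suite and the acceptance script run reduced-scale versions of
every analysis, chosen as the smallest sizes at which the properties under
test are statistically identifiable: null-model calibration uses 7
datasets of 3 + 3 samples over 200 taxa with 199 null draws (105 pairs);
regime recovery pools between-group pairs from 3 such datasets; the
PERMANOVA level check uses 500 null datasets of 10 samples × 30 taxa at
199 permutations; LMG invariants use 100 random 9-predictor datasets. At
survey scale one would use 999 null draws and permutations throughout —
both are arguments everywhere.

Degenerate inputs are handled explicitly rather than silently: identical
communities give `NA` bNTI (warning); zero-variance taxa and soil factors
are excluded or reported `NA` (warning); constant dissimilarities yield a
zero-stress degenerate ordination (warning); exactly collinear predictors
are dropped from the LMG regression (warning, `NA` share); an empty
network exports a valid zero-edge file (warning). Ties are broken
lexicographically wherever an order matters (top-OTU selection, targeted
attack), and every stochastic routine takes an explicit seed, making the
pipeline bit-reproducible from its manifest.

## Known limitations

* beta-NTI inherits the usual sensitivity of SES statistics to the
  randomisation pool; only the table-wide pool is implemented (per-group
  pools are an easy extension but change the question being asked).
* The Raup–Crick null draws occurrences proportional to observed
  occurrence frequency estimated from the supplied samples; with very few
  samples that estimate is coarse, and RC values discretise visibly at
  low `nNull`.
* The Spearman edge test at 6 replicates has limited resolution: the
  t approximation is anticonservative at |rho| near 1, which is why the
  exact option exists for small n.
* LMG is exact but exponential in the number of predictors; it is meant
  for the nine-factor setting (512 fits), not for dozens of covariates.
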