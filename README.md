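# micasm

Community assembly processes, co-occurrence networks and environmental
drivers for distance-gradient soil microbiomes.

## What this is for

Surveys of soil (e.g. rhizosphere) bacterial communities along a
disturbance gradient typically ask four questions: how do diversity and
composition change along the gradient; which taxa are *abundant* and which
*rare* at each distance, and do the two fractions respond differently;
whether community turnover is governed by deterministic selection or by
stochastic dispersal and drift; and which soil variables drive the
patterns. `micasm` implements that full inference stack for an OTU/ASV
table with replicated distance groups, a rooted phylogeny and a table of
nine soil covariates (TN, TP, TK, salt, SOM, SUE, SALP, SSC, pH) — plus a
seeded synthetic-data generator with tunable selection/dispersal regimes,
so every stage is testable against known ground truth.

The core statistics, in the field's standard notation:

* **beta-MNTD / beta-NTI** — abundance-weighted mean distance of each
  taxon to its nearest relative in the paired community,
  `betaMNTD(j,m) = 1/2 [ Σ_i f_ij min_k d(i,k) + Σ_k f_km min_i d(k,i) ]`,
  standardised against a tip-shuffling null:
  `betaNTI = (obs − mean(null)) / sd(null)`. `betaNTI > 2` heterogeneous
  selection, `< −2` homogeneous selection.
* **RCbray** — the observed Bray–Curtis placed in a null distribution of
  communities reassembled from the regional pool under fixed richness and
  depth; `RC = 2((#{null < obs} + ½ ties)/n_null − ½) ∈ [−1, 1]`.
  `RC > 0.95` dispersal limitation, `< −0.95` homogenizing dispersal,
  otherwise undominated.
* **Abundant/rare partition** — per group: min relative abundance > 0.1%
  ⇒ abundant; max < 0.01% ⇒ rare (strict, per-group, with exact-zero
  assignment in the combined tables).
* **Networks** — Spearman co-occurrence among the top 250 taxa per group
  (`|rho| > 0.8`, `p < 0.01`), topology (degree `2E/N`, density
  `2E/(N(N−1))`, path length, clustering, modularity), Zi–Pi node roles
  (thresholds 2.5 / 0.62) and natural-connectivity robustness
  `ln(mean(exp(λ_i)))` under random and adaptive targeted node removal.
* **Drivers** — exact LMG relative-importance decomposition of the
  nine-factor regression on alpha diversity (shares sum to the model R²),
  univariate trends, an RDA/envfit Monte Carlo test of each factor against
  community structure, and Mantel-permutation regression of pairwise
  beta-NTI on environmental differences.

## Worked example

```r
library(micasm)

cfg <- simConfig(nTaxa = 400, nGroups = 5,
                 repsPerGroup = c(9, 6, 6, 6, 6), depth = 10000, seed = 4)
sim <- simulateDataset(cfg)
x <- sim$community
x
#> CommunityExperiment: 33 samples x 400 taxa
#> groups: H0(9) H1(6) H2(6) H3(6) H5(6)
#> scale: counts
#> soil factors: TN, TP, TK, salt, SOM, SUE, SALP, SSC, pH
#> tree: 400 tips

alpha <- alphaDiversity(x)
head(alpha, 3)
#>   sample group  shannon   simpson richness
#> 1 H0_s01    H0 5.193242 0.9892144      392
#> 2 H0_s02    H0 5.190384 0.9890904      394
#> 3 H0_s03    H0 5.225071 0.9898670      389

pm <- permanovaTest(brayCurtis(x), sampleGroups(x), nPerm = 999, seed = 1)
sprintf("PERMANOVA: F = %.2f, R2 = %.3f, p = %.3f", pm$F, pm$R2, pm$p)
#> "PERMANOVA: F = 79.13, R2 = 0.919, p = 0.001"
```

Distance explains ~92% of the compositional variance here because the
generator's default gradient is strong. Assembly processes between the two
most disturbed groups:

```r
sub <- x[, sampleGroups(x) %in% c("H0", "H1")]
pw <- assemblyAnalysis(sub, nNull = 199, seed = 1)
summarizeAssembly(pw)
#>   scope                 process count   percent
#> 1   all heterogeneous_selection     6  5.714286
#> 2   all   homogeneous_selection     0  0.000000
#> 3   all    dispersal_limitation    79 75.238095
#> 4   all  homogenizing_dispersal     0  0.000000
#> 5   all             undominated    20 19.047619
```

So with the default moderate filter most pairs classify as dispersal
limitation (high turnover relative to the null), with a deterministic
minority — the percentages are the per-process contributions that a
stacked-bar assembly figure would display. A co-occurrence network for the
most disturbed group and the soil-factor attribution of Shannon
diversity:

```r
net <- buildNetwork(selectTopOtus(x, "H0", 100),
                    rhoThresh = 0.7, pThresh = 0.05)
networkTopology(net)[, c("n_nodes", "n_edges", "average_degree",
                         "density", "modularity")]
#>   n_nodes n_edges average_degree    density modularity
#> 1      99     184       3.717172 0.03793032  0.6700142

imp <- lmgImportance(soilFactors(x), setNames(alpha$shannon, alpha$sample))
head(imp[order(-imp$lmg), ], 3)
#>   factor        lmg lmg_percent sign
#> 6    SUE 0.09465080    39.09495   -1
#> 5    SOM 0.02628464    10.85671   -1
#> 3     TK 0.02492223    10.29398   -1
attr(imp, "totalR2")
#> 0.242
```

The nine factors jointly explain 24% of the Shannon variation; SUE carries
the largest LMG share (39% of the explained variance), with a negative
univariate slope. `runPipeline()` chains all stages (partition →
diversity → assembly → networks → drivers) over the three taxa scopes
(total / abundant / rare) from one config and writes a reproducibility
manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.

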