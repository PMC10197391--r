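# landgen

Landscape genomics of population differentiation and genomic offset, for
population geneticists working with reduced-representation SNP data (for
example ddRAD) sampled from georeferenced populations of a wide-ranging
species. The package quantifies how much of the spatial pattern of
genome-wide differentiation is explained by geography (isolation by
distance, IBD), by landscape resistance (isolation by resistance, IBR) and
by environmental differences (isolation by environment, IBE), and projects
the fitted genotype–environment relationship onto future climate layers to
map *genomic offset* — the expected mismatch between present-day allele
frequencies and a future climate at the same location.

## What it computes

Given a diploid biallelic VCF, a population/coordinate table, per-population
environmental values and a habitat-suitability raster:

- **Diversity and differentiation.** Per-population observed and expected
  heterozygosity (He with the small-sample gene-copy correction
  n_g/(n_g−1)·(1−p²−q²)), nucleotide diversity at SNP sites, multilocus
  F_IS = 1 − H̄ₒ/H̄ₑ, a pooled 1-df χ² check of Hₒ against Hardy–Weinberg
  expectation, and pairwise Weir–Cockerham (1984) θ from the two-population
  variance components a, b, c, aggregated as Σa / Σ(a+b+c) (the per-locus
  mean variant is also reported).
- **Distances.** Straight-line distance (haversine, R = 6371 km, or
  planar), least-cost distance and circuit-theory effective resistance over
  an 8-neighbor grid graph built from the suitability raster (conductance =
  suitability by default), and per-variable environmental distances
  |xᵢ − xⱼ|.
- **Matrix association.** Permutation Mantel and partial Mantel tests
  (Spearman by default; the genetic matrix is the one permuted) and
  reciprocal causal modeling: for every pair of candidate drivers {A, B}
  the heatmap entry D[A,B] = R_PM(G∼A|B) − R_PM(G∼B|A).
- **Generalized dissimilarity modeling.** Monotone matrix regression
  μ = 1 − exp(−η), η = β₀ + Σₖ Σₛ β_ks |I_ks(x₁) − I_ks(x₂)|, with
  three I-spline basis functions per predictor (knots at the
  0/50/100th percentiles) and all coefficients constrained non-negative;
  percent deviance explained and spline-height predictor importance.
- **MLPE ranking.** Single-predictor mixed models
  y = β₀ + β₁x + Zu + e with a random effect for each population entering
  a pair, fitted by maximum likelihood and ranked by AIC (k = 4).
- **Genomic offset.** Per raster cell,
  offset = 1 − exp(−Σₖ |fₖ(x_future) − fₖ(x_current)|) over the model's
  climate predictors, with GCM ensemble averaging of future layers.

A seeded synthetic-landscape generator (`syntheticDataset()`) draws
environmental gradients, habitat suitability, population locations and SNP
genotypes whose population allele-frequency covariance decays with both
geographic and environmental distance — so every stage of the pipeline is
testable end-to-end with known generative truth.

## Worked example

```r
library(landgen)
cfg <- syntheticConfig(seed = 7)            # 21 pops x 4 ind, 2000 SNPs
res <- runPipeline(cfg, "demo-run", nPerm = 999, rcmPerm = 99)

res$fst
#> PairwiseMatrix [genetic] over 21 populations
#>   off-diagonal range [0.0888, 0.3802], mean 0.3032

head(res$diversity[, c("pop", "nInd", "Ho", "He", "Fis")], 2)
#>   pop nInd        Ho        He       Fis
#> 1 P01    4 0.1805231 0.2560857 0.2950676
#> 2 P02    4 0.1753644 0.2511023 0.3016216

res$mantel[res$mantel$variable == "euclidean", ]
#>   variable         r     p nPerm
#>  euclidean 0.9392803 0.001   999

res$gdm
#> GDMModel: 4 predictors, 95.5% deviance explained
#>   geographic     spline height 0.2631
#>   var3           spline height 0.0688
#>   ...

head(res$mlpe[, c("predictor", "AIC", "deltaAIC")], 2)
#>  predictor       AIC deltaAIC
#>  euclidean -975.5809  0.00000
#>        lcd -881.7538 93.82708

summary(as.vector(rasterValues(res$offset$offset)))
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.007963 0.028651 0.036218 0.037188 0.045681 0.065810
```

Pairwise FST averages ≈ 0.30 with strong isolation by distance (Mantel
r = 0.94 against straight-line distance, p = 0.001); the GDM attributes
most turnover to geographic distance, MLPE ranks straight-line distance
first by a wide AIC margin, and the projected offset under the synthetic
future scenario stays below 0.07 per cell. Every table is also written
under the run directory (`fst_matrix.csv`, `mantel_tests.tsv`,
`rcm_heatmap.csv`, `gdm_importance.tsv`, `mlpe_ranking.tsv`,
`genomic_offset.asc`, ...) with MD5 checksums in `manifest.json`.

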