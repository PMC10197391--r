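---
title: "Methods: landscape genomics of differentiation and genomic offset"
author: "landgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genomics of differentiation and genomic offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the estimators and models, the assumptions behind them, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices that were genuinely open when the package was designed.

## The scientific setting

The package targets studies that sample a handful of diploid individuals
from each of a few dozen georeferenced populations of one species,
genotype them at thousands of biallelic SNPs (typically by
reduced-representation sequencing), and ask which forces structure
genome-wide differentiation: geographic separation (isolation by
distance), landscape resistance to movement (isolation by resistance), or
environmental differences driving divergent selection (isolation by
environment). A second question follows: if climate changes, how far will
each location's environment move relative to the fitted
genotype–environment relationship — the *genomic offset*?

## Genotypes, filtering and diversity

Genotypes are alternate-allele dosages in {0, 1, 2, NA}, held as a
`SummarizedExperiment` subclass with loci as rows. Filtering mirrors the
conventional VCF thresholds: site QUAL ≥ 30, minor-allele frequency ≥ 0.01
on non-missing calls, and call rate ≥ 0.7. The call-rate threshold is
deliberately interpreted as a *minimum proportion of called genotypes*,
which is the convention of the standard command-line filtering tool whose
parameter name suggests the opposite reading.

Per population, over loci with at least one called genotype:

* Hₒ = heterozygous calls / called genotypes, averaged over loci;
* Hₑ per locus uses the unbiased gene-copy correction
  (n_g/(n_g − 1))(1 − p² − q²), averaged over loci;
* π is reported at SNP sites only and there equals per-site unbiased
  heterozygosity. It is *not* comparable to π computed over RAD loci that
  include invariant sites, which is typically several-fold smaller; the
  two columns are kept separate for interface parity, not because they
  estimate different quantities at SNP sites.
* F_IS = 1 − H̄ₒ/H̄ₑ as a ratio of multilocus means (the common software
  convention); a per-locus-averaged variant is available via
  `perLocusFis = TRUE`. The ratio form is flagged undefined when H̄ₑ = 0.

The Hₒ-vs-Hₑ check pools genotype calls across loci within a population
and compares observed versus Hardy–Weinberg-expected heterozygote counts
with a 1-df χ² on the two-cell het/hom partition. Pooling across loci was
an open choice (the aggregation level is rarely stated in empirical
papers); pooling maximizes power at the population level, which is where
the question ("does this population depart from HW?") lives.

Pairwise differentiation uses the two-population Weir–Cockerham (1984)
variance components a (among populations), b (among individuals within
populations) and c (within individuals). The headline estimator is the
weighted ratio Σa / Σ(a + b + c) over loci; the mean of per-locus ratios
is also reported because "mean pairwise FST" is ambiguous between the two
and the choice matters at low sample sizes. Negative estimates are
retained (they are part of the estimator's sampling distribution), only
counted as a flag. Loci with fewer than one called genotype in either
population, or fewer than three total, are skipped for that pair.

Diversity–environment correlations are plain Pearson r across populations
with t = |r|√(df/(1 − r²)), df = n − 2, and a two-sided p from the t
distribution. The t statistic is always derived from r by this formula;
published tables occasionally contain t values inconsistent with their own
r at the stated df, and the package intentionally never reproduces such
inconsistencies.

## Distances

* **Straight-line**: haversine great-circle distance with Earth radius
  6371 km for lon/lat input (km), or planar Euclidean distance in map
  units. Which one an empirical study used is often unstated; both are
  exposed and `mode = "auto"` picks by column names.
* **Resistance surface**: habitat suitability s ∈ [0, 1] maps to per-cell
  conductance max(s, ε), ε = 10⁻³ (resistance 1/conductance). This
  "suitability = conductance" convention is the common habitat
  parameterization of circuit-theory tools; the alternative
  resistance = 1 − s + ε is exposed by flag since the transform actually
  used by older GIS toolchains is rarely documented. The ε floor keeps
  fully unsuitable cells traversable but expensive, so landscapes stay
  connected.
* **Least-cost distance**: Dijkstra shortest paths on the 8-neighbor grid
  graph; the cost of a move is the arithmetic mean of the two cell
  resistances × cell size × √2 for diagonals. Arithmetic-mean edge costs
  and √2 diagonal weighting are pinned here because "8-neighbor" alone
  does not determine them.
* **Circuit distance**: the same grid as a resistor network with edge
  conductance mean(c₁, c₂)/length-factor; pairwise effective resistance
  R_ij = (eᵢ − eⱼ)ᵀ L⁺ (eᵢ − eⱼ) computed via sparse Cholesky solves of
  the Laplacian grounded at one focal node (one factorization, one solve
  per remaining focal node) — never a dense pseudoinverse, which is used
  only as a test oracle on grids of ≤ 100 cells. Populations snap to the
  nearest non-nodata cell center with row-major tie-breaking.

Environmental distance is the absolute per-variable difference between
populations, one matrix per variable.

## Mantel, partial Mantel, reciprocal causal modeling

The Mantel statistic is the correlation (Spearman by default — rank
transform first, then product-moment) of the n(n−1)/2 off-diagonal
entries. The null is generated by simultaneous row/column permutation of
the *genetic* matrix, and the two-sided p is
(1 + #{|r*| ≥ |r_obs|})/(n_perm + 1). For n ≤ 8 an exact mode enumerates
all n! relabelings. Spearman is the default because rank correlation is
the stated convention of the empirical literature this package serves,
even though much of the Mantel literature defaults to Pearson; both are
exposed.

The partial statistic is the first-order partial correlation
R_PM = (r_AB − r_AC·r_BC)/√((1 − r_AC²)(1 − r_BC²)) on the (possibly
rank-transformed) off-diagonal vectors. Permutation uses the
raw-label-permutation method — permute A's labels and recompute the full
partial statistic — rather than residual permutation; raw permutation is
simpler to reproduce exactly and its small conservatism is irrelevant to
the heatmap use below. When B and C are identical the formula is a 0/0
limit whose value along any approach path is 0, and the implementation
returns 0 rather than a flag; a genuinely collinear control
(|r| = 1, B ≠ C) is flagged undefined.

Reciprocal causal modeling runs, for every unordered pair of candidate
drivers {A, B}, the two partial tests R_PM(G ∼ A | B) and
R_PM(G ∼ B | A), and reports D[A,B] = R_PM-A − R_PM-B. With 11 candidate
matrices this is exactly 55 reciprocal models / 110 partial tests. A row
of consistently positive D identifies a driver supported against every
alternative. D is antisymmetric by construction and asserted so.

## Generalized dissimilarity modeling

The GDM regresses pairwise dissimilarity d ∈ [0, 1] (here pairwise FST,
negatives clamped to 0) on predictor differences through
μ = 1 − exp(−η) with

η = β₀ + Σₖ Σₛ β_ks |I_ks(x_k,site1) − I_ks(x_k,site2)|,

where each predictor carries three monotone I-spline basis functions with
knots at the 0th/50th/100th percentiles of its observed values (the
reference implementation's default). Geographic distance enters as a
pairwise predictor splined directly on the distance value. The basis is
built from the B-spline identity — quadratic B-splines B₁..B₄ on the knot
vector (a,a,a,m,b,b,b) give I_i = Σ_{j>i} B_j — so each basis function is
exactly 0 at the predictor minimum, exactly 1 at its maximum, and
non-decreasing; inputs beyond the span are clamped (flat extension),
which is also how future-climate extrapolation is handled.

Fitting minimizes the continuous binomial-form deviance
2Σ w[d log(d/μ) + (1−d) log((1−d)/(1−μ))] under β ≥ 0 (including the
intercept, so μ ≥ 0 always) by iteratively reweighted least squares with
a Lawson–Hanson non-negative least-squares inner step and step-halving;
convergence is declared when the deviance moves by < 10⁻⁶, capped at 100
iterations (non-convergence returns the fit with a warning flag). The
response is clamped to [10⁻⁶, 1 − 10⁻⁶] inside the deviance. Percent
deviance explained is 100(1 − D_resid/D_null) against the best
intercept-only model. Predictor importance is the fitted spline height
Σₛ β_ks — the maximum of fₖ, since every basis reaches 1 — normalized to
percentages. The response is not rescaled before fitting (whether
empirical studies rescale FST first is usually unstated; not rescaling is
the conservative default), and GDM predictor p-values are deliberately
out of scope — the way published GDM p-values are derived is generally
unspecified, and the permutation machinery in the Mantel module covers
significance questions.

## MLPE ranking

For each candidate distance matrix X the model
y = β₀ + β₁x + Zu + e is fitted to the n(n−1)/2 pairs, where Z is the
pair→population incidence matrix (two ones per row),
u ∼ N(0, σ_u² I), e ∼ N(0, σ_e² I), so V = σ_u² ZZᵀ + σ_e² I. β and σ_e²
are profiled out analytically (after one eigendecomposition of ZZᵀ) and
the ratio λ = σ_u²/σ_e² is optimized on a bounded log scale, making the
fit deterministic. Maximum likelihood (not REML) is used so AICs are
comparable across predictors; AIC = −2ℓ + 2k with k = 4 (β₀, β₁, two
variances). Predictors are z-scored over off-diagonals before fitting (the
convention of the resistance-modeling package family), the response is
left raw. The equivalent pairwise correlation ρ = σ_u²/(σ_u² + σ_e²) is
reported. A fit whose optimal λ sits at the lower search bound is the OLS
collapse (σ_u² = 0) and is flagged, not treated as an error. ΔAIC is
always recomputed from the fitted AICs — published ΔAIC columns are
occasionally inconsistent with their own AIC column, and the package never
copies such values.

## Genomic offset

For every raster cell,
offset = 1 − exp(−Σₖ |fₖ(x_k^future) − fₖ(x_k^current)|) over the GDM's
climate predictors; the geographic term contributes nothing because
location does not change. The η-scale sum is emitted as a companion layer
because which of the two scales published offset maps use is typically
unstated; the dissimilarity scale is the default since it is bounded and
interpretable as expected turnover. GCM ensembles are averaged cell-wise
on the raw climate scale *before* the spline transform (matching the
practice of extracting ensemble means from climate archives), nodata
propagating. Cells whose future values leave the fitted knot span use the
flat spline extension and are counted.

## The synthetic generator: what it emulates, what it does not

`syntheticConfig()` defaults describe the study design the package is
aimed at: 21 populations × 4 diploids, 2000 biallelic SNPs, a 64 × 64
grid of 500 m cells, 10% missing calls, QUAL ∼ U[25, 60] (so the QUAL ≥ 30
filter actually removes loci), and Wright's F = 0.35 (strong
within-population inbreeding, as reported for the amphibian systems this
workflow targets).

Allele frequencies follow a logit-scale Gaussian process: per locus an
ancestral logit is drawn uniformly on [logit 0.1, logit 0.9] and
population logits are drawn jointly with covariance
σ² exp(−d_geo/φ_geo − d_env/φ_env). The product-exponential kernel makes
IBD and IBE strengths independently tunable, which is exactly what the
recovery tests need. d_env is the mean absolute difference of the
environmental variables (the same definition used for the environmental
distance matrices). Frequencies are clipped to [10⁻³, 1 − 10⁻³] and the
covariance gets a 10⁻⁸ diagonal jitter before factorization. The defaults
σ² = 4, φ_geo = 18 km (≈ 40% of the landscape extent), φ_env = 3 were
fixed once so that realized pairwise FST falls inside the empirically
typical 0.02–0.6 band with a mean near 0.3, and were not revisited.

Environmental layers are rotated planar gradients plus Gaussian-smoothed
seeded noise (amplitude 0.3); suitability is a logistic transform of a
fixed linear combination, hence strictly inside (0, 1). The future
scenario adds a uniform displacement (default 0.75 environmental units)
plus a small smooth perturbation.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), genealogical noise (frequencies are the truth, not a
coalescent realization), demographic history such as range expansions,
allele-frequency clines driven by selection at individual loci, and
spatially autocorrelated missingness. Passing tests therefore demonstrate
that the estimators recover the generative IBD/IBE structure of this
model — not that any particular empirical dataset satisfies it. One
consequence worth knowing: because the synthetic environmental layers are
spatial gradients, environmental and geographic distances are confounded
in full synthetic runs exactly as they are in real landscapes; tests that
need a *pure* IBD signal therefore feed spatially unstructured
environmental values into the frequency simulator directly.

## Numerical choices and degenerate inputs

* Permutation p-values use the +1 correction and a 10⁻¹² comparison
  tolerance so exact-enumeration equivalence survives floating-point ties.
* Zero-variance off-diagonal vectors, collinear controls, zero null
  deviance, all-zero GDM coefficients and monomorphic populations are
  flagged (NA) rather than silently zeroed.
* The NNLS solver is active-set (Lawson–Hanson) with a tiny ridge fallback
  on rank-deficient subproblems; it terminates on exact KKT conditions, so
  GDM fits are order-invariant to ~10⁻⁸.
* A degenerate I-spline median knot (median equal to a boundary) is nudged
  to the interval midpoint; a constant predictor yields an all-zero basis
  and drops out of the fit.
* Raster I/O is the plain-text ESRI ASCII grid format; population
  coordinates snap to the nearest usable cell, and disconnected resistance
  graphs raise errors naming the offending pair.

## Problem sizes used by the test suite

The suite validates kernels against exact oracles at small sizes (dense
Laplacian pseudoinverse at ≤ 100 cells, exhaustive path enumeration on
3 × 3 grids, all 24 relabelings at n = 4) and calibrates statistics at
moderate sizes chosen for tight Monte-Carlo error at desk scale: 1000 null
Mantel replicates at n = 21, 5000-locus null and recovery simulations, 20-
to 100-seed recovery panels for RCM, GDM and MLPE, and full pipeline runs
at 21 × 4 × 2000 SNPs on a 64 × 64 grid (a few seconds each). These sizes
are the package's own validation design.

## Known limitations

* The two-population FST path is quadratic in the number of populations
  (one pass per pair); fine for ≤ 100 populations, not tuned beyond.
* Partial Mantel permutation is raw-label permutation; users wanting
  residual-permutation variants should be aware the p-values differ
  slightly in small samples.
* GDM standard errors / predictor p-values are not provided.
* Circuit distances assume the raster graph fits in memory as a sparse
  Laplacian; extremely large grids (≫ 10⁶ cells) were not a design target.
* Great-circle distances treat coordinates as spherical; no geodetic datum
  handling.
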