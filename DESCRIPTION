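Package: landgen
Title: Landscape Genomics of Population Differentiation and Genomic Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A landscape-genomics toolkit for diploid SNP data sampled from
    georeferenced populations. Computes per-population diversity (observed and
    expected heterozygosity, nucleotide diversity at SNP sites, inbreeding
    coefficients) and pairwise Weir-Cockerham FST from VCF genotypes; builds
    geographic (straight-line, least-cost, circuit-theory) and environmental
    distance matrices on habitat-suitability resistance surfaces; tests
    isolation by distance and by environment with permutation Mantel, partial
    Mantel and reciprocal causal modeling; fits generalized dissimilarity
    models with monotone I-spline predictors; ranks single-predictor
    maximum-likelihood-population-effects (MLPE) mixed models by AIC; and
    projects fitted dissimilarity models onto future climate rasters to map
    genomic offset. Includes a fully seeded synthetic-landscape generator so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    Matrix,
    igraph,
    jsonlite,
    vcfR,
    geosphere,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
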