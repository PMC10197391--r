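#' Run the full landscape-genomics pipeline
#'
#' Orchestrates every stage end-to-end from one configuration: genotype
#' filtering, per-population diversity and the Ho-vs-He check, pairwise
#' FST, geographic/resistance/environmental distance matrices, Mantel tests
#' and the reciprocal-causal-modeling heatmap, GDM fitting with predictor
#' importance, MLPE AIC ranking, and (when future climate layers are
#' available) the genomic-offset projection. All tables are written as
#' TSV/CSV under `outDir` with MD5 checksums in `manifest.json`; reruns
#' with the same configuration and seed reproduce identical outputs.
#'
#' @param config either a [syntheticConfig()] (synthetic run) or a list
#'   with paths `vcf`, `popTable`, `envTable`, `suitability` (real-data
#'   run; `popTable` TSV needs `pop`,`x`,`y` or `pop`,`lon`,`lat` columns)
#' @param outDir output directory
#' @param nPerm Mantel permutations (default 999)
#' @param rcmPerm permutations per RCM partial test (default 99; the delta
#'   heatmap uses the statistics, not the p-values)
#' @param filter named list overriding `minQual`, `minMaf`, `maxMissing`
#' @return invisibly, a list with every stage result (`diversity`, `chi2`,
#'   `fst`, `distances`, `mantel`, `rcm`, `gdm`, `importance`, `mlpe`,
#'   `offset`, `files`)
#' @export
runPipeline <- function(config, outDir, nPerm = 999, rcmPerm = 99,
                        filter = list()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  synthetic <- inherits(config, "syntheticConfig")
  seed <- if (synthetic) config$seed else 1L
  files <- character(0)
  putTable <- function(x, name) {
    f <- file.path(outDir, name)
    write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- f
  }
  putMatrix <- function(pm, name) {
    f <- file.path(outDir, name)
    m <- as.matrix(pm)
    write.csv(data.frame(pop = rownames(m), m, check.names = FALSE), f,
              quote = FALSE, row.names = FALSE)
    files[[name]] <<- f
  }

  ## stage 1: inputs
  if (synthetic) {
    ds <- syntheticDataset(config, dir = file.path(outDir, "inputs"))
    gm <- readVCF(ds$files["vcf"],
                  popAssignment = setNames(populations(ds$genotypes),
                                           colnames(ds$genotypes)))
    popTable <- ds$popTable
    envValues <- ds$envValues
    suit <- ds$rasters$suitability
    current <- ds$rasters$env
    future <- ds$future
    euclidMode <- "planar"
  } else {
    gm <- readVCF(config$vcf,
                  popAssignment = read.table(config$popAssignment %||%
                                               config$popTable,
                                             header = TRUE, sep = "\t"))
    popTable <- read.table(config$popTable, header = TRUE, sep = "\t")
    envValues <- as.matrix(read.table(config$envTable, header = TRUE,
                                      sep = "\t", row.names = 1))
    suit <- readAsciiGrid(config$suitability)
    current <- future <- NULL
    euclidMode <- "auto"
  }

  ## stage 2: filter
  fargs <- modifyList(list(minQual = 30, minMaf = 0.01, maxMissing = 0.7),
                      filter)
  gm <- filterSNPs(gm, fargs$minQual, fargs$minMaf, fargs$maxMissing)
  putTable(data.frame(filter = names(S4Vectors::metadata(gm)$filterLog),
                      count = as.integer(S4Vectors::metadata(gm)$filterLog)),
           "filter_attrition.tsv")

  ## stage 3: diversity
  div <- populationDiversity(gm)
  chi <- hoHeChi2(gm)
  putTable(div, "diversity.tsv")
  putTable(chi, "ho_he_chi2.tsv")
  divEnv <- diversityEnvCorrelation(div, envValues)
  putTable(divEnv, "diversity_env_correlation.tsv")

  ## stage 4: FST
  fst <- fstMatrix(gm)
  putMatrix(fst, "fst_matrix.csv")

  ## stage 5: distances
  euclid <- euclideanMatrix(popTable, mode = euclidMode)
  rr <- suitabilityToResistance(suit)
  lcd <- leastCostDistance(rr, popTable)
  cd <- circuitDistance(rr, popTable)
  envD <- envDistanceMatrices(envValues)
  distances <- c(list(euclidean = euclid, lcd = lcd, cd = cd), envD)
  for (nm in names(distances))
    putMatrix(distances[[nm]], sprintf("distance_%s.csv", nm))

  ## stage 6: Mantel + RCM
  mant <- do.call(rbind, lapply(names(distances), function(nm) {
    res <- mantelTest(fst, distances[[nm]], nPerm = nPerm,
                      seed = .substream(seed, paste0("mantel-", nm)))
    data.frame(variable = nm, r = res@statistic, p = res@p.value,
               nPerm = res@nPerm)
  }))
  putTable(mant, "mantel_tests.tsv")
  rcm <- rcmHeatmap(fst, distances, nPerm = rcmPerm, seed = seed)
  write.csv(data.frame(variable = rownames(rcm@delta), rcm@delta,
                       check.names = FALSE),
            file.path(outDir, "rcm_heatmap.csv"), quote = FALSE,
            row.names = FALSE)
  files[["rcm_heatmap.csv"]] <- file.path(outDir, "rcm_heatmap.csv")

  ## stage 7: GDM
  sp <- buildSitePairs(fst, envValues, geo = euclid)
  gdm <- fitGDM(sp)
  imp <- predictorImportance(gdm)
  putTable(imp, "gdm_importance.tsv")
  putTable(gdmSplineTable(gdm), "gdm_splines.tsv")
  putTable(data.frame(quantity = c("nullDeviance", "residDeviance",
                                   "percentExplained", "intercept"),
                      value = c(gdm@nullDeviance, gdm@residDeviance,
                                gdm@explained, gdm@intercept)),
           "gdm_summary.tsv")

  ## stage 8: MLPE ranking
  mlpe <- rankMLPE(fst, distances)
  putTable(mlpe[, c("predictor", "AIC", "deltaAIC")], "mlpe_ranking.tsv")

  ## stage 9: offset (synthetic runs carry a future scenario)
  offset <- NULL
  if (!is.null(future)) {
    offset <- genomicOffset(gdm, current, future)
    f <- file.path(outDir, "genomic_offset.asc")
    writeAsciiGrid(offset$offset, f)
    files[["genomic_offset.asc"]] <- f
    putTable(populationOffsets(offset$offset, popTable),
             "population_offsets.tsv")
  }

  manifest <- list(seed = seed,
                   synthetic = synthetic,
                   nPerm = nPerm,
                   rcmPerm = rcmPerm,
                   checksums = as.list(tools::md5sum(unlist(files))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genotypes = gm, diversity = div, chi2 = chi,
                 diversityEnv = divEnv, fst = fst, distances = distances,
                 mantel = mant, rcm = rcm, gdm = gdm, importance = imp,
                 mlpe = mlpe, offset = offset, files = files,
                 popTable = popTable, envValues = envValues))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
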