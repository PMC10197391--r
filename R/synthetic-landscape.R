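#' Configuration for the synthetic landscape-genomics generator
#'
#' Builds and validates the configuration controlling every synthetic stage:
#' raster generation, population placement, allele-frequency simulation and
#' genotype drawing. Defaults emulate the sampling design the package is
#' aimed at: 21 populations of 4-5 toads each, thousands of biallelic SNPs
#' with missing calls, moderate inbreeding, and population allele-frequency
#' covariance decaying with both geographic and environmental distance
#' (isolation by distance plus isolation by environment).
#'
#' @param nPops number of populations (default 21)
#' @param nIndPerPop diploid individuals per population (default 4; may be a
#'   vector of length `nPops`)
#' @param nLoci number of biallelic SNP loci (default 2000)
#' @param gridShape integer c(rows, cols) of the landscape grid (default
#'   64 x 64)
#' @param cellSize cell edge in meters (default 500, a 500 m analysis grid)
#' @param nEnv number of synthetic environmental variables (default 3)
#' @param noiseAmp amplitude (sd) of the smoothed noise added to each
#'   environmental gradient (default 0.3; 0 gives noise-free layers)
#' @param sigma2 logit-scale variance of population allele frequencies
#'   around the ancestral frequency (default 4; 0 removes all structure)
#' @param phiGeo geographic decay range of the logit-frequency covariance,
#'   in meters (default 18000)
#' @param phiEnv environmental decay range, in environmental units (default
#'   3)
#' @param inbreedingF Wright's inbreeding coefficient F used to draw
#'   genotypes (default 0.35, matching strong within-population inbreeding)
#' @param missingRate fraction of genotype calls set missing (default 0.1)
#' @param futureShift additive climate displacement applied to build the
#'   synthetic future scenario (default 0.75 environmental units)
#' @param minSepCells minimum pairwise population separation in cell widths
#'   (default 2)
#' @param seed integer root seed; all stages derive named substreams from it
#' @return a validated configuration list of class `"syntheticConfig"`
#' @export
syntheticConfig <- function(nPops = 21, nIndPerPop = 4, nLoci = 2000,
                            gridShape = c(64, 64), cellSize = 500,
                            nEnv = 3, noiseAmp = 0.3, sigma2 = 4,
                            phiGeo = 18000, phiEnv = 3,
                            inbreedingF = 0.35, missingRate = 0.1,
                            futureShift = 0.75, minSepCells = 2,
                            seed = 1) {
  cfg <- list(nPops = as.integer(nPops), nIndPerPop = as.integer(nIndPerPop),
              nLoci = as.integer(nLoci), gridShape = as.integer(gridShape),
              cellSize = cellSize, nEnv = as.integer(nEnv),
              noiseAmp = noiseAmp, sigma2 = sigma2, phiGeo = phiGeo,
              phiEnv = phiEnv, inbreedingF = inbreedingF,
              missingRate = missingRate, futureShift = futureShift,
              minSepCells = minSepCells, seed = as.integer(seed))
  stopifnot(cfg$nPops >= 1, all(cfg$nIndPerPop >= 1), cfg$nLoci >= 1,
            length(cfg$gridShape) == 2, cfg$cellSize > 0, cfg$nEnv >= 1,
            cfg$sigma2 >= 0, cfg$phiGeo > 0, cfg$phiEnv > 0,
            cfg$inbreedingF >= 0, cfg$inbreedingF <= 1,
            cfg$missingRate >= 0, cfg$missingRate <= 1, cfg$noiseAmp >= 0)
  if (any(cfg$gridShape < 2)) stop("degenerate grid: both dimensions must be >= 2")
  if (!length(cfg$nIndPerPop) %in% c(1L, cfg$nPops))
    stop("nIndPerPop must be scalar or length nPops")
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Generate synthetic environmental and habitat-suitability rasters
#'
#' Each environmental layer is a deterministic planar gradient (direction
#' rotated per variable) plus Gaussian-smoothed seeded noise of amplitude
#' `noiseAmp`. Habitat suitability is the logistic transform of a fixed
#' linear combination of the layers, so every cell lies strictly in (0, 1).
#' All rasters share grid, origin and cell size.
#'
#' @param config a [syntheticConfig()] object
#' @return list with `env` (a [ClimateStack-class] of `nEnv` layers named
#'   `var1..varK`) and `suitability` (a [GridRaster-class])
#' @export
generateEnvRasters <- function(config) {
  nr <- config$gridShape[1]; nc <- config$gridShape[2]
  if (nr < 2 || nc < 2) stop("degenerate grid")
  cs <- config$cellSize
  set.seed(.substream(config$seed, "env-rasters"))
  xs <- (seq_len(nc) - 0.5) / nc - 0.5   # centered unit coordinates
  ys <- (nr - seq_len(nr) + 0.5) / nr - 0.5
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  layers <- vector("list", config$nEnv)
  for (k in seq_len(config$nEnv)) {
    th <- 2 * pi * (k - 1) / config$nEnv + pi / 7
    grad <- 2 * (cos(th) * X + sin(th) * Y)
    noise <- if (config$noiseAmp > 0) {
      raw <- matrix(rnorm(nr * nc), nr, nc)
      sm <- .gaussBlur(raw, sigma = 2)
      sm <- sm / max(sd(as.vector(sm)), 1e-12) * config$noiseAmp
      sm
    } else matrix(0, nr, nc)
    layers[[k]] <- GridRaster(grad + noise, xll = 0, yll = 0, cellsize = cs)
  }
  names(layers) <- paste0("var", seq_len(config$nEnv))
  w <- 1.2 * (-0.7)^(seq_len(config$nEnv) - 1)
  lin <- Reduce(`+`, Map(function(r, wk) wk * r@values, layers, w))
  suit <- GridRaster(plogis(0.2 + lin), xll = 0, yll = 0, cellsize = cs)
  list(env = ClimateStack(layers, scenario = "current"), suitability = suit)
}

#' Displace a climate stack to build a synthetic future scenario
#'
#' Adds a uniform shift plus a small smooth seeded perturbation to every
#' layer, emulating an end-of-century climate displacement on the scale of
#' the current layers.
#'
#' @param stack a [ClimateStack-class]
#' @param shift additive displacement in layer units
#' @param seed integer seed for the perturbation field
#' @return a [ClimateStack-class] tagged `"future"`
#' @export
futureClimate <- function(stack, shift, seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  layers <- lapply(stack@layers, function(r) {
    v <- r@values
    pert <- .gaussBlur(matrix(rnorm(length(v)), nrow(v), ncol(v)), 2)
    pert <- pert / max(sd(as.vector(pert)), 1e-12) * 0.2 * abs(shift)
    GridRaster(v + shift + pert, xll = r@xll, yll = r@yll,
               cellsize = r@cellsize)
  })
  ClimateStack(layers, scenario = "future")
}

#' Place populations on a synthetic landscape
#'
#' Draws `nPops` population locations at cell centers of non-nodata cells,
#' enforcing a minimum pairwise separation of `minSepCells` cell widths.
#' Deterministic under the config seed.
#'
#' @param config a [syntheticConfig()] object
#' @param rasters output of [generateEnvRasters()] (the suitability raster
#'   defines the extent and nodata mask)
#' @return data.frame with columns `pop`, `x`, `y`, `row`, `col`
#' @export
placePopulations <- function(config, rasters) {
  suit <- rasters$suitability
  v <- suit@values
  ok <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(ok) == 0) stop("raster has no usable cells")
  set.seed(.substream(config$seed, "place-pops"))
  cc <- .cellCenters(suit)
  minSep <- config$minSepCells * suit@cellsize
  sel <- matrix(numeric(0), 0, 2)
  rows <- integer(0); cols <- integer(0)
  tries <- 0L; maxTries <- 500L * config$nPops
  while (nrow(sel) < config$nPops && tries < maxTries) {
    tries <- tries + 1L
    i <- ok[sample.int(nrow(ok), 1L), ]
    pt <- c(cc$x[i[2]], cc$y[i[1]])
    if (nrow(sel) == 0 ||
        min(sqrt((sel[, 1] - pt[1])^2 + (sel[, 2] - pt[2])^2)) >= minSep) {
      sel <- rbind(sel, pt)
      rows <- c(rows, i[1]); cols <- c(cols, i[2])
    }
  }
  if (nrow(sel) < config$nPops)
    stop(sprintf(
      "could not place %d populations at separation >= %g after %d tries",
      config$nPops, minSep, maxTries))
  data.frame(pop = sprintf("P%02d", seq_len(config$nPops)),
             x = sel[, 1], y = sel[, 2], row = rows, col = cols,
             stringsAsFactors = FALSE)
}

#' Per-population environmental values
#'
#' Extracts every layer of a climate stack at the population locations.
#'
#' @param stack a [ClimateStack-class]
#' @param popTable data.frame with `pop`, `x`, `y`
#' @return numeric matrix populations x variables with dimnames
#' @export
populationEnv <- function(stack, popTable) {
  m <- vapply(stack@layers,
              function(r) extractAt(r, popTable$x, popTable$y),
              numeric(nrow(popTable)))
  m <- matrix(m, nrow = nrow(popTable),
              dimnames = list(popTable$pop, names(stack@layers)))
  m
}

# mean absolute difference across environmental variables; the environmental
# distance entering the generative covariance
.envDist <- function(envValues) {
  n <- nrow(envValues)
  d <- matrix(0, n, n, dimnames = list(rownames(envValues),
                                       rownames(envValues)))
  for (k in seq_len(ncol(envValues)))
    d <- d + abs(outer(envValues[, k], envValues[, k], `-`))
  d / ncol(envValues)
}

#' Simulate population allele frequencies with IBD + IBE structure
#'
#' For each locus an ancestral logit frequency is drawn uniformly on
#' \[logit(0.1), logit(0.9)\]; population logits are drawn jointly from a
#' Gaussian with covariance
#' `sigma2 * exp(-dGeo / phiGeo - dEnv / phiEnv)` (product-exponential decay
#' in geographic and environmental distance), so isolation by distance and
#' by environment are independently tunable. Frequencies are the inverse
#' logit, clipped to \[1e-3, 1 - 1e-3\].
#'
#' @param popTable data.frame from [placePopulations()] (planar meters)
#' @param envValues matrix from [populationEnv()], aligned to `popTable`
#' @param config a [syntheticConfig()] object
#' @return a [SyntheticTruth-class]
#' @export
simulateAlleleFrequencies <- function(popTable, envValues, config) {
  if (!identical(rownames(envValues), popTable$pop))
    stop("envValues rows must align with popTable populations")
  n <- nrow(popTable)
  dGeo <- as.matrix(dist(popTable[, c("x", "y")]))
  dEnv <- .envDist(envValues)
  Sigma <- config$sigma2 * exp(-dGeo / config$phiGeo - dEnv / config$phiEnv)
  dimnames(Sigma) <- list(popTable$pop, popTable$pop)
  set.seed(.substream(config$seed, "allele-freqs"))
  anc <- runif(config$nLoci, qlogis(0.1), qlogis(0.9))
  if (config$sigma2 > 0) {
    L <- tryCatch(chol(Sigma + diag(1e-8, n)), error = function(e)
      stop("covariance not positive definite after jitter: ",
           conditionMessage(e)))
    Z <- t(L) %*% matrix(rnorm(n * config$nLoci), n, config$nLoci)
  } else {
    Z <- matrix(0, n, config$nLoci)
  }
  logits <- sweep(Z, 2, anc, `+`)
  eps <- 1e-3
  freqs <- pmin(pmax(plogis(logits), eps), 1 - eps)
  rownames(freqs) <- popTable$pop
  new("SyntheticTruth", freqs = freqs, covariance = Sigma,
      config = unclass(config))
}

#' Draw diploid genotypes from generative allele frequencies
#'
#' Genotypes use the inbreeding-adjusted probabilities
#' P(het) = 2p(1-p)(1-F), P(hom-alt) = p^2 + Fp(1-p),
#' P(hom-ref) = (1-p)^2 + Fp(1-p), then calls are masked missing at
#' `missingRate`. Per-site QUAL scores are drawn uniformly on \[25, 60\] so
#' downstream quality filtering is exercised.
#'
#' @param truth a [SyntheticTruth-class]
#' @param config a [syntheticConfig()] object
#' @return an [SNPGenotypes-class] with population assignment in `colData`
#' @export
simulateGenotypes <- function(truth, config) {
  p <- truth@freqs
  nPops <- nrow(p); nLoci <- ncol(p)
  nInd <- if (length(config$nIndPerPop) == 1)
    rep(config$nIndPerPop, nPops) else config$nIndPerPop
  set.seed(.substream(config$seed, "genotypes"))
  F <- config$inbreedingF
  ids <- character(0); popOf <- character(0)
  dosage <- matrix(NA_integer_, nLoci, sum(nInd))
  col0 <- 0L
  for (i in seq_len(nPops)) {
    pi <- p[i, ]
    pHet <- 2 * pi * (1 - pi) * (1 - F)
    pAlt <- pi^2 + F * pi * (1 - pi)
    for (j in seq_len(nInd[i])) {
      u <- runif(nLoci)
      g <- ifelse(u < pAlt, 2L, ifelse(u < pAlt + pHet, 1L, 0L))
      col0 <- col0 + 1L
      dosage[, col0] <- g
      ids <- c(ids, sprintf("%s_%d", rownames(p)[i], j))
      popOf <- c(popOf, rownames(p)[i])
    }
  }
  if (config$missingRate > 0) {
    miss <- matrix(runif(length(dosage)) < config$missingRate,
                   nrow(dosage), ncol(dosage))
    dosage[miss] <- NA_integer_
  }
  qual <- round(runif(nLoci, 25, 60), 2)
  refIdx <- sample.int(4, nLoci, replace = TRUE)
  altIdx <- (refIdx - 1L + sample.int(3, nLoci, replace = TRUE)) %% 4L + 1L
  loci <- data.frame(chrom = "1", pos = seq_len(nLoci) * 100L, qual = qual,
                     ref = c("A", "C", "G", "T")[refIdx],
                     alt = c("A", "C", "G", "T")[altIdx],
                     stringsAsFactors = FALSE)
  SNPGenotypes(dosage, loci,
               data.frame(sample = ids, population = popOf,
                          stringsAsFactors = FALSE))
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT columns with diploid
#' unphased GT calls (`./.` for missing).
#'
#' @param gm an [SNPGenotypes-class]
#' @param path output path
#' @return invisibly, the path
#' @export
writeVCF <- function(gm, path) {
  li <- lociInfo(gm)
  d <- dosages(gm)
  gtmap <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d)] <- gtmap[d[!is.na(d)] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=landgen",
              sprintf("##contig=<ID=%s>", unique(li$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(li$chrom, li$pos, ".", li$ref, li$alt,
                format(li$qual, trim = TRUE), "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a complete synthetic landscape-genomics dataset
#'
#' Convenience wrapper running raster generation, population placement,
#' allele-frequency simulation, genotype drawing and the synthetic future
#' climate scenario under one seeded configuration. When `dir` is given, all
#' standard files (VCF, population TSV, environmental TSV, ASCII-grid
#' rasters) are written there along with a manifest of MD5 checksums.
#'
#' @param config a [syntheticConfig()] object
#' @param dir optional output directory
#' @return list with `config`, `rasters` (env stack + suitability),
#'   `future` (displaced climate stack), `popTable`, `envValues`, `truth`,
#'   `genotypes`, and `files` (paths, when `dir` was given)
#' @export
syntheticDataset <- function(config = syntheticConfig(), dir = NULL) {
  rasters <- generateEnvRasters(config)
  popTable <- placePopulations(config, rasters)
  envValues <- populationEnv(rasters$env, popTable)
  truth <- simulateAlleleFrequencies(popTable, envValues, config)
  gm <- simulateGenotypes(truth, config)
  future <- futureClimate(rasters$env, shift = config$futureShift,
                          seed = .substream(config$seed, "future-climate"))
  out <- list(config = config, rasters = rasters, future = future,
              popTable = popTable, envValues = envValues, truth = truth,
              genotypes = gm)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(vcf = file.path(dir, "genotypes.vcf"),
               pops = file.path(dir, "populations.tsv"),
               env = file.path(dir, "environment.tsv"),
               suitability = file.path(dir, "suitability.asc"))
    writeVCF(gm, files["vcf"])
    write.table(popTable, files["pops"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(pop = rownames(envValues), envValues),
                files["env"], sep = "\t", quote = FALSE, row.names = FALSE)
    writeAsciiGrid(rasters$suitability, files["suitability"])
    for (nm in names(rasters$env@layers)) {
      f <- file.path(dir, sprintf("env_%s.asc", nm))
      writeAsciiGrid(rasters$env@layers[[nm]], f)
      files[paste0("env_", nm)] <- f
      ff <- file.path(dir, sprintf("future_%s.asc", nm))
      writeAsciiGrid(future@layers[[nm]], ff)
      files[paste0("future_", nm)] <- ff
    }
    out$files <- files
  }
  out
}
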