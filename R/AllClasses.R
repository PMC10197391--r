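#' @import methods
#' @importFrom stats cor sd median quantile rnorm runif optimize pt plogis
#'   qlogis setNames complete.cases pchisq dist
#' @importFrom utils read.table write.table write.csv combn head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

## ---------------------------------------------------------------------------
## PairwiseMatrix: labeled symmetric zero-diagonal matrix, the common currency
## for genetic / geographic / environmental distances.
## ---------------------------------------------------------------------------

#' Labeled symmetric pairwise distance matrix
#'
#' The common container for all pairwise quantities handled by the package:
#' genetic differentiation (Weir-Cockerham theta), straight-line / least-cost /
#' circuit geographic distances, and per-variable environmental distances.
#' The matrix is square, symmetric, zero on the diagonal and carries
#' population labels as dimnames. Genetic matrices may hold small negative
#' entries (unbiased FST estimates below zero are retained, not clamped).
#'
#' @slot mat numeric matrix, symmetric with zero diagonal and dimnames.
#' @slot kind character tag, one of `"genetic"`, `"geographic-euclidean"`,
#'   `"geographic-lcd"`, `"geographic-cd"` or `"environmental:<variable>"`.
#' @export
setClass("PairwiseMatrix", slots = c(mat = "matrix", kind = "character"))

setValidity("PairwiseMatrix", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix must carry population labels as dimnames")
  if (!identical(rownames(m), colnames(m)))
    return("row and column labels differ")
  if (anyDuplicated(rownames(m))) return("duplicated population labels")
  if (any(!is.finite(m))) return("non-finite entries")
  if (max(abs(m - t(m))) > 1e-8) return("matrix not symmetric")
  if (max(abs(diag(m))) > 1e-8) return("diagonal not zero")
  if (length(object@kind) != 1L) return("kind must be a single string")
  if (!startsWith(object@kind, "environmental") &&
      !object@kind %in% c("genetic", "geographic-euclidean",
                          "geographic-lcd", "geographic-cd", "generic"))
    return(sprintf("unknown kind '%s'", object@kind))
  if (startsWith(object@kind, "geographic") && min(m) < -1e-8)
    return("geographic distances must be non-negative")
  TRUE
})

#' Construct a PairwiseMatrix
#'
#' @param mat square numeric matrix (will be symmetrized at tolerance 1e-8
#'   and its diagonal zeroed).
#' @param kind kind tag (see [PairwiseMatrix-class]).
#' @param labels optional character vector of labels; defaults to existing
#'   dimnames.
#' @return a [PairwiseMatrix-class] object.
#' @export
PairwiseMatrix <- function(mat, kind = "generic", labels = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(labels)) dimnames(mat) <- list(labels, labels)
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  new("PairwiseMatrix", mat = mat, kind = kind)
}

#' @describeIn PairwiseMatrix-class number of populations
#' @param x,object a `PairwiseMatrix`
#' @export
setMethod("length", "PairwiseMatrix", function(x) nrow(x@mat))

#' @export
setMethod("as.matrix", "PairwiseMatrix", function(x, ...) x@mat)

#' Population labels of a pairwise matrix
#' @param x a [PairwiseMatrix-class]
#' @return character vector of population ids
#' @export
pwLabels <- function(x) rownames(x@mat)

#' Kind tag of a pairwise matrix
#' @param x a [PairwiseMatrix-class]
#' @return character tag
#' @export
pwKind <- function(x) x@kind

#' Lower-triangle values of a pairwise matrix
#'
#' Returns the n(n-1)/2 unique off-diagonal entries in column-major
#' lower-triangle order, the ordering used throughout for site-pair tables
#' and Mantel statistics.
#' @param x a [PairwiseMatrix-class] or plain symmetric matrix
#' @return numeric vector
#' @export
pwValues <- function(x) {
  m <- if (is(x, "PairwiseMatrix")) x@mat else as.matrix(x)
  m[lower.tri(m)]
}

setMethod("show", "PairwiseMatrix", function(object) {
  cat(sprintf("PairwiseMatrix [%s] over %d populations\n", object@kind,
              nrow(object@mat)))
  v <- pwValues(object)
  cat(sprintf("  off-diagonal range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
})

## ---------------------------------------------------------------------------
## SNPGenotypes: diploid dosage matrix with locus metadata, built on
## SummarizedExperiment (loci = rows, individuals = columns).
## ---------------------------------------------------------------------------

#' Diploid SNP genotypes as a SummarizedExperiment
#'
#' Container for biallelic diploid genotypes coded as alternate-allele dosage
#' (0, 1, 2, or `NA` for missing), with loci as rows and individuals as
#' columns. `rowData` carries the locus records (`chrom`, `pos`, `qual`,
#' `ref`, `alt`); `colData` carries `sample` and (optionally) `population`.
#'
#' @export
setClass("SNPGenotypes", contains = "SummarizedExperiment")

setValidity("SNPGenotypes", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% 0:2)) return("dosages must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos", "qual", "ref", "alt")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData needs columns:", paste(need, collapse = ", ")))
  if (any(rd$pos <= 0)) return("positions must be positive")
  if (anyDuplicated(colnames(object))) return("individual ids must be unique")
  TRUE
})

#' Construct an SNPGenotypes object
#'
#' @param dosage integer matrix (loci x individuals) of alt-allele dosages in
#'   \{0, 1, 2, NA\}.
#' @param loci data.frame with columns `chrom`, `pos`, `qual`, `ref`, `alt`
#'   (one row per locus).
#' @param samples character vector of individual ids, or data.frame with a
#'   `sample` column and optionally `population`.
#' @return an [SNPGenotypes-class] object.
#' @export
SNPGenotypes <- function(dosage, loci, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.character(samples)) samples <- data.frame(sample = samples)
  rownames(dosage) <- rownames(loci) <-
    paste(loci$chrom, loci$pos, sep = ":")
  colnames(dosage) <- samples$sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(loci),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample))
  new("SNPGenotypes", se)
}

#' Dosage matrix accessor
#' @param x an [SNPGenotypes-class]
#' @return integer matrix loci x individuals (NA = missing call)
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' Locus metadata accessor
#' @param x an [SNPGenotypes-class]
#' @return data.frame of locus records
#' @export
lociInfo <- function(x) as.data.frame(SummarizedExperiment::rowData(x))

#' Population assignment accessor
#' @param x an [SNPGenotypes-class]
#' @return named character vector (individual -> population), or NULL
#' @export
populations <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"population" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$population), rownames(cd))
}

setMethod("show", "SNPGenotypes", function(object) {
  d <- dosages(object)
  cat(sprintf("SNPGenotypes: %d loci x %d individuals (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  pops <- populations(object)
  if (!is.null(pops))
    cat(sprintf("  %d populations: %s\n", length(unique(pops)),
                paste(head(unique(pops), 6), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## GridRaster / ResistanceRaster / ClimateStack
## ---------------------------------------------------------------------------

#' Single-band gridded raster
#'
#' Minimal planar raster: a numeric matrix (row 1 = northern-most row, as in
#' ESRI ASCII grids), the lower-left corner of the grid, and a square cell
#' size in map units (meters for synthetic landscapes). `NA` cells are
#' nodata.
#'
#' @slot values numeric matrix (rows x cols); NA = nodata
#' @slot xll,yll numeric, lower-left corner coordinates
#' @slot cellsize numeric, cell edge length in map units
#' @export
setClass("GridRaster",
         slots = c(values = "matrix", xll = "numeric", yll = "numeric",
                   cellsize = "numeric"))

setValidity("GridRaster", function(object) {
  if (object@cellsize <= 0) return("cellsize must be positive")
  if (nrow(object@values) < 1 || ncol(object@values) < 1)
    return("empty raster")
  TRUE
})

#' Construct a GridRaster
#' @param values numeric matrix (row 1 = top of the map)
#' @param xll,yll lower-left corner (default 0, 0)
#' @param cellsize cell size in map units (default 1)
#' @return a [GridRaster-class]
#' @export
GridRaster <- function(values, xll = 0, yll = 0, cellsize = 1) {
  new("GridRaster", values = as.matrix(values), xll = xll, yll = yll,
      cellsize = cellsize)
}

#' @export
setMethod("dim", "GridRaster", function(x) dim(x@values))

#' Raster cell values
#' @param x a [GridRaster-class]
#' @return numeric matrix
#' @export
rasterValues <- function(x) x@values

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf("GridRaster %d x %d, cell %.6g, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), object@cellsize, object@xll, object@yll))
  cat(sprintf("  values in [%.4g, %.4g], %d nodata cells\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
})

#' Per-cell conductance raster for landscape connectivity
#'
#' A [GridRaster-class] whose values are per-cell conductances (> 0 on all
#' non-nodata cells), derived from habitat suitability via
#' [suitabilityToResistance()]. Resistance is the reciprocal of conductance.
#' @export
setClass("ResistanceRaster", contains = "GridRaster")

setValidity("ResistanceRaster", function(object) {
  v <- object@values
  if (any(v[!is.na(v)] <= 0)) return("conductance must be positive")
  TRUE
})

#' Co-registered stack of climate rasters
#'
#' One layer per climate predictor used by a generalized dissimilarity model,
#' all sharing grid geometry, plus a scenario tag (for example `"current"` or
#' `"future-SSP245-2081-2100"`).
#'
#' @slot layers named list of [GridRaster-class] objects
#' @slot scenario character scenario tag
#' @export
setClass("ClimateStack", slots = c(layers = "list", scenario = "character"))

setValidity("ClimateStack", function(object) {
  ly <- object@layers
  if (length(ly) < 1) return("at least one layer required")
  if (is.null(names(ly)) || any(names(ly) == ""))
    return("layers must be named")
  if (!all(vapply(ly, is, TRUE, "GridRaster")))
    return("all layers must be GridRaster objects")
  g <- vapply(ly, function(r)
    paste(nrow(r@values), ncol(r@values), r@xll, r@yll, r@cellsize), "")
  if (length(unique(g)) != 1) return("layers differ in grid geometry")
  TRUE
})

#' Construct a ClimateStack
#' @param layers named list of [GridRaster-class] layers
#' @param scenario scenario tag
#' @return a [ClimateStack-class]
#' @export
ClimateStack <- function(layers, scenario = "current") {
  new("ClimateStack", layers = layers, scenario = scenario)
}

setMethod("show", "ClimateStack", function(object) {
  cat(sprintf("ClimateStack [%s]: %d layers (%s)\n", object@scenario,
              length(object@layers),
              paste(names(object@layers), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' Generative truth of a synthetic landscape-genomics dataset
#'
#' Holds the population-by-locus allele-frequency matrix actually used to
#' draw genotypes, the realized between-population covariance of logit
#' frequencies, and the configuration, so recovery tests can compare
#' estimates against known targets.
#'
#' @slot freqs numeric matrix (populations x loci), entries strictly in (0,1)
#' @slot covariance realized covariance of population logit frequencies
#' @slot config the generating configuration list
#' @export
setClass("SyntheticTruth",
         slots = c(freqs = "matrix", covariance = "matrix", config = "list"))

setValidity("SyntheticTruth", function(object) {
  f <- object@freqs
  if (any(f <= 0 | f >= 1)) return("frequencies must lie strictly in (0,1)")
  S <- object@covariance
  if (max(abs(S - t(S))) > 1e-8) return("covariance not symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    return("covariance not positive semi-definite")
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d populations x %d loci\n",
              nrow(object@freqs), ncol(object@freqs)))
})

## ---------------------------------------------------------------------------
## MantelResult / RCMHeatmap
## ---------------------------------------------------------------------------

#' Result of a (partial) Mantel permutation test
#'
#' @slot statistic Mantel correlation (or partial-Mantel R) of off-diagonal
#'   entries
#' @slot p.value two-sided permutation p-value with the +1 correction
#' @slot nPerm number of permutations (0 when exact enumeration was used)
#' @slot method correlation method, `"spearman"` or `"pearson"`
#' @slot partial logical, whether a third matrix was partialled out
#' @slot seed integer seed used for the permutation stream (NA if exact)
#' @export
setClass("MantelResult",
         slots = c(statistic = "numeric", p.value = "numeric",
                   nPerm = "numeric", method = "character",
                   partial = "logical", seed = "numeric"))

setValidity("MantelResult", function(object) {
  p <- object@p.value
  if (!is.na(p) && (p <= 0 || p > 1)) return("p must lie in (0, 1]")
  TRUE
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("%sMantel (%s): r = %.4f, p = %.4g (%s permutations)\n",
              if (object@partial) "partial " else "", object@method,
              object@statistic, object@p.value,
              if (object@nPerm == 0) "exhaustive" else object@nPerm))
})

#' Reciprocal causal modeling summary
#'
#' For every unordered pair of candidate distance matrices \{A, B\}, the
#' difference of reciprocal partial-Mantel statistics
#' D\[A, B\] = R_PM(G ~ A | B) - R_PM(G ~ B | A). Positive rows identify
#' better-supported drivers of genetic distance.
#'
#' @slot delta antisymmetric matrix of R_PM differences
#' @slot rpm matrix of underlying partial-Mantel statistics; `rpm[A, B]` is
#'   R_PM of genetic distance against A controlling for B
#' @slot pvalues permutation p-values companion to `rpm`
#' @slot nPerm permutations per partial test
#' @slot nTests number of partial-Mantel evaluations performed
#' @export
setClass("RCMHeatmap",
         slots = c(delta = "matrix", rpm = "matrix", pvalues = "matrix",
                   nPerm = "numeric", nTests = "numeric"))

setValidity("RCMHeatmap", function(object) {
  D <- object@delta
  s <- abs(D + t(D))
  if (any(is.finite(s) & s > 1e-8)) return("delta must be antisymmetric")
  if (max(abs(diag(D))) > 1e-12) return("delta diagonal must be zero")
  TRUE
})

setMethod("show", "RCMHeatmap", function(object) {
  cat(sprintf("RCMHeatmap: %d variables, %d reciprocal models, %d partial tests\n",
              nrow(object@delta), choose(nrow(object@delta), 2),
              object@nTests))
})

## ---------------------------------------------------------------------------
## GDMModel / MLPEFit
## ---------------------------------------------------------------------------

#' Fitted generalized dissimilarity model
#'
#' Monotone (I-spline) matrix regression of pairwise genetic dissimilarity on
#' environmental differences and geographic distance, with link
#' mu = 1 - exp(-eta) and non-negative coefficients.
#'
#' @slot predictors predictor names in model order
#' @slot knots named list; per predictor the I-spline knots (min/median/max of
#'   observed values)
#' @slot intercept non-negative intercept
#' @slot coefficients named list of non-negative spline coefficient vectors
#' @slot nullDeviance deviance of the best intercept-only model
#' @slot residDeviance residual deviance at the fit
#' @slot explained percent deviance explained
#' @slot converged logical convergence flag
#' @slot sitePairs the site-pair table the model was fitted to
#' @export
setClass("GDMModel",
         slots = c(predictors = "character", knots = "list",
                   intercept = "numeric", coefficients = "list",
                   nullDeviance = "numeric", residDeviance = "numeric",
                   explained = "numeric", converged = "logical",
                   sitePairs = "data.frame"))

setValidity("GDMModel", function(object) {
  if (object@intercept < 0) return("intercept must be non-negative")
  if (any(unlist(object@coefficients) < 0))
    return("spline coefficients must be non-negative")
  TRUE
})

setMethod("show", "GDMModel", function(object) {
  cat(sprintf("GDMModel: %d predictors, %.1f%% deviance explained%s\n",
              length(object@predictors), object@explained,
              if (object@converged) "" else " (NOT converged)"))
  h <- vapply(object@coefficients, sum, 0)
  for (k in order(h, decreasing = TRUE))
    cat(sprintf("  %-14s spline height %.4f\n", object@predictors[k],
                h[k]))
})

#' Fitted MLPE pairwise mixed model
#'
#' Maximum-likelihood fit of y_ij = b0 + b1 x_ij + u_i + u_j + e_ij over the
#' n(n-1)/2 population pairs, with a random effect per population entering
#' each pair (the maximum-likelihood-population-effects correction for
#' non-independence of pairwise data).
#'
#' @slot beta numeric(2): intercept and slope on the standardized predictor
#' @slot sigmaU2 population random-effect variance (>= 0)
#' @slot sigmaE2 residual variance (> 0)
#' @slot rho equivalent MLPE correlation sigmaU2 / (sigmaU2 + sigmaE2)
#' @slot logLik maximized log-likelihood (ML, not REML)
#' @slot aic -2 logLik + 2k with k = 4 parameters
#' @slot m number of pairs; @slot n number of populations
#' @slot atBound TRUE when the variance-ratio optimizer stopped at a bound
#' @slot predictor predictor label
#' @export
setClass("MLPEFit",
         slots = c(beta = "numeric", sigmaU2 = "numeric", sigmaE2 = "numeric",
                   rho = "numeric", logLik = "numeric", aic = "numeric",
                   m = "numeric", n = "numeric", atBound = "logical",
                   predictor = "character"))

setValidity("MLPEFit", function(object) {
  if (object@sigmaU2 < 0 || object@sigmaE2 <= 0)
    return("variances out of range")
  if (!is.finite(object@aic)) return("AIC must be finite")
  TRUE
})

setMethod("show", "MLPEFit", function(object) {
  cat(sprintf(
    "MLPEFit [%s]: beta1 = %.4f, sigmaU2 = %.4g, sigmaE2 = %.4g, AIC = %.2f%s\n",
    object@predictor, object@beta[2], object@sigmaU2, object@sigmaE2,
    object@aic, if (object@atBound) " (variance ratio at bound)" else ""))
})
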