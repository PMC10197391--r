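#' Read diploid biallelic genotypes from a VCF file
#'
#' Parses the GT field into alternate-allele dosages. Multi-allelic records
#' and half-calls (for example `./1`) are dropped with a reported count;
#' phased separators are accepted.
#'
#' @param path VCF 4.x file path (plain text or gzipped)
#' @param popAssignment optional named character vector or data.frame
#'   (`sample`, `population`) attaching populations to individuals
#' @return an [SNPGenotypes-class]
#' @export
readVCF <- function(path, popAssignment = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  if (!"GT" %in% unique(unlist(strsplit(v@gt[, "FORMAT"], ":"))))
    stop("VCF has no GT field")
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) |
    nchar(fix[, "REF"]) != 1 | nchar(fix[, "ALT"]) != 1
  nMulti <- sum(multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  nHalf <- sum(!known)
  keep <- !multi
  if (!any(keep)) stop("zero biallelic SNP records retained")
  loci <- data.frame(chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     qual = as.numeric(fix[keep, "QUAL"]),
                     ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(popAssignment)) {
    if (is.data.frame(popAssignment))
      popAssignment <- setNames(as.character(popAssignment$population),
                                popAssignment$sample)
    samples$population <- unname(popAssignment[samples$sample])
    if (anyNA(samples$population))
      stop("population assignment missing for some individuals")
  }
  gm <- SNPGenotypes(code[keep, , drop = FALSE], loci, samples)
  if (nMulti + nHalf > 0)
    message(sprintf("readVCF: dropped %d non-biallelic records, %d half-calls set missing",
                    nMulti, nHalf))
  S4Vectors::metadata(gm)$dropped <- c(multiallelic = nMulti,
                                       halfcalls = nHalf)
  gm
}

#' Filter SNPs on quality, minor-allele frequency and call rate
#'
#' Mirrors the conventional VCF filtering thresholds: site QUAL at least
#' `minQual`, minor-allele frequency (computed on non-missing calls) at
#' least `minMaf`, and proportion of called genotypes at least `maxMissing`
#' (the threshold is a minimum call rate, the convention of the usual
#' command-line tool). Per-filter attrition counts are stored in the result
#' metadata.
#'
#' @param gm an [SNPGenotypes-class]
#' @param minQual minimum site QUAL (default 30)
#' @param minMaf minimum minor-allele frequency (default 0.01)
#' @param maxMissing minimum call rate in \[0,1\] (default 0.7)
#' @return filtered [SNPGenotypes-class]
#' @export
filterSNPs <- function(gm, minQual = 30, minMaf = 0.01, maxMissing = 0.7) {
  d <- dosages(gm)
  li <- lociInfo(gm)
  called <- rowSums(!is.na(d))
  callRate <- called / ncol(d)
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(p, 1 - p)
  passQ <- !is.na(li$qual) & li$qual >= minQual
  passM <- called > 0 & maf >= minMaf
  passC <- callRate >= maxMissing
  keep <- passQ & passM & passC
  log <- c(input = nrow(d), failQual = sum(!passQ), failMaf = sum(!passM),
           failCallRate = sum(!passC), retained = sum(keep))
  if (!any(keep))
    stop(sprintf(
      "all loci removed (QUAL: %d failed, MAF: %d failed, call rate: %d failed)",
      log["failQual"], log["failMaf"], log["failCallRate"]))
  out <- gm[keep, ]
  S4Vectors::metadata(out)$filterLog <- log
  out
}

# population assignment resolved from argument or colData
.popAssign <- function(gm, popAssignment = NULL) {
  if (is.null(popAssignment)) popAssignment <- populations(gm)
  if (is.null(popAssignment))
    stop("no population assignment available")
  if (is.data.frame(popAssignment))
    popAssignment <- setNames(as.character(popAssignment$population),
                              popAssignment$sample)
  pops <- popAssignment[colnames(gm)]
  if (anyNA(pops)) stop("individuals without population assignment")
  pops
}

# per-population per-locus summaries: called genotypes, alt-allele
# frequency, observed heterozygote fraction. Returned as loci x pops mats.
.popLocusSummaries <- function(d, pops) {
  upops <- unique(pops)
  nMat <- pMat <- hMat <- matrix(NA_real_, nrow(d), length(upops),
                                 dimnames = list(NULL, upops))
  for (g in upops) {
    dg <- d[, pops == g, drop = FALSE]
    called <- rowSums(!is.na(dg))
    nMat[, g] <- called
    pMat[, g] <- ifelse(called > 0, rowSums(dg, na.rm = TRUE) / (2 * called),
                        NA_real_)
    hMat[, g] <- ifelse(called > 0, rowSums(dg == 1L, na.rm = TRUE) / called,
                        NA_real_)
  }
  list(n = nMat, p = pMat, h = hMat, pops = upops)
}

#' Per-population genetic diversity
#'
#' Computes, per population over loci with at least one called genotype:
#' observed heterozygosity Ho (heterozygous calls / called genotypes,
#' averaged over loci), unbiased expected heterozygosity
#' He = (n_g / (n_g - 1)) (1 - p^2 - q^2) with n_g called gene copies,
#' averaged over loci; nucleotide diversity pi at the retained SNP sites
#' (per-site unbiased heterozygosity, reported separately for interface
#' parity); and the multilocus inbreeding coefficient
#' Fis = 1 - mean(Ho) / mean(He).
#'
#' @param gm an [SNPGenotypes-class]
#' @param popAssignment optional assignment (defaults to `colData`)
#' @param perLocusFis also return the mean of per-locus Fis values
#' @return data.frame with columns `pop`, `nInd`, `nLoci`, `Ho`, `He`, `pi`,
#'   `Fis` (NA-flagged where undefined)
#' @export
populationDiversity <- function(gm, popAssignment = NULL,
                                perLocusFis = FALSE) {
  d <- dosages(gm)
  pops <- .popAssign(gm, popAssignment)
  s <- .popLocusSummaries(d, pops)
  out <- lapply(s$pops, function(g) {
    use <- !is.na(s$n[, g]) & s$n[, g] > 0
    if (!any(use))
      return(data.frame(pop = g, nInd = sum(pops == g), nLoci = 0L,
                        Ho = NA_real_, He = NA_real_, pi = NA_real_,
                        Fis = NA_real_))
    ng <- 2 * s$n[use, g]
    p <- s$p[use, g]
    he <- ifelse(ng > 1, ng / (ng - 1) * (1 - p^2 - (1 - p)^2), NA_real_)
    ho <- s$h[use, g]
    mHo <- mean(ho, na.rm = TRUE)
    mHe <- mean(he, na.rm = TRUE)
    fis <- if (is.finite(mHe) && mHe > 0) 1 - mHo / mHe else NA_real_
    data.frame(pop = g, nInd = sum(pops == g), nLoci = sum(use),
               Ho = mHo, He = mHe, pi = mHe, Fis = fis)
  })
  res <- do.call(rbind, out)
  if (perLocusFis) {
    res$FisPerLocus <- vapply(s$pops, function(g) {
      use <- !is.na(s$n[, g]) & s$n[, g] > 0
      ng <- 2 * s$n[use, g]
      p <- s$p[use, g]
      he <- ng / (ng - 1) * (1 - p^2 - (1 - p)^2)
      f <- 1 - s$h[use, g] / he
      mean(f[is.finite(f) & he > 0])
    }, 0)
  }
  rownames(res) <- NULL
  res
}

#' Chi-square test of observed versus Hardy-Weinberg heterozygosity
#'
#' Per population, genotype calls are pooled over loci: the observed
#' heterozygote count is compared with the Hardy-Weinberg expected count
#' (per-locus 2pq times called genotypes, summed) by a 1-df chi-square on
#' the heterozygote/homozygote partition.
#'
#' @param gm an [SNPGenotypes-class]
#' @param popAssignment optional assignment
#' @return data.frame with `pop`, `observedHet`, `expectedHet`,
#'   `totalCalls`, `chi2`, `p` (NA-flagged when the expectation is
#'   degenerate)
#' @export
hoHeChi2 <- function(gm, popAssignment = NULL) {
  d <- dosages(gm)
  pops <- .popAssign(gm, popAssignment)
  s <- .popLocusSummaries(d, pops)
  out <- lapply(s$pops, function(g) {
    use <- !is.na(s$n[, g]) & s$n[, g] > 0
    nCalls <- sum(s$n[use, g])
    oHet <- sum(s$h[use, g] * s$n[use, g])
    p <- s$p[use, g]
    eHet <- sum(2 * p * (1 - p) * s$n[use, g])
    if (nCalls == 0 || eHet <= 0 || eHet >= nCalls)
      return(data.frame(pop = g, observedHet = oHet, expectedHet = eHet,
                        totalCalls = nCalls, chi2 = NA_real_, p = NA_real_))
    chi2 <- (oHet - eHet)^2 / eHet + (oHet - eHet)^2 / (nCalls - eHet)
    data.frame(pop = g, observedHet = oHet, expectedHet = eHet,
               totalCalls = nCalls, chi2 = chi2,
               p = pchisq(chi2, df = 1, lower.tail = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# two-population Weir-Cockerham variance components, vectorized over loci.
# n1/n2 called genotypes, p1/p2 alt frequencies, h1/h2 observed het
# fractions. Returns per-locus a, b, c (NA at uninformative loci).
.wcComponents <- function(n1, p1, h1, n2, p2, h2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- b[!ok] <- cc[!ok] <- NA_real_
  list(a = unname(a), b = unname(b), c = unname(cc))
}

#' Pairwise Weir-Cockerham FST between two populations
#'
#' Computes per-locus variance components a (among populations), b (among
#' individuals within populations) and c (within individuals) from the
#' two-population Weir & Cockerham (1984) estimator, and aggregates them as
#' the ratio estimator theta = sum(a) / sum(a + b + c) (weighted variant)
#' together with the mean of per-locus ratios.
#'
#' @param gm an [SNPGenotypes-class]
#' @param popA,popB population labels
#' @param popAssignment optional assignment
#' @return list with per-locus `a`, `b`, `c`, `thetaWeighted`, `thetaMean`,
#'   and `nLoci` (informative loci used)
#' @export
wcFstPair <- function(gm, popA, popB, popAssignment = NULL) {
  d <- dosages(gm)
  pops <- .popAssign(gm, popAssignment)
  if (!popA %in% pops || !popB %in% pops)
    stop("unknown population label")
  sel <- pops %in% c(popA, popB)
  s <- .popLocusSummaries(d[, sel, drop = FALSE], pops[sel])
  comp <- .wcComponents(s$n[, popA], s$p[, popA], s$h[, popA],
                        s$n[, popB], s$p[, popB], s$h[, popB])
  .aggregateTheta(comp)
}

.aggregateTheta <- function(comp) {
  a <- comp$a; b <- comp$b; cc <- comp$c
  ok <- is.finite(a) & is.finite(b) & is.finite(cc)
  if (!any(ok)) stop("no shared informative loci between the populations")
  tot <- a[ok] + b[ok] + cc[ok]
  thetaW <- if (sum(tot) > 0) sum(a[ok]) / sum(tot) else NA_real_
  perLocus <- a[ok][tot != 0] / tot[tot != 0]
  thetaM <- if (length(perLocus)) mean(perLocus) else NA_real_
  clamp <- function(x) if (is.na(x)) x else min(max(x, -1), 1)
  list(a = a, b = b, c = cc, thetaWeighted = clamp(thetaW),
       thetaMean = clamp(thetaM), nLoci = sum(ok))
}

#' Pairwise FST matrix over all populations
#'
#' Symmetric zero-diagonal matrix of pairwise Weir-Cockerham theta
#' (weighted ratio estimator by default). Negative estimates are retained,
#' not clamped; their count is attached as an attribute.
#'
#' @param gm an [SNPGenotypes-class]
#' @param popAssignment optional assignment
#' @param variant `"weighted"` (sum-ratio, default) or `"mean"` (mean of
#'   per-locus ratios)
#' @return a [PairwiseMatrix-class] of kind `"genetic"`, with attribute
#'   `nNegative`
#' @export
fstMatrix <- function(gm, popAssignment = NULL,
                      variant = c("weighted", "mean")) {
  variant <- match.arg(variant)
  d <- dosages(gm)
  pops <- .popAssign(gm, popAssignment)
  s <- .popLocusSummaries(d, pops)
  k <- length(s$pops)
  if (k < 2) stop("at least two populations required")
  m <- matrix(0, k, k, dimnames = list(s$pops, s$pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    comp <- .wcComponents(s$n[, i], s$p[, i], s$h[, i],
                          s$n[, j], s$p[, j], s$h[, j])
    th <- .aggregateTheta(comp)
    m[i, j] <- m[j, i] <-
      if (variant == "weighted") th$thetaWeighted else th$thetaMean
  }
  if (any(!is.finite(m))) stop("non-finite FST estimates")
  pm <- PairwiseMatrix(m, kind = "genetic")
  attr(pm@mat, "nNegative") <- sum(pwValues(pm) < 0)
  pm
}

#' Pearson correlations between diversity statistics and environment
#'
#' For each environmental variable and each diversity statistic, the Pearson
#' correlation r across populations, t = |r| sqrt(df / (1 - r^2)) with
#' df = n - 2, and the two-sided p from the t distribution.
#'
#' @param diversity data.frame from [populationDiversity()]
#' @param envTable matrix or data.frame of per-population environmental
#'   values (rows aligned by population label)
#' @param stats which diversity columns to correlate
#' @return data.frame with `variable`, `statistic`, `r`, `t`, `p`, `df`
#' @export
diversityEnvCorrelation <- function(diversity, envTable,
                                    stats = c("Ho", "He", "pi", "Fis")) {
  env <- as.matrix(as.data.frame(envTable)[, , drop = FALSE])
  if (!is.null(rownames(env)) && all(diversity$pop %in% rownames(env)))
    env <- env[diversity$pop, , drop = FALSE]
  if (nrow(env) != nrow(diversity))
    stop("environmental table not aligned with diversity summary")
  if (nrow(diversity) < 3) stop("at least three populations required")
  rows <- list()
  for (v in colnames(env)) for (st in stats) {
    x <- diversity[[st]]; y <- env[, v]
    ok <- is.finite(x) & is.finite(y)
    df <- sum(ok) - 2
    if (df < 1 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      rows[[length(rows) + 1]] <-
        data.frame(variable = v, statistic = st, r = NA_real_,
                   t = NA_real_, p = NA_real_, df = df)
      next
    }
    r <- cor(x[ok], y[ok])
    t <- abs(r) * sqrt(df / (1 - r^2))
    rows[[length(rows) + 1]] <-
      data.frame(variable = v, statistic = st, r = r, t = t,
                 p = 2 * pt(-t, df), df = df)
  }
  do.call(rbind, rows)
}
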