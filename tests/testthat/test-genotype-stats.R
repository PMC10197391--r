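vcfLines <- function(records, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("VCF parsing maps GT codes and drops non-biallelic records", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcfLines(c(
    "1\t100\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/0",
    "1\t200\t.\tG\tT\t40\tPASS\t.\tGT\t./.\t1|1",
    "1\t300\t.\tA\tC,G\t60\tPASS\t.\tGT\t0/1\t0/2",   # multi-allelic
    "1\t400\t.\tT\tA\t45\tPASS\t.\tGT\t./1\t0/0")),   # half-call
    f)
  gm <- suppressMessages(readVCF(f))
  d <- dosages(gm)
  expect_equal(nrow(d), 3)                 # multi-allelic dropped
  expect_equal(unname(d[1, ]), c(1L, 0L))
  expect_equal(unname(d[2, ]), c(NA_integer_, 2L))  # ./. and phased 1|1
  expect_equal(unname(d[3, ]), c(NA_integer_, 0L))  # half-call -> missing
  expect_equal(unname(S4Vectors::metadata(gm)$dropped[["multiallelic"]]), 1)
})

test_that("SNP filtering applies QUAL, MAF and call-rate thresholds", {
  # 5 loci x 10 individuals: one fails each filter, two pass
  d <- matrix(1L, 5, 10)
  d[1, ] <- c(rep(0L, 9), 1L)          # maf 0.05, passes
  d[2, ] <- rep(c(0L, 2L), 5)          # passes
  d[3, ] <- rep(0L, 10); d[3, 1] <- 1L # maf 0.05 but QUAL fails
  d[4, ] <- c(1L, rep(0L, 9))          # call-rate fails below
  d[4, 5:10] <- NA_integer_            # call rate 0.4
  d[5, ] <- rep(0L, 10)                # monomorphic: maf 0 fails
  gm <- makeGM(d, qual = c(50, 50, 20, 50, 50))
  out <- filterSNPs(gm, minQual = 30, minMaf = 0.01, maxMissing = 0.7)
  expect_equal(nrow(dosages(out)), 2)
  log <- S4Vectors::metadata(out)$filterLog
  expect_equal(unname(log[c("failQual", "failMaf", "failCallRate")]),
               c(1, 1, 1))
  # zero thresholds are the identity
  expect_equal(nrow(dosages(filterSNPs(gm, 0, 0, 0))), 5)
  expect_error(filterSNPs(gm, minQual = 1000), "all loci removed")
})

test_that("diversity formulas match closed-form small cases", {
  # one locus, 10 individuals, all heterozygous
  gm <- makeGM(matrix(1L, 1, 10), pops = rep("A", 10))
  div <- populationDiversity(gm)
  expect_equal(div$Ho, 1)
  expect_equal(div$He, 20 / 19 * 0.5, tolerance = 1e-12)
  expect_equal(div$Fis, 1 - 1 / (20 / 19 * 0.5), tolerance = 1e-12)
  expect_equal(div$Fis, -0.9, tolerance = 1e-3)
  # monomorphic population: zero diversity, Fis flagged undefined
  gm0 <- makeGM(matrix(0L, 4, 6), pops = rep("A", 6))
  div0 <- populationDiversity(gm0)
  expect_equal(div0$Ho, 0)
  expect_equal(div0$He, 0)
  expect_equal(div0$pi, 0)
  expect_true(is.na(div0$Fis))
})

test_that("multilocus Fis estimate recovers the generative F", {
  set.seed(31)
  p <- runif(5000, 0.1, 0.9)
  F <- 0.3
  nInd <- 40
  probs <- cbind((1 - p)^2 + F * p * (1 - p),
                 2 * p * (1 - p) * (1 - F),
                 p^2 + F * p * (1 - p))
  d <- t(vapply(seq_along(p), function(l)
    sample(0:2, nInd, TRUE, prob = probs[l, ]), integer(nInd)))
  gm <- makeGM(d, pops = rep("A", nInd))
  div <- populationDiversity(gm)
  expect_lt(abs(div$Fis - F), 0.03)
})

test_that("Ho-vs-He chi-square matches hand arithmetic and HW identity", {
  # exact Hardy-Weinberg counts: 25 / 50 / 25 -> chi2 = 0, p = 1
  d <- matrix(rep(c(0L, 1L, 2L), c(25, 50, 25)), ncol = 100, nrow = 1)
  gm <- makeGM(d, pops = rep("A", 100))
  res <- hoHeChi2(gm)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # 100 calls, 20 het observed vs 50 expected -> chi2 = 900/50 + 900/50
  d2 <- matrix(rep(c(0L, 1L, 2L), c(40, 20, 40)), ncol = 100, nrow = 1)
  gm2 <- makeGM(d2, pops = rep("A", 100))
  res2 <- hoHeChi2(gm2)
  expect_equal(res2$expectedHet, 50)
  expect_equal(res2$observedHet, 20)
  expect_equal(res2$chi2, 36, tolerance = 1e-12)
  # monomorphic pool: expectation degenerate, test flagged
  gm3 <- makeGM(matrix(0L, 2, 10), pops = rep("A", 10))
  expect_true(is.na(hoHeChi2(gm3)$chi2))
})

test_that("chi-square rejection rate is calibrated under F = 0", {
  rej <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    p <- runif(200, 0.2, 0.8)
    d <- t(vapply(p, function(pp)
      sample(0:2, 30, TRUE, prob = c((1 - pp)^2, 2 * pp * (1 - pp), pp^2)),
      integer(30)))
    gm <- makeGM(d, pops = rep("A", 30))
    if (hoHeChi2(gm)$p <= 0.05) rej <- rej + 1L
  }
  expect_lte(rej / 20, 0.15)
})

test_that("Weir-Cockerham pair estimator matches closed forms", {
  # fixed difference -> theta = 1
  d <- cbind(matrix(0L, 1, 10), matrix(2L, 1, 10))
  gm <- makeGM(d, pops = rep(c("A", "B"), each = 10))
  expect_equal(wcFstPair(gm, "A", "B")$thetaWeighted, 1)
  # both populations 5 hom-ref / 0 het / 5 hom-alt: hand-evaluated
  # components a = -1/36, b = 5/18, c = 0 -> theta = -1/9
  d2 <- cbind(matrix(rep(c(0L, 2L), each = 5), 1, 10),
              matrix(rep(c(0L, 2L), each = 5), 1, 10))
  gm2 <- makeGM(d2, pops = rep(c("A", "B"), each = 10))
  th <- wcFstPair(gm2, "A", "B")
  expect_equal(th$a, -0.25 / 9, tolerance = 1e-12)
  expect_equal(th$b, 2.5 / 9, tolerance = 1e-12)
  expect_equal(th$c, 0)
  expect_equal(th$thetaWeighted, -1 / 9, tolerance = 1e-12)
})

test_that("theta is invariant to population order and allele relabeling", {
  set.seed(12)
  d <- matrix(sample(c(0:2, NA), 200 * 16, TRUE, prob = c(4, 3, 3, 1)),
              200, 16)
  pops <- rep(c("A", "B"), each = 8)
  gm <- makeGM(d, pops = pops)
  t1 <- wcFstPair(gm, "A", "B")
  t2 <- wcFstPair(gm, "B", "A")
  expect_equal(t1$thetaWeighted, t2$thetaWeighted, tolerance = 1e-12)
  gmFlip <- makeGM(2L - d, pops = pops)  # global ref/alt flip
  t3 <- wcFstPair(gmFlip, "A", "B")
  expect_equal(t1$thetaWeighted, t3$thetaWeighted, tolerance = 1e-12)
  expect_equal(t1$a, t3$a, tolerance = 1e-12)
})

test_that("per-locus components match the nested-ANOVA oracle", {
  set.seed(42)
  for (i in 1:30) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    yA <- sample(0:2, n1, TRUE); yB <- sample(0:2, n2, TRUE)
    o <- wcOracleComponents(yA, yB)
    cmp <- landgen:::.wcComponents(n1, mean(yA) / 2, mean(yA == 1),
                                   n2, mean(yB) / 2, mean(yB == 1))
    expect_equal(c(cmp$a, cmp$b, cmp$c), unname(o), tolerance = 1e-12)
  }
})

test_that("FST matrix is symmetric, labeled and pairwise-consistent", {
  set.seed(13)
  d <- matrix(sample(0:2, 300 * 20, TRUE), 300, 20)
  pops <- rep(c("N", "S", "E", "W"), each = 5)
  gm <- makeGM(d, pops = pops)
  fm <- fstMatrix(gm)
  expect_s4_class(fm, "PairwiseMatrix")
  expect_equal(pwKind(fm), "genetic")
  m <- as.matrix(fm)
  expect_equal(m["N", "S"], wcFstPair(gm, "N", "S")$thetaWeighted,
               tolerance = 1e-12)
  expect_equal(m, t(m))
  # relabeling the populations permutes rows/columns consistently
  reord <- c("W", "E", "N", "S")
  gm2 <- makeGM(d[, order(match(pops, reord))],
                pops = sort(factor(pops, levels = reord)))
  m2 <- as.matrix(fstMatrix(gm2))
  expect_equal(m2[c("N", "S", "E", "W"), c("N", "S", "E", "W")], m,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("heterozygosity estimates stay in [0, 1] across random runs", {
  for (s in 1:10) {
    ds <- syntheticDataset(syntheticConfig(
      seed = 700 + s, nPops = 5, nIndPerPop = 3, nLoci = 80,
      inbreedingF = runif(1), missingRate = runif(1, 0, 0.4)))
    div <- populationDiversity(ds$genotypes)
    expect_true(all(div$Ho >= 0 & div$Ho <= 1))
    expect_true(all(div$He >= 0 & div$He <= 1))
    expect_true(all(is.na(div$Fis) | (div$Fis >= -1 & div$Fis <= 1)))
  }
})

test_that("diversity-environment correlation follows the t formula", {
  # the t statistic implied by r at 19 degrees of freedom; the printed
  # table's Ho row (r = -0.473 -> t = 2.338) is reproduced, and the same
  # formula gives 3.30 (not 10.871) for r = 0.603, which the package
  # follows consistently
  tOf <- function(r, df) abs(r) * sqrt(df / (1 - r^2))
  expect_equal(tOf(-0.473, 19), 2.338, tolerance = 5e-3)
  expect_equal(tOf(0.603, 19), 3.2955, tolerance = 5e-4)
  set.seed(5)
  div <- data.frame(pop = sprintf("P%02d", 1:21), nInd = 4, nLoci = 100,
                    Ho = runif(21, 0.1, 0.4), He = runif(21, 0.3, 0.6),
                    pi = runif(21, 0.05, 0.12), Fis = runif(21, 0, 0.6))
  env <- matrix(rnorm(42), 21, 2, dimnames = list(div$pop, c("e1", "e2")))
  tab <- diversityEnvCorrelation(div, env)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$df == 19))
  row <- tab[tab$variable == "e1" & tab$statistic == "Ho", ]
  expect_equal(row$r, cor(div$Ho, env[, "e1"]), tolerance = 1e-12)
  expect_equal(row$t, tOf(row$r, 19), tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-row$t, 19), tolerance = 1e-12)
  # perfectly collinear vectors: r = 1, p -> 0
  divC <- div; envC <- env; envC[, "e1"] <- div$Ho
  rowC <- diversityEnvCorrelation(divC, envC)
  rowC <- rowC[rowC$variable == "e1" & rowC$statistic == "Ho", ]
  expect_equal(rowC$r, 1)
  expect_equal(rowC$p, 0)
})
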