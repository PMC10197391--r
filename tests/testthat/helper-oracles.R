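# Independent oracles and small fixture builders used across the suite.

# Weir-Cockerham two-population variance components by the nested-ANOVA
# route (gamete / individual / population mean squares), an algebraically
# independent path from the package's direct moment formulas.
wcOracleComponents <- function(yA, yB) {
  yA <- yA[!is.na(yA)]; yB <- yB[!is.na(yB)]
  n1 <- length(yA); n2 <- length(yB); nt <- n1 + n2
  p1 <- sum(yA) / (2 * n1); p2 <- sum(yB) / (2 * n2)
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * nt)
  SSG <- (sum(yA == 1) + sum(yB == 1)) / 2
  SSI <- 2 * (sum((yA / 2 - p1)^2) + sum((yB / 2 - p2)^2))
  SSP <- 2 * (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)
  MSG <- SSG / nt
  MSI <- SSI / (nt - 2)
  MSP <- SSP / 1
  nc <- nt - (n1^2 + n2^2) / nt
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# all permutations of 1..n by simple recursion (independent of the
# package's generator)
oraclePerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oraclePerms(n - 1L)) for (k in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

# exhaustive Mantel permutation p-value via direct cor() on permuted
# matrices
mantelOracleExact <- function(a, b, method) {
  lo <- lower.tri(a)
  robs <- cor(a[lo], b[lo], method = method)
  rs <- vapply(oraclePerms(nrow(a)), function(p)
    cor(a[p, p][lo], b[lo], method = method), 0)
  list(r = robs, p = mean(abs(rs) >= abs(robs) - 1e-12))
}

# minimum-cost path on a small resistance grid by exhaustive DFS over all
# simple paths (8-neighbor moves, mean-resistance edge costs)
lcdOracle <- function(v, cellsize, from, to) {
  nr <- nrow(v); nc <- ncol(v)
  best <- Inf
  moves <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  dfs <- function(cell, visited, cost) {
    if (cost >= best) return(invisible())
    if (all(cell == to)) { best <<- cost; return(invisible()) }
    for (m in seq_len(nrow(moves))) {
      nxt <- cell + moves[m, ]
      if (nxt[1] < 1 || nxt[1] > nr || nxt[2] < 1 || nxt[2] > nc) next
      key <- (nxt[1] - 1) * nc + nxt[2]
      if (visited[key] || is.na(v[nxt[1], nxt[2]])) next
      fac <- if (all(moves[m, ] != 0)) sqrt(2) else 1
      step <- (1 / v[cell[1], cell[2]] + 1 / v[nxt[1], nxt[2]]) / 2 *
        cellsize * fac
      visited[key] <- TRUE
      dfs(nxt, visited, cost + step)
      visited[key] <- FALSE
    }
  }
  visited <- rep(FALSE, nr * nc)
  visited[(from[1] - 1) * nc + from[2]] <- TRUE
  dfs(from, visited, 0)
  best
}

# labeled symmetric matrix from a lower-triangle vector (column-major)
pwFromVec <- function(vec, labs, kind = "generic") {
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  m[lower.tri(m)] <- vec
  m <- m + t(m)
  PairwiseMatrix(m, kind = kind)
}

randDistMatrix <- function(n, seed, labs = sprintf("P%02d", seq_len(n))) {
  set.seed(seed)
  m <- as.matrix(dist(matrix(rnorm(2 * n), n)))
  dimnames(m) <- list(labs, labs)
  PairwiseMatrix(m, kind = "generic")
}

# genotype container from a dosage matrix (loci x individuals)
makeGM <- function(dosage, qual = NULL, pops = NULL) {
  nl <- nrow(dosage); ni <- ncol(dosage)
  if (is.null(qual)) qual <- rep(50, nl)
  loci <- data.frame(chrom = "1", pos = seq_len(nl) * 10L, qual = qual,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("ind%03d", seq_len(ni)),
                        stringsAsFactors = FALSE)
  if (!is.null(pops)) samples$population <- pops
  SNPGenotypes(dosage, loci, samples)
}

# orthonormal columns spanning centered vectors of length m, used to build
# off-diagonal vectors with exact sample correlations
orthoBasis <- function(m, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(m * k), m, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  qr.Q(qr(X))[, seq_len(k)]
}
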