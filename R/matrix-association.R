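# transform an off-diagonal vector for the chosen correlation method
.assocTransform <- function(x, method) {
  if (method == "spearman") rank(x) else x
}

.asPlainMatrix <- function(x) {
  if (is(x, "PairwiseMatrix")) x@mat else as.matrix(x)
}

#' Mantel permutation test between two distance matrices
#'
#' Correlates the n(n-1)/2 off-diagonal entries of two aligned symmetric
#' matrices (Spearman rank correlation by default). The null distribution is
#' generated by simultaneous row/column permutation of `A` (by convention
#' the genetic matrix); the two-sided p-value is
#' (1 + #\{|r*| >= |r_obs|\}) / (nPerm + 1). With `exact = TRUE` all n!
#' relabelings are enumerated instead (n <= 8) and
#' p = #\{|r*| >= |r_obs|\} / n!.
#'
#' @param A,B [PairwiseMatrix-class] objects (or plain labeled symmetric
#'   matrices) on the same populations; `A` is the matrix whose labels are
#'   permuted
#' @param nPerm number of random permutations (default 999)
#' @param method `"spearman"` (default) or `"pearson"`
#' @param seed integer seed for the permutation stream
#' @param exact enumerate all permutations instead of sampling
#' @return a [MantelResult-class]
#' @export
mantelTest <- function(A, B, nPerm = 999,
                       method = c("spearman", "pearson"), seed = 1,
                       exact = FALSE) {
  method <- match.arg(method)
  if (is(A, "PairwiseMatrix") && is(B, "PairwiseMatrix"))
    .checkAligned(A, B)
  a <- .asPlainMatrix(A); b <- .asPlainMatrix(B)
  n <- nrow(a)
  if (n < 4) stop("at least four populations required")
  lo <- lower.tri(a)
  bv <- .assocTransform(b[lo], method)
  av <- .assocTransform(a[lo], method)
  if (sd(av) == 0 || sd(bv) == 0) {
    return(new("MantelResult", statistic = NA_real_, p.value = NA_real_,
               nPerm = nPerm, method = method, partial = FALSE,
               seed = as.numeric(seed)))
  }
  robs <- cor(av, bv)
  tol <- 1e-12
  if (exact) {
    perms <- .allPerms(n)
    rstar <- apply(perms, 1, function(pp) {
      ap <- a[pp, pp]
      cor(.assocTransform(ap[lo], method), bv)
    })
    p <- mean(abs(rstar) >= abs(robs) - tol)
    return(new("MantelResult", statistic = robs, p.value = p, nPerm = 0,
               method = method, partial = FALSE, seed = NA_real_))
  }
  set.seed(as.integer(seed %% 2147483647))
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    pp <- sample.int(n)
    ap <- a[pp, pp]
    rstar <- cor(.assocTransform(ap[lo], method), bv)
    if (abs(rstar) >= abs(robs) - tol) cnt <- cnt + 1L
  }
  new("MantelResult", statistic = robs, p.value = (1 + cnt) / (nPerm + 1),
      nPerm = nPerm, method = method, partial = FALSE,
      seed = as.numeric(seed))
}

# partial correlation of transformed off-diagonal vectors
.partialR <- function(av, bv, cv) {
  rab <- cor(av, bv); rac <- cor(av, cv); rbc <- cor(bv, cv)
  den <- (1 - rac^2) * (1 - rbc^2)
  if (den <= 0) return(NA_real_)
  (rab - rac * rbc) / sqrt(den)
}

#' Partial Mantel permutation test
#'
#' Partial correlation of `A` and `B` off-diagonals controlling for `C`
#' (vectors rank-transformed first under the Spearman method):
#' R_PM = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2)). The null
#' permutes the labels of `A` and recomputes the full partial statistic
#' each draw (raw-permutation method).
#'
#' @inheritParams mantelTest
#' @param C the matrix partialled out
#' @return a [MantelResult-class] with `partial = TRUE`
#' @export
partialMantelTest <- function(A, B, C, nPerm = 999,
                              method = c("spearman", "pearson"),
                              seed = 1) {
  method <- match.arg(method)
  if (is(A, "PairwiseMatrix") && is(B, "PairwiseMatrix") &&
      is(C, "PairwiseMatrix"))
    .checkAligned(A, B, C)
  a <- .asPlainMatrix(A); b <- .asPlainMatrix(B); cM <- .asPlainMatrix(C)
  n <- nrow(a)
  if (n < 4) stop("at least four populations required")
  lo <- lower.tri(a)
  av <- .assocTransform(a[lo], method)
  bv <- .assocTransform(b[lo], method)
  cv <- .assocTransform(cM[lo], method)
  # perfect control (B identical to C): the 0/0 limit of the formula is 0
  if (isTRUE(all.equal(bv, cv, tolerance = 1e-12)))
    return(new("MantelResult", statistic = 0, p.value = 1,
               nPerm = nPerm, method = method, partial = TRUE,
               seed = as.numeric(seed)))
  if (sd(av) == 0 || sd(bv) == 0 || sd(cv) == 0 ||
      abs(cor(av, cv)) >= 1 - 1e-12 || abs(cor(bv, cv)) >= 1 - 1e-12) {
    return(new("MantelResult", statistic = NA_real_, p.value = NA_real_,
               nPerm = nPerm, method = method, partial = TRUE,
               seed = as.numeric(seed)))
  }
  robs <- .partialR(av, bv, cv)
  tol <- 1e-12
  set.seed(as.integer(seed %% 2147483647))
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    pp <- sample.int(n)
    ap <- a[pp, pp]
    rstar <- .partialR(.assocTransform(ap[lo], method), bv, cv)
    if (!is.na(rstar) && abs(rstar) >= abs(robs) - tol) cnt <- cnt + 1L
  }
  new("MantelResult", statistic = robs, p.value = (1 + cnt) / (nPerm + 1),
      nPerm = nPerm, method = method, partial = TRUE,
      seed = as.numeric(seed))
}

#' Reciprocal causal modeling heatmap
#'
#' For every unordered pair of candidate matrices \{A, B\} the reciprocal
#' partial-Mantel statistics R_PM-A = R_PM(G ~ A | B) and
#' R_PM-B = R_PM(G ~ B | A) are computed; the heatmap entry is their
#' difference D\[A, B\] = R_PM-A - R_PM-B (antisymmetric, zero diagonal).
#' With k candidates this runs exactly k(k-1) partial Mantel tests, i.e.
#' 110 tests / 55 reciprocal models for the canonical 11-variable set.
#'
#' @param G genetic [PairwiseMatrix-class]
#' @param variableMatrices named list of candidate matrices aligned with `G`
#' @param nPerm permutations per partial test (default 999)
#' @param method correlation method, `"spearman"` default
#' @param seed root seed; each test derives its own substream
#' @return an [RCMHeatmap-class]
#' @export
rcmHeatmap <- function(G, variableMatrices, nPerm = 999,
                       method = c("spearman", "pearson"), seed = 1) {
  method <- match.arg(method)
  k <- length(variableMatrices)
  if (k < 2) stop("at least two candidate matrices required")
  vars <- names(variableMatrices)
  if (is.null(vars) || any(vars == ""))
    stop("variableMatrices must be named")
  D <- RPM <- P <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(D) <- 0
  nTests <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sA <- .substream(seed, paste0("rcm-", vars[i], "|", vars[j]))
    sB <- .substream(seed, paste0("rcm-", vars[j], "|", vars[i]))
    resA <- partialMantelTest(G, variableMatrices[[i]],
                              variableMatrices[[j]], nPerm = nPerm,
                              method = method, seed = sA)
    resB <- partialMantelTest(G, variableMatrices[[j]],
                              variableMatrices[[i]], nPerm = nPerm,
                              method = method, seed = sB)
    nTests <- nTests + 2L
    RPM[i, j] <- resA@statistic; P[i, j] <- resA@p.value
    RPM[j, i] <- resB@statistic; P[j, i] <- resB@p.value
    if (is.na(resA@statistic) || is.na(resB@statistic)) {
      D[i, j] <- D[j, i] <- NA_real_   # flagged, not silently zero
    } else {
      D[i, j] <- resA@statistic - resB@statistic
      D[j, i] <- -D[i, j]
    }
  }
  new("RCMHeatmap", delta = D, rpm = RPM, pvalues = P, nPerm = nPerm,
      nTests = as.numeric(nTests))
}
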