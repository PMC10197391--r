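# pair -> population incidence matrix Z (m x n, two ones per row), pairs in
# lower-triangle column-major order to match pwValues()
.pairIncidence <- function(n) {
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(ij)
  Z <- matrix(0, m, n)
  Z[cbind(seq_len(m), ij[, 1])] <- 1
  Z[cbind(seq_len(m), ij[, 2])] <- 1
  Z
}

#' Fit a single-predictor MLPE mixed model
#'
#' Maximum-likelihood (not REML) fit of
#' y = b0 + b1 x + Z u + e over all population pairs, where Z is the
#' pair-to-population incidence (two ones per row), u ~ N(0, sigmaU2 I) and
#' e ~ N(0, sigmaE2 I); the marginal covariance is
#' V = sigmaU2 Z Z' + sigmaE2 I. The fixed effects and sigmaE2 are profiled
#' out and the variance ratio sigmaU2/sigmaE2 is optimized on a bounded log
#' scale, making the fit deterministic given the data. The predictor is
#' z-scored over off-diagonal entries by default so AICs are comparable
#' across candidate matrices; the response is left raw.
#'
#' @param G response [PairwiseMatrix-class] (genetic distance)
#' @param X predictor [PairwiseMatrix-class] aligned with `G`
#' @param standardize z-score the predictor off-diagonals (default TRUE)
#' @param predictor label stored in the fit
#' @return an [MLPEFit-class] (AIC uses k = 4 parameters)
#' @export
fitMLPE <- function(G, X, standardize = TRUE, predictor = "x") {
  if (is(G, "PairwiseMatrix") && is(X, "PairwiseMatrix"))
    .checkAligned(G, X)
  g <- .asPlainMatrix(G); xm <- .asPlainMatrix(X)
  n <- nrow(g)
  if (n < 4) stop("at least four populations required")
  y <- g[lower.tri(g)]
  x <- xm[lower.tri(xm)]
  if (standardize) {
    if (sd(x) == 0) stop("constant predictor cannot be standardized")
    x <- (x - mean(x)) / sd(x)
  }
  m <- length(y)
  Z <- .pairIncidence(n)
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  Q <- eg$vectors
  dvals <- pmax(eg$values, 0)
  yt <- drop(crossprod(Q, y))
  Xt <- crossprod(Q, cbind(1, x))
  prof <- function(loglam) {
    lam <- exp(loglam)
    wi <- 1 / (1 + lam * dvals)
    A <- crossprod(Xt, wi * Xt)
    beta <- solve(A, crossprod(Xt, wi * yt))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(wi * r^2)
    sigE <- rss / m
    nll <- 0.5 * (m * log(2 * pi) + m * log(sigE) +
                    sum(log(1 + lam * dvals)) + m)
    list(nll = nll, beta = drop(beta), sigE = sigE, lam = lam)
  }
  lo <- -30; hi <- 15
  opt <- optimize(function(l) prof(l)$nll, c(lo, hi))
  # the profile is flat as loglam -> -inf (sigmaU2 -> 0); treat the lower
  # bound as the OLS collapse rather than a failed optimum
  atLower <- opt$minimum < lo + 1
  best <- prof(opt$minimum)
  ols <- prof(-300)                  # numerically exact OLS collapse
  if (ols$nll <= best$nll + 1e-9) {
    best <- ols
    best$lam <- 0
    atLower <- TRUE
  }
  sigU <- best$lam * best$sigE
  new("MLPEFit", beta = unname(best$beta), sigmaU2 = sigU,
      sigmaE2 = best$sigE,
      rho = sigU / (sigU + best$sigE), logLik = -best$nll,
      aic = 2 * best$nll + 2 * 4, m = m, n = n,
      atBound = atLower || opt$minimum > hi - 1,
      predictor = predictor)
}

#' Rank candidate distance predictors by MLPE AIC
#'
#' Fits one single-predictor MLPE model per candidate matrix (each z-scored
#' over off-diagonals) and tabulates AIC and delta AIC relative to the best
#' model.
#'
#' @param G response [PairwiseMatrix-class]
#' @param predictorMatrices named list of candidate matrices aligned with
#'   `G`
#' @return data.frame with `predictor`, `beta1`, `logLik`, `AIC`,
#'   `deltaAIC`, sorted by ascending AIC; failed fits are reported with NA
#'   rather than dropped
#' @export
rankMLPE <- function(G, predictorMatrices) {
  if (length(predictorMatrices) < 2)
    stop("at least two candidate predictors required")
  vars <- names(predictorMatrices)
  if (is.null(vars) || any(vars == ""))
    stop("predictorMatrices must be named")
  rows <- lapply(vars, function(v) {
    fit <- tryCatch(fitMLPE(G, predictorMatrices[[v]], predictor = v),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(predictor = v, beta1 = NA_real_,
                        logLik = NA_real_, AIC = NA_real_,
                        error = conditionMessage(fit)))
    data.frame(predictor = v, beta1 = fit@beta[2], logLik = fit@logLik,
               AIC = fit@aic, error = NA_character_)
  })
  tab <- do.call(rbind, rows)
  tab$deltaAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
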