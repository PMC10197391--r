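# Monotone I-spline basis with 3 functions over knots (min, median, max).
# Built from the B-spline identity: with quadratic B-splines B_1..B_4 on the
# knot vector (a,a,a,m,b,b,b), I_i(x) = sum_{j > i} B_j(x). Each basis is
# non-decreasing, 0 at the minimum and 1 at the maximum; inputs outside
# [a, b] are clamped (flat extension).
.isplineBasis <- function(x, knots) {
  a <- knots[1]; m <- knots[2]; b <- knots[3]
  out <- matrix(0, length(x), 3)
  if (!is.finite(a) || !is.finite(b) || b - a <= 0) return(out)
  # guard against a degenerate median collapsing onto a boundary
  if (m <= a || m >= b) m <- (a + b) / 2
  xc <- pmin(pmax(x, a), b)
  B <- splines::splineDesign(c(a, a, a, m, b, b, b), xc, ord = 3)
  cbind(B[, 2] + B[, 3] + B[, 4], B[, 3] + B[, 4], B[, 4])
}

.isplineKnots <- function(x) unname(quantile(x, c(0, 0.5, 1), names = FALSE))

#' Build a GDM site-pair table
#'
#' One row per unordered population pair, holding the response dissimilarity
#' (pairwise FST, negatives clamped to 0), a unit weight, both sites'
#' predictor values, and optionally the pairwise geographic distance as an
#' additional predictor.
#'
#' @param fst genetic [PairwiseMatrix-class]
#' @param envTable per-population predictor values (matrix/data.frame with
#'   population rownames or `pop` column), aligned to the FST labels
#' @param geo optional geographic [PairwiseMatrix-class]; when supplied (and
#'   `includeGeo` is TRUE) distance enters as predictor `"geographic"`
#' @param includeGeo include the geographic distance predictor
#' @return data.frame of class `"sitePairTable"` with columns `distance`
#'   (response), `weight`, `s1.<var>`/`s2.<var>` per predictor and
#'   `geographic` when present
#' @export
buildSitePairs <- function(fst, envTable, geo = NULL, includeGeo = TRUE) {
  labs <- pwLabels(fst)
  envTable <- as.data.frame(envTable)
  if ("pop" %in% names(envTable)) {
    rownames(envTable) <- envTable$pop
    envTable$pop <- NULL
  }
  if (!all(labs %in% rownames(envTable)))
    stop("environmental table does not cover all FST populations")
  envTable <- envTable[labs, , drop = FALSE]
  n <- length(labs)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pmax(pwValues(fst), 0)
  out <- data.frame(distance = d, weight = 1,
                    site1 = labs[ij[, 2]], site2 = labs[ij[, 1]],
                    stringsAsFactors = FALSE)
  for (v in names(envTable)) {
    out[[paste0("s1.", v)]] <- envTable[ij[, 2], v]
    out[[paste0("s2.", v)]] <- envTable[ij[, 1], v]
  }
  if (includeGeo && !is.null(geo)) {
    if (!identical(pwLabels(geo), labs))
      stop("geographic matrix not aligned with FST labels")
    out$geographic <- pwValues(geo)
  }
  class(out) <- c("sitePairTable", "data.frame")
  out
}

# design matrix of |f_k(site1) - f_k(site2)| I-spline columns (env
# predictors) and I_s(distance) columns (geographic), plus knots
.gdmDesign <- function(sitePairs, knots = NULL) {
  nm <- names(sitePairs)
  envVars <- sub("^s1\\.", "", nm[startsWith(nm, "s1.")])
  preds <- c(envVars, if ("geographic" %in% nm) "geographic")
  if (length(preds) == 0) stop("site-pair table has no predictors")
  if (is.null(knots)) {
    knots <- lapply(preds, function(v) {
      vals <- if (v == "geographic") sitePairs$geographic
              else c(sitePairs[[paste0("s1.", v)]],
                     sitePairs[[paste0("s2.", v)]])
      .isplineKnots(vals)
    })
    names(knots) <- preds
  }
  cols <- list()
  for (v in preds) {
    if (v == "geographic") {
      X <- .isplineBasis(sitePairs$geographic, knots[[v]])
    } else {
      X <- abs(.isplineBasis(sitePairs[[paste0("s1.", v)]], knots[[v]]) -
                 .isplineBasis(sitePairs[[paste0("s2.", v)]], knots[[v]]))
    }
    colnames(X) <- paste0(v, ".", seq_len(ncol(X)))
    cols[[v]] <- X
  }
  list(X = do.call(cbind, cols), knots = knots, predictors = preds)
}

.gdmDeviance <- function(d, mu, w, eps = 1e-6) {
  d <- pmin(pmax(d, eps), 1 - eps)
  mu <- pmin(pmax(mu, eps / 10), 1 - eps / 10)
  2 * sum(w * (d * log(d / mu) + (1 - d) * log((1 - d) / (1 - mu))))
}

# best intercept-only deviance (null model), beta0 >= 0
.gdmNullDeviance <- function(d, w) {
  f <- function(b0) .gdmDeviance(d, 1 - exp(-b0), w)
  opt <- optimize(f, c(0, 20))
  if (f(0) < opt$objective) list(b0 = 0, dev = f(0))
  else list(b0 = opt$minimum, dev = opt$objective)
}

#' Fit a generalized dissimilarity model
#'
#' Fits mu = 1 - exp(-eta) with
#' eta = b0 + sum_k sum_s beta_ks |I_ks(x_k, site1) - I_ks(x_k, site2)|
#' (geographic distance splined directly on the distance value), minimizing
#' the continuous binomial-form deviance under non-negativity of all
#' coefficients, via iteratively reweighted least squares with a
#' Lawson-Hanson non-negative least-squares inner step. Convergence when
#' the deviance changes by less than 1e-6, capped at 100 iterations.
#'
#' @param sitePairs table from [buildSitePairs()]
#' @param nSplines number of I-spline basis functions per predictor
#'   (currently fixed at 3: knots at the 0th/50th/100th percentiles)
#' @return a [GDMModel-class]
#' @export
fitGDM <- function(sitePairs, nSplines = 3) {
  if (nSplines != 3)
    stop("this implementation uses 3 I-splines per predictor")
  des <- .gdmDesign(sitePairs)
  X <- cbind(intercept = 1, des$X)
  d <- sitePairs$distance
  w <- sitePairs$weight
  if (any(w <= 0)) stop("weights must be positive")
  if (nrow(X) < ncol(X) + 1)
    stop("too few site pairs for the number of spline coefficients")
  null <- .gdmNullDeviance(d, w)
  beta <- c(null$b0, rep(0, ncol(X) - 1))
  dev <- .gdmDeviance(d, 1 - exp(-drop(X %*% beta)), w)
  converged <- FALSE
  for (iter in seq_len(100)) {
    eta <- drop(X %*% beta)
    mu <- 1 - exp(-eta)
    mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    dmu <- 1 - mu                      # d mu / d eta = exp(-eta)
    z <- eta + (d - mu) / dmu
    W <- w * dmu^2 / (mu * (1 - mu))
    sw <- sqrt(W)
    betaNew <- .nnls(X * sw, z * sw)
    devNew <- .gdmDeviance(d, 1 - exp(-drop(X %*% betaNew)), w)
    # step-halving if the quadratic step overshoots
    step <- 1
    while (devNew > dev + 1e-10 && step > 1e-4) {
      step <- step / 2
      betaTry <- beta + step * (betaNew - beta)
      devNew <- .gdmDeviance(d, 1 - exp(-drop(X %*% betaTry)), w)
      if (devNew <= dev + 1e-10) betaNew <- betaTry
    }
    delta <- abs(dev - devNew)
    beta <- betaNew
    dev <- devNew
    if (delta < 1e-6) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GDM fit did not converge within 100 iterations")
  coefs <- split(beta[-1], rep(des$predictors, each = 3))[des$predictors]
  names(coefs) <- des$predictors
  explained <- if (null$dev > 0) 100 * (1 - dev / null$dev) else NA_real_
  new("GDMModel", predictors = des$predictors, knots = des$knots,
      intercept = beta[1], coefficients = coefs,
      nullDeviance = null$dev, residDeviance = dev,
      explained = explained, converged = converged,
      sitePairs = as.data.frame(sitePairs))
}

#' Evaluate a fitted GDM partial response function
#'
#' Returns f_k(x) = sum_s beta_ks I_ks(x) for one predictor; values outside
#' the knot span use flat (constant) extension.
#'
#' @param model a [GDMModel-class]
#' @param predictor predictor name
#' @param x numeric values at which to evaluate
#' @return numeric vector f_k(x)
#' @export
gdmPartial <- function(model, predictor, x) {
  if (!predictor %in% model@predictors)
    stop("unknown predictor: ", predictor)
  drop(.isplineBasis(x, model@knots[[predictor]]) %*%
         model@coefficients[[predictor]])
}

#' Percent deviance explained by a fitted GDM
#'
#' 100 (1 - residual deviance / null deviance), the null being the best
#' intercept-only model on the same data.
#'
#' @param model a [GDMModel-class]
#' @return percentage (NA-flagged when the null deviance is zero)
#' @export
percentDevianceExplained <- function(model) {
  if (model@nullDeviance <= 0) return(NA_real_)
  model@explained
}

#' Predictor importance from fitted spline heights
#'
#' The importance of predictor k is the total spline height
#' sum_s beta_ks (the maximum of f_k, since every basis function reaches 1);
#' percentages are relative to the summed heights.
#'
#' @param model a [GDMModel-class]
#' @return data.frame with `predictor`, `height`, `percent`, sorted by
#'   decreasing importance (percent NA-flagged if all coefficients are 0)
#' @export
predictorImportance <- function(model) {
  h <- vapply(model@coefficients, sum, 0)
  tot <- sum(h)
  out <- data.frame(predictor = model@predictors, height = unname(h),
                    percent = if (tot > 0) unname(100 * h / tot)
                              else rep(NA_real_, length(h)))
  out[order(-out$height), , drop = FALSE]
}

#' Tabulated fitted I-splines for plotting
#'
#' Evaluates every fitted partial response on a grid over its observed
#' range.
#'
#' @param model a [GDMModel-class]
#' @param nPoints grid size per predictor (default 200)
#' @return data.frame with `predictor`, `x`, `f`
#' @export
gdmSplineTable <- function(model, nPoints = 200) {
  do.call(rbind, lapply(model@predictors, function(v) {
    kn <- model@knots[[v]]
    x <- seq(kn[1], kn[3], length.out = nPoints)
    data.frame(predictor = v, x = x, f = gdmPartial(model, v, x))
  }))
}
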