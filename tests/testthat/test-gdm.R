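test_that("I-spline basis endpoint identities and monotonicity", {
  set.seed(2)
  for (i in 1:10) {
    kn <- sort(runif(3, -5, 5))
    x <- seq(kn[1], kn[3], length.out = 100)
    B <- landgen:::.isplineBasis(x, kn)
    expect_equal(unname(B[1, ]), c(0, 0, 0), tolerance = 1e-12)
    expect_equal(unname(B[100, ]), c(1, 1, 1), tolerance = 1e-12)
    expect_true(all(diff(B[, 1]) >= -1e-12))
    expect_true(all(diff(B[, 2]) >= -1e-12))
    expect_true(all(diff(B[, 3]) >= -1e-12))
    # flat extension beyond the knot span
    expect_equal(landgen:::.isplineBasis(kn[3] + 10, kn),
                 landgen:::.isplineBasis(kn[3], kn))
  }
})

test_that("non-negative least squares matches a bound-constrained oracle", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:40, 1); p <- sample(2:8, 1)
    A <- matrix(rnorm(n * p), n, p)
    b <- rnorm(n)
    x <- landgen:::.nnls(A, b)
    obj <- function(z) sum((A %*% z - b)^2)
    o <- optim(rep(0.1, p), obj, gr = function(z) 2 * crossprod(A, A %*% z - b),
               method = "L-BFGS-B", lower = 0,
               control = list(factr = 1e3, maxit = 500))
    expect_true(all(x >= 0))
    expect_lte(obj(x), obj(o$par) + 1e-6)
  }
})

test_that("site-pair construction counts pairs and aligns predictors", {
  labs3 <- c("a", "b", "c")
  f3 <- randDistMatrix(3, seed = 1, labs = labs3)
  f3 <- PairwiseMatrix(as.matrix(f3), "genetic")
  env3 <- data.frame(v = c(1, 2, 3), k = 7, row.names = labs3)
  sp3 <- buildSitePairs(f3, env3, includeGeo = FALSE)
  expect_equal(nrow(sp3), 3)
  expect_equal(sp3$s1.k, sp3$s2.k)              # constant variable
  labs21 <- sprintf("P%02d", 1:21)
  f21 <- randDistMatrix(21, seed = 2, labs = labs21)
  f21 <- PairwiseMatrix(as.matrix(f21), "genetic")
  env21 <- data.frame(v = rnorm(21), row.names = labs21)
  expect_equal(nrow(buildSitePairs(f21, env21, includeGeo = FALSE)), 210)
  # negative response values are clamped to zero
  neg <- PairwiseMatrix(as.matrix(f3) - 10, "genetic")
  expect_true(all(buildSitePairs(neg, env3,
                                 includeGeo = FALSE)$distance >= 0))
  expect_error(buildSitePairs(f3, env3[1:2, , drop = FALSE],
                              includeGeo = FALSE), "cover")
})

gdmToy <- function(n = 21, slope = 0.6, b0 = 0.1, noise = 0, seed = 3) {
  set.seed(seed)
  labs <- sprintf("P%02d", seq_len(n))
  x <- runif(n, 0, 10)
  f <- function(v) slope * (v - min(x)) / diff(range(x))
  D <- outer(x, x, function(a, b) 1 - exp(-(b0 + abs(f(a) - f(b)))))
  if (noise > 0) {
    e <- matrix(rnorm(n^2, sd = noise), n)
    D <- D + (e + t(e)) / 2
    D <- pmin(pmax(D, 0), 0.97)
  }
  diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  list(fst = PairwiseMatrix(D, "genetic"),
       env = data.frame(v = x, row.names = labs), x = x, f = f)
}

test_that("noiseless generative dissimilarities are recovered", {
  toy <- gdmToy()
  sp <- buildSitePairs(toy$fst, toy$env, includeGeo = FALSE)
  m <- fitGDM(sp)
  expect_true(m@converged)
  expect_gte(m@explained, 99)
  expect_equal(m@intercept, 0.1, tolerance = 0.01)
  # fitted partial response matches the generator at the knots within 5%
  kn <- m@knots$v
  fFit <- gdmPartial(m, "v", kn)
  fTrue <- toy$f(kn) - toy$f(kn[1])
  expect_equal(fFit[2], fTrue[2], tolerance = 0.05)
  expect_equal(fFit[3], fTrue[3], tolerance = 0.05)
  # order invariance of the rows
  sp2 <- sp[sample(nrow(sp)), ]
  m2 <- fitGDM(sp2)
  expect_equal(unlist(m2@coefficients), unlist(m@coefficients),
               tolerance = 1e-8)
  expect_equal(m2@intercept, m@intercept, tolerance = 1e-8)
})

test_that("deviance accounting: null fit, perfect fit, noise monotonicity", {
  # response carrying no predictor signal: explained deviance ~ 0
  set.seed(9)
  labs <- sprintf("P%02d", 1:15)
  e <- matrix(rnorm(225, sd = 0.02), 15)
  D <- 0.3 + (e + t(e)) / 2
  diag(D) <- 0
  dimnames(D) <- list(labs, labs)
  fNull <- PairwiseMatrix(D, "genetic")
  envU <- data.frame(v = rep(c(1, 2, 3), 5), row.names = labs)
  mNull <- fitGDM(buildSitePairs(fNull, envU, includeGeo = FALSE))
  expect_lt(mNull@explained, 5)
  expect_gte(mNull@explained, 0)
  # mu within [0, 1) guaranteed by the link and non-negative coefficients
  expect_gte(mNull@intercept, 0)
  # increasing noise degrades the fit monotonically
  expl <- vapply(c(0, 0.05, 0.15), function(ns) {
    toy <- gdmToy(noise = ns, seed = 13)
    suppressWarnings(
      fitGDM(buildSitePairs(toy$fst, toy$env, includeGeo = FALSE))@explained)
  }, 0)
  expect_true(all(diff(expl) < 0))
  expect_equal(percentDevianceExplained(
    fitGDM(buildSitePairs(gdmToy()$fst, gdmToy()$env,
                          includeGeo = FALSE))),
    fitGDM(buildSitePairs(gdmToy()$fst, gdmToy()$env,
                          includeGeo = FALSE))@explained)
})

test_that("fitted responses are monotone and bounded", {
  toy <- gdmToy(noise = 0.05, seed = 17)
  m <- suppressWarnings(fitGDM(buildSitePairs(toy$fst, toy$env,
                                              includeGeo = FALSE)))
  kn <- m@knots$v
  grid <- seq(kn[1], kn[3], length.out = 100)
  fv <- gdmPartial(m, "v", grid)
  expect_true(all(diff(fv) >= -1e-10))
  expect_true(all(fv >= 0))
  # predictions bounded in [0, 1)
  des <- landgen:::.gdmDesign(m@sitePairs, m@knots)
  eta <- m@intercept + drop(des$X %*% unlist(m@coefficients))
  mu <- 1 - exp(-eta)
  expect_true(all(mu >= 0 & mu < 1))
})

test_that("predictor importance arithmetic and noise robustness", {
  model <- new("GDMModel", predictors = c("a", "b"),
               knots = list(a = c(0, 1, 2), b = c(0, 1, 2)),
               intercept = 0.1,
               coefficients = list(a = c(2, 0.5, 0.5), b = c(1, 0, 0)),
               nullDeviance = 10, residDeviance = 5, explained = 50,
               converged = TRUE, sitePairs = data.frame())
  imp <- predictorImportance(model)
  expect_equal(imp$percent, c(75, 25))
  expect_equal(imp$predictor, c("a", "b"))
  # a single active predictor takes 100%
  toy <- gdmToy()
  m1 <- fitGDM(buildSitePairs(toy$fst, toy$env, includeGeo = FALSE))
  expect_equal(predictorImportance(m1)$percent[1], 100)
  # adding a pure-noise predictor barely moves the explained deviance
  set.seed(21)
  env2 <- toy$env
  env2$junk <- rnorm(nrow(env2))
  m2 <- suppressWarnings(
    fitGDM(buildSitePairs(toy$fst, env2, includeGeo = FALSE)))
  expect_lt(abs(m2@explained - m1@explained), 2)
})
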