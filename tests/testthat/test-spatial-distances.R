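test_that("straight-line distances: haversine and planar modes", {
  pt <- data.frame(pop = c("a", "b", "c"),
                   lon = c(0, 1, 0), lat = c(0, 0, 1))
  m <- as.matrix(euclideanMatrix(pt))               # auto -> great-circle
  expect_equal(m["a", "a"], 0)
  expect_equal(m["a", "c"], 111.19, tolerance = 1e-4) # one degree at R=6371
  expect_equal(m["a", "b"], m["a", "c"], tolerance = 1e-9) # equator symmetry
  ptXY <- data.frame(pop = c("a", "b"), x = c(0, 3), y = c(0, 4))
  expect_equal(as.matrix(euclideanMatrix(ptXY))["a", "b"], 5)
  bad <- data.frame(pop = "a", lon = 0, lat = 95)
  expect_error(euclideanMatrix(rbind(pt, bad)), "latitude")
})

test_that("environmental distances are absolute differences", {
  ev <- data.frame(v1 = c(5, 3), v2 = c(2, 2), row.names = c("a", "b"))
  out <- envDistanceMatrices(ev)
  expect_equal(as.matrix(out$v1)["a", "b"], 2)
  expect_true(all(as.matrix(out$v2) == 0))          # constant variable
  expect_equal(pwKind(out$v1), "environmental:v1")
  ev4 <- data.frame(v = c(1, 2, 4, 8),
                    row.names = c("a", "b", "c", "d"))
  m <- as.matrix(envDistanceMatrices(ev4)$v)
  hand <- matrix(c(0, 1, 3, 7, 1, 0, 2, 6, 3, 2, 0, 4, 7, 6, 4, 0), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(m, hand)
  evNA <- data.frame(v = c(1, NA), row.names = c("a", "b"))
  expect_error(envDistanceMatrices(evNA), "missing value of v.*b")
})

test_that("suitability-to-conductance transforms and their rank reversal", {
  s <- GridRaster(matrix(c(1, 0.5, 0, 0.25), 2, 2))
  rc <- suitabilityToResistance(s)
  expect_equal(rasterValues(rc)[1, 1], 1)
  expect_equal(rasterValues(rc)[1, 2], 1e-3)        # clamped floor
  ri <- suitabilityToResistance(s, method = "inverse")
  # cellwise: resistances under the two methods are rank-reversed in
  # suitability, i.e. both orderings agree with suitability itself
  resC <- as.vector(1 / rasterValues(rc))
  resI <- as.vector(1 / rasterValues(ri))
  expect_equal(order(resC), order(resI))
  bad <- GridRaster(matrix(c(0.5, 1.2), 1, 2))
  expect_error(suitabilityToResistance(bad), "0, 1")
})

test_that("least-cost distances: uniform grids, linearity, oracle", {
  vu <- matrix(0.5, 3, 6)  # conductance 0.5 = resistance 2 everywhere
  rr <- new("ResistanceRaster", GridRaster(vu, cellsize = 10))
  pt <- data.frame(pop = c("a", "b"), x = c(5, 55), y = c(15, 15))
  expect_equal(as.matrix(leastCostDistance(rr, pt))["a", "b"],
               5 * 2 * 10)                       # k steps * r * cellsize
  rrHalf <- new("ResistanceRaster", GridRaster(vu * 2, cellsize = 10))
  expect_equal(as.matrix(leastCostDistance(rrHalf, pt))["a", "b"],
               5 * 1 * 10)                       # halving r halves LCD
  # random 3x3 grids against exhaustive simple-path enumeration
  set.seed(8)
  for (i in 1:10) {
    v <- matrix(runif(9, 0.05, 1), 3, 3)
    rr3 <- new("ResistanceRaster", GridRaster(v, cellsize = 1))
    p3 <- data.frame(pop = c("a", "b"), x = c(0.5, 2.5), y = c(2.5, 0.5))
    got <- as.matrix(leastCostDistance(rr3, p3))["a", "b"]
    want <- lcdOracle(v, 1, from = c(1, 1), to = c(3, 3))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("circuit distances: closed forms and dense pseudoinverse oracle", {
  # two-node chain with a single edge of conductance g -> 1/g
  e <- data.frame(from = 1, to = 2)
  L <- landgen:::.laplacian(e, 4, 2)
  expect_equal(landgen:::.effectiveResistance(L, c(1, 2))[1, 2], 0.25)
  # 4-cycle of unit resistors, opposite corners -> (2*2)/(2+2) = 1
  e4 <- data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1))
  L4 <- landgen:::.laplacian(e4, rep(1, 4), 4)
  expect_equal(landgen:::.effectiveResistance(L4, c(1, 3))[1, 2], 1)
  skip_if_not_installed("MASS")
  set.seed(15)
  for (i in 1:10) {
    nr <- sample(4:10, 1); nc <- sample(4:10, 1)
    v <- matrix(runif(nr * nc, 0.1, 1), nr, nc)
    rr <- new("ResistanceRaster", GridRaster(v, cellsize = 1))
    pts <- data.frame(pop = c("a", "b", "c"),
                      x = c(0.5, nc - 0.5, nc / 2),
                      y = c(0.5, nr - 0.5, nr / 2))
    cd <- as.matrix(circuitDistance(rr, pts))
    ed <- landgen:::.gridEdges(v)
    Ld <- as.matrix(landgen:::.laplacian(ed, (ed$v1 + ed$v2) / 2 / ed$fac,
                                         nr * nc))
    Lp <- MASS::ginv(Ld)
    nodes <- landgen:::.snapToCells(rr, pts)
    want <- outer(diag(Lp)[nodes], diag(Lp)[nodes], `+`) -
      2 * Lp[nodes, nodes]
    expect_lt(max(abs(cd - want)), 1e-8)
  }
})

test_that("distance matrices obey metric and circuit-theory inequalities", {
  set.seed(23)
  v <- matrix(runif(64, 0.1, 1), 8, 8)
  rr <- new("ResistanceRaster", GridRaster(v, cellsize = 1))
  pts <- data.frame(pop = sprintf("p%d", 1:5),
                    x = c(0.5, 7.5, 3.5, 0.5, 7.5),
                    y = c(0.5, 7.5, 4.5, 7.5, 0.5))
  lcd <- as.matrix(leastCostDistance(rr, pts))
  cd <- as.matrix(circuitDistance(rr, pts))
  # effective resistance never exceeds the least-cost resistance
  expect_true(all(cd <= lcd + 1e-9))
  # triangle inequality, all triples exhaustively
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(lcd[i, j], lcd[i, k] + lcd[k, j] + 1e-9)
    expect_lte(cd[i, j], cd[i, k] + cd[k, j] + 1e-9)
  }
  # Rayleigh monotonicity: raising one cell's resistance cannot decrease
  # any effective resistance
  for (rep in 1:3) {
    v2 <- v
    cell <- c(sample(8, 1), sample(8, 1))
    v2[cell[1], cell[2]] <- v2[cell[1], cell[2]] / 10  # conductance down
    cd2 <- as.matrix(circuitDistance(new("ResistanceRaster",
                                         GridRaster(v2, cellsize = 1)),
                                     pts))
    expect_true(all(cd2 >= cd - 1e-9))
  }
})

test_that("populations snap to usable cells; disconnection is an error", {
  v <- matrix(1, 5, 5)
  v[3, ] <- NA                                    # impassable wall
  rr <- new("ResistanceRaster", GridRaster(v, cellsize = 1))
  pts <- data.frame(pop = c("a", "b"), x = c(2.5, 2.5), y = c(4.5, 0.5))
  expect_error(leastCostDistance(rr, pts), "disconnected")
  expect_error(circuitDistance(rr, pts), "disconnected")
  # a point sitting on nodata snaps to the nearest usable cell
  v2 <- matrix(1, 3, 3); v2[2, 2] <- NA
  rr2 <- new("ResistanceRaster", GridRaster(v2, cellsize = 1))
  node <- landgen:::.snapToCells(rr2, data.frame(pop = "a", x = 1.5,
                                                 y = 1.5))
  expect_true(node != 5)                           # not the nodata center
})

test_that("ASCII grid rasters round-trip through disk", {
  v <- matrix(runif(20), 4, 5)
  v[2, 3] <- NA
  r <- GridRaster(v, xll = 100, yll = 200, cellsize = 25)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(r, f)
  r2 <- readAsciiGrid(f)
  expect_equal(rasterValues(r2), rasterValues(r), tolerance = 1e-9)
  expect_equal(r2@cellsize, 25)
  expect_equal(r2@xll, 100)
  expect_equal(r2@yll, 200)
})
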