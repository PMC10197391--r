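#' Straight-line distance matrix between populations
#'
#' Great-circle mode uses the haversine formula on longitude/latitude with
#' Earth radius 6371 km and returns kilometers; planar mode returns raw
#' Euclidean distance in coordinate units. With `mode = "auto"`, longitude/
#' latitude columns (`lon`/`lat` or `longitude`/`latitude`) select
#' great-circle, `x`/`y` columns select planar.
#'
#' @param popTable data.frame with a `pop` column and either `x`/`y`
#'   (planar map units) or `lon`/`lat` (decimal degrees)
#' @param mode `"auto"`, `"great-circle"` or `"planar"`
#' @return a [PairwiseMatrix-class] of kind `"geographic-euclidean"`
#' @export
euclideanMatrix <- function(popTable, mode = c("auto", "great-circle",
                                               "planar")) {
  mode <- match.arg(mode)
  nm <- tolower(names(popTable))
  names(popTable) <- nm
  if ("longitude" %in% nm) popTable$lon <- popTable$longitude
  if ("latitude" %in% nm) popTable$lat <- popTable$latitude
  hasLL <- all(c("lon", "lat") %in% names(popTable))
  if (mode == "auto") mode <- if (hasLL) "great-circle" else "planar"
  if (mode == "great-circle") {
    if (!hasLL) stop("great-circle mode needs lon/lat columns")
    if (any(abs(popTable$lat) > 90)) stop("latitude outside [-90, 90]")
    pts <- as.matrix(popTable[, c("lon", "lat")])
    n <- nrow(pts)
    m <- matrix(0, n, n)
    for (i in seq_len(n))
      m[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371) # km
  } else {
    cols <- if (all(c("x", "y") %in% names(popTable))) c("x", "y")
            else c("lon", "lat")
    m <- as.matrix(dist(popTable[, cols]))
  }
  PairwiseMatrix(m, kind = "geographic-euclidean", labels = popTable$pop)
}

#' Per-variable environmental distance matrices
#'
#' Entry (i, j) of each matrix is the absolute difference of the variable
#' between populations i and j.
#'
#' @param envTable matrix/data.frame of per-population values (rownames or a
#'   `pop` column give labels)
#' @return named list of [PairwiseMatrix-class] objects, one per variable,
#'   each of kind `"environmental:<variable>"`
#' @export
envDistanceMatrices <- function(envTable) {
  envTable <- as.data.frame(envTable)
  if ("pop" %in% names(envTable)) {
    rownames(envTable) <- envTable$pop
    envTable$pop <- NULL
  }
  labs <- rownames(envTable)
  if (is.null(labs)) stop("environmental table must carry population labels")
  out <- list()
  for (v in names(envTable)) {
    x <- envTable[[v]]
    if (anyNA(x))
      stop(sprintf("missing value of %s for population %s", v,
                   labs[which(is.na(x))[1]]))
    out[[v]] <- PairwiseMatrix(abs(outer(x, x, `-`)),
                               kind = paste0("environmental:", v),
                               labels = labs)
  }
  out
}

#' Convert a habitat-suitability raster to a conductance surface
#'
#' Default method maps suitability directly to conductance,
#' `conductance = max(suitability, epsilon)` (so resistance is its
#' reciprocal and perfectly unsuitable cells remain traversable but
#' costly). The alternative maps suitability to resistance
#' `1 - suitability + epsilon`, i.e. `conductance = 1 / (1 - s + eps)`.
#'
#' @param suitability a [GridRaster-class] with values in \[0, 1\]
#' @param method `"conductance"` (default) or `"inverse"`
#' @param epsilon floor keeping every cell traversable (default 1e-3)
#' @return a [ResistanceRaster-class] holding per-cell conductance
#' @export
suitabilityToResistance <- function(suitability,
                                    method = c("conductance", "inverse"),
                                    epsilon = 1e-3) {
  method <- match.arg(method)
  v <- suitability@values
  if (any(v[!is.na(v)] < 0 | v[!is.na(v)] > 1))
    stop("suitability values must lie in [0, 1]")
  cond <- switch(method,
                 conductance = pmax(v, epsilon),
                 inverse = 1 / (1 - v + epsilon))
  new("ResistanceRaster", GridRaster(cond, xll = suitability@xll,
                                     yll = suitability@yll,
                                     cellsize = suitability@cellsize))
}

# snap populations to nearest non-nodata cell center (row-major tie-break);
# returns vector of 1-based cell node ids (row-major over the full grid)
.snapToCells <- function(rr, popTable) {
  v <- rr@values
  nr <- nrow(v); nc <- ncol(v)
  cc <- .cellCenters(rr)
  nodes <- integer(nrow(popTable))
  for (i in seq_len(nrow(popTable))) {
    rc <- .coordToCell(rr, popTable$x[i], popTable$y[i])
    if (!is.na(v[rc[1], rc[2]])) {
      nodes[i] <- (rc[1] - 1L) * nc + rc[2]
    } else {
      d2 <- outer((cc$y - popTable$y[i])^2, (cc$x - popTable$x[i])^2, `+`)
      d2[is.na(v)] <- Inf
      best <- which(d2 == min(d2))       # row-major over t(): recompute
      ord <- arrayInd(best, dim(d2))
      ord <- ord[order(ord[, 1], ord[, 2]), , drop = FALSE]
      nodes[i] <- (ord[1, 1] - 1L) * nc + ord[1, 2]
    }
  }
  nodes
}

# 8-neighbor edge list over non-nodata cells; returns data.frame with node
# ids (row-major), the two cell values, and the diagonal factor
.gridEdges <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  id <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  shifts <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  from <- to <- integer(0); w1 <- w2 <- fac <- numeric(0)
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    A <- id[r1, c1, drop = FALSE]
    B <- id[r1 + dr, c1 + dc, drop = FALSE]
    va <- v[r1, c1, drop = FALSE]
    vb <- v[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(va) & !is.na(vb)
    from <- c(from, A[ok]); to <- c(to, B[ok])
    w1 <- c(w1, va[ok]); w2 <- c(w2, vb[ok])
    fac <- c(fac, rep(s[3], sum(ok)))
  }
  data.frame(from = from, to = to, v1 = w1, v2 = w2, fac = fac)
}

#' Least-cost distance matrix on a resistance surface
#'
#' Shortest cumulative-cost paths over the 8-neighbor grid graph. The cost
#' of moving between adjacent cells is the mean of the two cell resistances
#' (reciprocal conductances) times the cell size, times sqrt(2) for
#' diagonal moves. Populations snap to the nearest non-nodata cell center.
#'
#' @param rr a [ResistanceRaster-class]
#' @param popTable data.frame with `pop`, `x`, `y` in map units
#' @return a [PairwiseMatrix-class] of kind `"geographic-lcd"` (map units)
#' @export
leastCostDistance <- function(rr, popTable) {
  v <- rr@values
  edges <- .gridEdges(v)
  res1 <- 1 / edges$v1; res2 <- 1 / edges$v2
  w <- (res1 + res2) / 2 * rr@cellsize * edges$fac
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from),
               to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(length(v)))))
  nodes <- .snapToCells(rr, popTable)
  dm <- igraph::distances(g, v = as.character(nodes),
                          to = as.character(nodes), weights = w,
                          algorithm = "dijkstra")
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm), arr.ind = TRUE)[1, ]
    stop(sprintf("populations %s and %s are disconnected on the resistance surface",
                 popTable$pop[bad[1]], popTable$pop[bad[2]]))
  }
  dimnames(dm) <- list(popTable$pop, popTable$pop)
  PairwiseMatrix(dm, kind = "geographic-lcd")
}

# effective resistance between node pairs given a sparse graph Laplacian.
# Grounds the first focal node and factorizes once; R_ij recovered as
# G_ii + G_jj - 2 G_ij on the grounded inverse (and G_ii for pairs with the
# grounded node itself).
.effectiveResistance <- function(L, nodes) {
  k <- length(nodes)
  n <- nrow(L)
  ground <- nodes[1]
  keep <- setdiff(seq_len(n), ground)
  Lr <- L[keep, keep, drop = FALSE]
  idx <- match(nodes[-1], keep)
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE),
    warning = function(w)
      stop("resistance graph is disconnected (grounded Laplacian not ",
           "positive definite)"),
    error = function(e)
      stop("resistance graph is disconnected: ", conditionMessage(e)))
  rhs <- Matrix::sparseMatrix(i = idx, j = seq_along(idx),
                              x = 1, dims = c(nrow(Lr), length(idx)))
  sol <- as.matrix(Matrix::solve(ch, rhs))
  G <- sol[idx, , drop = FALSE]              # grounded inverse on focal nodes
  R <- matrix(0, k, k)
  dG <- diag(as.matrix(G))
  R[-1, -1] <- outer(dG, dG, `+`) - 2 * as.matrix(G)
  R[1, -1] <- R[-1, 1] <- dG
  diag(R) <- 0
  R
}

# sparse Laplacian from an edge conductance list
.laplacian <- function(edges, conduct, nNodes) {
  A <- Matrix::sparseMatrix(i = c(edges$from, edges$to),
                            j = c(edges$to, edges$from),
                            x = c(conduct, conduct),
                            dims = c(nNodes, nNodes))
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

#' Circuit (effective-resistance) distance matrix
#'
#' Treats the 8-neighbor raster graph as a resistor network: the
#' conductance of each edge is the mean of the two cell conductances
#' divided by the move length factor (1, or sqrt(2) for diagonals). The
#' pairwise effective resistance integrates all possible paths and is
#' computed by sparse grounded Laplacian solves (never a dense
#' pseudoinverse).
#'
#' @param rr a [ResistanceRaster-class]
#' @param popTable data.frame with `pop`, `x`, `y`
#' @return a [PairwiseMatrix-class] of kind `"geographic-cd"` (resistance
#'   units)
#' @export
circuitDistance <- function(rr, popTable) {
  v <- rr@values
  edges <- .gridEdges(v)
  conduct <- (edges$v1 + edges$v2) / 2 / edges$fac
  L <- .laplacian(edges, conduct, length(v))
  nodes <- .snapToCells(rr, popTable)
  if (anyDuplicated(nodes))
    stop("two populations snap to the same raster cell; refine the grid")
  R <- .effectiveResistance(L, nodes)
  dimnames(R) <- list(popTable$pop, popTable$pop)
  PairwiseMatrix(R, kind = "geographic-cd")
}
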