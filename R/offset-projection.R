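#' Average climate stacks across global circulation models
#'
#' Cellwise arithmetic mean of each layer across stacks of identical
#' geometry and layer sets; nodata propagates (a cell that is nodata in any
#' input is nodata in the mean).
#'
#' @param stacks list of [ClimateStack-class] objects
#' @return a [ClimateStack-class]
#' @export
averageGCMs <- function(stacks) {
  if (length(stacks) < 1) stop("at least one stack required")
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(names(s@layers), names(ref@layers)))
      stop("stacks differ in layer sets")
    g1 <- ref@layers[[1]]; g2 <- s@layers[[1]]
    if (!identical(dim(g1@values), dim(g2@values)) ||
        g1@cellsize != g2@cellsize || g1@xll != g2@xll || g1@yll != g2@yll)
      stop("stacks differ in grid geometry")
  }
  layers <- lapply(names(ref@layers), function(nm) {
    vals <- lapply(stacks, function(s) s@layers[[nm]]@values)
    mean_ <- Reduce(`+`, vals) / length(vals)   # NA propagates
    r <- ref@layers[[nm]]
    GridRaster(mean_, xll = r@xll, yll = r@yll, cellsize = r@cellsize)
  })
  names(layers) <- names(ref@layers)
  ClimateStack(layers, scenario = ref@scenario)
}

#' Project a fitted GDM onto current and future climate: genomic offset
#'
#' For every raster cell the offset is the model-predicted dissimilarity
#' between current and future conditions at the same location:
#' offset = 1 - exp(-sum_k |f_k(x_k^future) - f_k(x_k^current)|) over the
#' model's climate predictors. The geographic-distance term contributes
#' nothing (location is unchanged). Future values beyond the fitted knot
#' range use flat spline extension; the number of such cells is reported as
#' an attribute. The raw eta-scale displacement is returned as a companion
#' layer.
#'
#' @param model a [GDMModel-class]
#' @param current,future [ClimateStack-class] objects whose layer names
#'   cover every non-geographic predictor of the model
#' @return list with `offset` (dissimilarity-scale [GridRaster-class]),
#'   `eta` (raw-scale layer) and `nExtrapolated` (cell count beyond knot
#'   span)
#' @export
genomicOffset <- function(model, current, future) {
  preds <- setdiff(model@predictors, "geographic")
  missing <- setdiff(preds, names(current@layers))
  if (length(missing))
    stop("predictor missing from current stack: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(preds, names(future@layers))
  if (length(missing))
    stop("predictor missing from future stack: ",
         paste(missing, collapse = ", "))
  ref <- current@layers[[1]]
  eta <- matrix(0, nrow(ref@values), ncol(ref@values))
  nodata <- matrix(FALSE, nrow(eta), ncol(eta))
  nExtra <- 0L
  for (v in preds) {
    cur <- current@layers[[v]]@values
    fut <- future@layers[[v]]@values
    nodata <- nodata | is.na(cur) | is.na(fut)
    kn <- model@knots[[v]]
    nExtra <- nExtra + sum(fut < kn[1] | fut > kn[3], na.rm = TRUE)
    fc <- gdmPartial(model, v, as.vector(cur))
    ff <- gdmPartial(model, v, as.vector(fut))
    dd <- abs(ff - fc)
    dd[is.na(dd)] <- 0
    eta <- eta + matrix(dd, nrow(eta), ncol(eta))
  }
  eta[nodata] <- NA
  off <- 1 - exp(-eta)
  list(offset = GridRaster(off, xll = ref@xll, yll = ref@yll,
                           cellsize = ref@cellsize),
       eta = GridRaster(eta, xll = ref@xll, yll = ref@yll,
                        cellsize = ref@cellsize),
       nExtrapolated = nExtra)
}

#' Genomic offset at population locations
#'
#' Extracts the offset layer at population coordinates.
#'
#' @param offsetRaster the `offset` layer from [genomicOffset()]
#' @param popTable data.frame with `pop`, `x`, `y`
#' @return data.frame with `pop`, `offset`
#' @export
populationOffsets <- function(offsetRaster, popTable) {
  data.frame(pop = popTable$pop,
             offset = extractAt(offsetRaster, popTable$x, popTable$y))
}
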