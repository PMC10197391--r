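#' Read an ESRI ASCII grid raster
#'
#' Parses the plain-text ESRI ASCII grid format (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header followed by whitespace-separated
#' cell values, northern row first).
#'
#' @param path file path
#' @return a [GridRaster-class]; nodata cells become `NA`
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (grepl("^\\s*[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has wrong cell count")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  GridRaster(m, xll = xll, yll = yll, cellsize = hdr$cellsize)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a [GridRaster-class]
#' @param path output file path
#' @param nodata nodata sentinel written for `NA` cells (default -9999)
#' @return invisibly, the path
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- raster@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", raster@xll),
           sprintf("yllcorner %.10g", raster@yll),
           sprintf("cellsize %.10g", raster@cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# x/y map coordinates of every cell center; row 1 is the top (northern) row
.cellCenters <- function(raster) {
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  cs <- raster@cellsize
  x <- raster@xll + (seq_len(nc) - 0.5) * cs
  y <- raster@yll + (nr - seq_len(nr) + 0.5) * cs
  list(x = x, y = y)
}

# map coordinates -> (row, col); clamped to the grid
.coordToCell <- function(raster, x, y) {
  nr <- nrow(raster@values); nc <- ncol(raster@values)
  cs <- raster@cellsize
  col <- pmin(pmax(ceiling((x - raster@xll) / cs), 1L), nc)
  row <- pmin(pmax(nr - ceiling((y - raster@yll) / cs) + 1L, 1L), nr)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' Nearest-cell extraction; points outside the extent take the nearest edge
#' cell.
#'
#' @param raster a [GridRaster-class]
#' @param x,y numeric coordinate vectors in map units
#' @return numeric vector of cell values (`NA` where the cell is nodata)
#' @export
extractAt <- function(raster, x, y) {
  rc <- .coordToCell(raster, x, y)
  raster@values[cbind(rc[, 1], rc[, 2])]
}

# separable Gaussian blur with edge renormalization (kernel mass that falls
# off the grid is redistributed, so a constant field stays constant)
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      idx <- seq_len(n) + off
      idx <- pmin(pmax(idx, 1L), n) # replicate edges
      out <- out + k[j] * v[idx]
    }
    out
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(m2, 1, smooth1))
}
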