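#' Create a RasterGrid
#'
#' @param values numeric matrix (row 1 = northern edge); NA marks missing cells
#' @param cellSize cell edge length in meters
#' @param origin map x/y of the upper-left grid corner
#' @param crs coordinate reference identifier (free-form)
#' @param nodata sentinel written for missing cells on disk
#' @return a \linkS4class{RasterGrid}
#' @export
rasterGrid <- function(values, cellSize = 1, origin = c(0, 0),
                       crs = "local", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = cellSize,
      origin = as.numeric(origin), crs = crs, nodata = nodata)
}

#' @describeIn rasterGrid cell values matrix
#' @param x a RasterGrid
#' @export
gridValues <- function(x) x@values

#' @describeIn rasterGrid cell size in meters
#' @export
cellSize <- function(x) x@cellSize

#' @describeIn rasterGrid upper-left corner map coordinates
#' @export
gridOrigin <- function(x) x@origin

#' @describeIn rasterGrid nodata sentinel
#' @export
nodataValue <- function(x) x@nodata

#' Replace the values of a grid, keeping its geometry
#'
#' @param x a RasterGrid
#' @param values replacement matrix with identical dimensions
#' @return a RasterGrid
#' @export
withValues <- function(x, values) {
  stopifnot(all(dim(values) == dim(x@values)))
  v <- as.matrix(values); storage.mode(v) <- "double"
  initialize(x, values = v)
}

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells, cell %g m, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), object@cellSize, object@origin[1],
              object@origin[2], object@crs))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%g, %g], %d missing\n", min(fin), max(fin),
                sum(is.na(v))))
  else cat("  all cells missing\n")
})

setMethod("dim", "RasterGrid", function(x) dim(x@values))

#' Do two grids share geometry?
#'
#' Same dimensions, cell size and origin (coordinates compared with a
#' micrometer tolerance).
#'
#' @param a,b RasterGrid objects
#' @return logical
#' @export
sameGeometry <- function(a, b) {
  isTRUE(all(dim(a@values) == dim(b@values))) &&
    isTRUE(abs(a@cellSize - b@cellSize) < 1e-6) &&
    isTRUE(all(abs(a@origin - b@origin) < 1e-6))
}

stopIfGeometryMismatch <- function(a, b, what = "grids") {
  if (!sameGeometry(a, b))
    stop(sprintf("geometry mismatch between %s", what), call. = FALSE)
  invisible(TRUE)
}

#' Map coordinates of every cell center
#'
#' @param x a RasterGrid
#' @return list with matrices \code{x} and \code{y} of cell-center coordinates
#' @export
cellCenters <- function(x) {
  nr <- nrow(x@values); nc <- ncol(x@values); cs <- x@cellSize
  cx <- x@origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- x@origin[2] - (seq_len(nr) - 0.5) * cs
  list(x = matrix(cx, nr, nc, byrow = TRUE), y = matrix(cy, nr, nc))
}

#' Row/column of the cell containing each point
#'
#' Points on a cell boundary belong to the cell below/right of the boundary,
#' except on the grid's outer south/east edge where they snap inside.
#'
#' @param x a RasterGrid
#' @param px,py point map coordinates
#' @return data.frame with columns row, col (NA when outside the grid)
#' @export
cellFromXY <- function(x, px, py) {
  cs <- x@cellSize
  col <- floor((px - x@origin[1]) / cs) + 1
  row <- floor((x@origin[2] - py) / cs) + 1
  nr <- nrow(x@values); nc <- ncol(x@values)
  col[px == x@origin[1] + nc * cs] <- nc
  row[py == x@origin[2] - nr * cs] <- nr
  bad <- row < 1 | row > nr | col < 1 | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @param x a RasterGrid
#' @param px,py point map coordinates
#' @return numeric vector (NA outside the grid or over missing cells)
#' @export
extractAtXY <- function(x, px, py) {
  rc <- cellFromXY(x, px, py)
  out <- rep(NA_real_, length(px))
  ok <- !is.na(rc$row)
  out[ok] <- x@values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Nearest-neighbor resampling onto a target geometry
#'
#' Used to bring the DEM onto the imagery grid. Each target cell takes the
#' value of the source cell containing its center.
#'
#' @param x source RasterGrid
#' @param target RasterGrid whose geometry is adopted
#' @return RasterGrid on the target geometry
#' @export
resampleNearest <- function(x, target) {
  cc <- cellCenters(target)
  vals <- extractAtXY(x, as.vector(cc$x), as.vector(cc$y))
  withValues(target, matrix(vals, nrow(target@values), ncol(target@values)))
}

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text raster interchange. Values are written with full precision
# (%.17g) so double grids round-trip exactly; integer grids are written as
# integers and round-trip bit-exactly.

#' Read a raster from an ESRI ASCII grid file
#'
#' @param path file path (.asc)
#' @param crs coordinate reference identifier to attach
#' @return a \linkS4class{RasterGrid}; cells equal to the file's NODATA value
#'   come back as NA
#' @export
readAsciiGrid <- function(path, crs = "local") {
  if (!file.exists(path))
    stop(sprintf("raster file not found: %s", path), call. = FALSE)
  lines <- readLines(path, n = 6)
  hdr <- list()
  nHdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nHdr <- nHdr + 1
    } else break
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop(sprintf("not an ASCII grid (missing header): %s", path), call. = FALSE)
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    xll <- hdr$xllcorner; yll <- hdr$yllcorner
  } else if (!is.null(hdr$xllcenter)) {
    xll <- hdr$xllcenter - cs / 2; yll <- hdr$yllcenter - cs / 2
  } else stop(sprintf("ASCII grid without corner keys: %s", path), call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = nHdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid %s: expected %d values, found %d",
                 path, nr * nc, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  rasterGrid(m, cellSize = cs, origin = c(xll, yll + nr * cs),
             crs = crs, nodata = nodata)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param x a RasterGrid
#' @param path output file path
#' @return the path, invisibly
#' @export
writeAsciiGrid <- function(x, path) {
  v <- x@values
  nr <- nrow(v); nc <- ncol(v); cs <- x@cellSize
  out <- v
  out[is.na(out)] <- x@nodata
  intLike <- all(out == round(out))
  fmt <- function(row) {
    if (intLike) paste(formatC(row, format = "d"), collapse = " ")
    else paste(formatC(row, format = "g", digits = 17), collapse = " ")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nc),
               sprintf("nrows %d", nr),
               sprintf("xllcorner %.10f", x@origin[1]),
               sprintf("yllcorner %.10f", x@origin[2] - nr * cs),
               sprintf("cellsize %.10f", cs),
               sprintf("NODATA_value %s",
                       formatC(x@nodata, format = if (x@nodata == round(x@nodata)) "d" else "g",
                               digits = 17))), con)
  writeLines(vapply(seq_len(nr), function(i) fmt(out[i, ]), character(1)), con)
  invisible(path)
}
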