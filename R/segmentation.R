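#' Create segmentation parameters
#'
#' Defaults follow the published object-based winter-crop workflow: scale 100,
#' shape 0.1, compactness 0.1, equal weights on green/red/NIR with the blue
#' band excluded (haze-prone).
#'
#' @param scale scale parameter; a merge is admissible iff fusion cost < scale^2
#' @param shapeWeight weight of shape heterogeneity, in [0, 1)
#' @param compactness compactness vs smoothness weight within the shape term
#' @param bandWeights named non-negative band weights
#' @param valueScale reflectance multiplier applied before merging (default
#'   10000, the integer scaling convention of surface-reflectance products)
#' @return a \linkS4class{SegmentationParams}
#' @export
segmentationParams <- function(scale = 100, shapeWeight = 0.1,
                               compactness = 0.1,
                               bandWeights = c(green = 1, red = 1, nir = 1),
                               valueScale = 10000) {
  new("SegmentationParams", scale = scale, shapeWeight = shapeWeight,
      compactness = compactness, bandWeights = bandWeights,
      valueScale = valueScale)
}

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf("SegmentationParams: scale %g, shape %g, compactness %g, bands %s (x%g)\n",
              object@scale, object@shapeWeight, object@compactness,
              paste(sprintf("%s=%g", names(object@bandWeights),
                            object@bandWeights), collapse = ","),
              object@valueScale))
})

#' Multiresolution region-merging segmentation
#'
#' Partitions one scene into spectrally homogeneous objects by iterative
#' pairwise region merging, starting from single-cell objects. A candidate
#' merge's fusion cost combines the growth in spectral heterogeneity
#' (cell-count-weighted band standard deviations) and in shape heterogeneity
#' (compactness l/sqrt(n) and smoothness l/b, with l the perimeter and b the
#' bounding-box perimeter); merging is globally cheapest-pair first (mutual
#' best fitting; ties to the lowest id pair in row-major order) and stops when
#' the cheapest admissible cost reaches scale^2. The run is deterministic;
#' \code{seed} is reserved for randomized start orderings and unused by the
#' default ordering.
#'
#' @param stack a reflectance \linkS4class{BandStack}
#' @param params a \linkS4class{SegmentationParams}
#' @param seed unused by the deterministic default ordering
#' @return a \linkS4class{SegmentLayer} with per-segment cell counts,
#'   perimeters (m), centroids and per-band mean/sd
#' @export
multiresolutionSegment <- function(stack, params = segmentationParams(),
                                   seed = NULL) {
  roles <- names(params@bandWeights)[params@bandWeights > 0]
  miss <- setdiff(roles, bandRoles(stack))
  if (length(miss))
    stop(sprintf("band(s) %s named in band weights but missing from the stack",
                 paste(miss, collapse = ", ")), call. = FALSE)
  grids <- lapply(roles, function(r) getBand(stack, r))
  ref <- grids[[1]]
  nr <- nrow(ref@values); nc <- ncol(ref@values)
  arr <- array(NA_real_, c(nr, nc, length(roles)))
  for (i in seq_along(grids)) arr[, , i] <- grids[[i]]@values * params@valueScale
  valid <- apply(!is.na(arr), c(1, 2), all)
  labels <- .mrsSegment(arr, valid, unname(params@bandWeights[roles]),
                        params@scale, params@shapeWeight, params@compactness)
  labGrid <- withValues(ref, labels)
  tab <- segmentTable(labGrid, stack, roles)
  new("SegmentLayer", labels = labGrid, table = tab, params = params)
}

# per-segment zonal table: n, perimeter (m), centroid, band mean/sd
segmentTable <- function(labGrid, stack, roles) {
  lab <- labGrid@values
  ids <- sort(unique(as.vector(lab[!is.na(lab)])))
  k <- length(ids)
  if (k == 0)
    return(data.frame(id = integer(), n = integer(), perimeter = numeric(),
                      centroidX = numeric(), centroidY = numeric(),
                      masked = logical(), class = character()))
  f <- factor(as.vector(lab), levels = ids)
  n <- as.integer(table(f))
  cc <- cellCenters(labGrid)
  cx <- tapply(as.vector(cc$x), f, mean)
  cy <- tapply(as.vector(cc$y), f, mean)
  tab <- data.frame(id = ids, n = n, perimeter = segmentPerimeters(lab, ids) *
                      labGrid@cellSize, centroidX = as.numeric(cx),
                    centroidY = as.numeric(cy))
  for (r in roles) {
    v <- as.vector(getBand(stack, r)@values)
    tab[[paste0("mean_", r)]] <- as.numeric(tapply(v, f, mean, na.rm = TRUE))
    sdPop <- function(x) { x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      sqrt(max(0, mean(x^2) - mean(x)^2)) }
    tab[[paste0("sd_", r)]] <- as.numeric(tapply(v, f, sdPop))
  }
  tab$masked <- FALSE
  tab$class <- NA_character_
  tab
}

# boundary edge counts per label, in cell-edge units
segmentPerimeters <- function(lab, ids) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(NA_integer_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  edges <- matrix(0L, nr, nc)
  for (sh in list(pad[1:nr, 2:(nc + 1)], pad[3:(nr + 2), 2:(nc + 1)],
                  pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)])) {
    diffEdge <- !is.na(ctr) & (is.na(sh) | sh != ctr)
    edges <- edges + diffEdge
  }
  f <- factor(as.vector(ctr), levels = ids)
  as.numeric(tapply(as.vector(edges), f, sum))
}

#' Attach zonal means of named grids to a segment layer
#'
#' Per segment, the cell-count-weighted mean of each grid over the segment's
#' cells, ignoring missing cells; segments with no valid cell for a grid get
#' NA. Grid names become columns \code{mean<Name>}; the names
#' \code{ndviDiff} and \code{slope} feed \code{\link{classifyPeriod}}.
#'
#' @param layer a \linkS4class{SegmentLayer}
#' @param grids named list of \linkS4class{RasterGrid} sharing the layer's
#'   geometry
#' @return the layer with extra attribute columns
#' @export
zonalAttributes <- function(layer, grids) {
  lab <- layer@labels@values
  f <- factor(as.vector(lab), levels = layer@table$id)
  for (nm in names(grids)) {
    stopIfGeometryMismatch(layer@labels, grids[[nm]],
                           sprintf("segments and grid '%s'", nm))
    v <- as.vector(grids[[nm]]@values)
    m <- tapply(v, f, function(x) if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE))
    col <- paste0("mean", toupper(substring(nm, 1, 1)), substring(nm, 2))
    layer@table[[col]] <- as.numeric(m)
  }
  layer
}

#' Mask segments whose centroid falls in a water body
#'
#' The centroid is the segment's area centroid (which may lie outside the
#' segment itself); a segment is masked iff that point is inside any water
#' polygon. Masked segments are excluded from classification and area
#' accounting.
#'
#' @param layer a \linkS4class{SegmentLayer}
#' @param water list of water-body polygons (two-column x/y coordinate
#'   matrices, closed or open rings)
#' @return the layer with the masked flag set
#' @export
maskWater <- function(layer, water) {
  if (!length(water)) return(layer)
  for (i in seq_along(water)) {
    if (polygonSelfIntersects(water[[i]]))
      stop(sprintf("water polygon %d is self-intersecting", i), call. = FALSE)
  }
  inAny <- rep(FALSE, nrow(layer@table))
  for (poly in water)
    inAny <- inAny | pointInPolygon(layer@table$centroidX,
                                    layer@table$centroidY, poly)
  layer@table$masked <- layer@table$masked | inAny
  layer
}

setMethod("show", "SegmentLayer", function(object) {
  cat(sprintf("SegmentLayer: %d segments over %d cells (%d masked)\n",
              nrow(object@table), sum(object@table$n),
              sum(object@table$masked)))
})

# ---- plain geometry helpers ---------------------------------------------

#' Even-odd point-in-polygon test
#'
#' @param px,py point coordinates
#' @param poly two-column coordinate matrix (ring; closure optional)
#' @return logical vector
#' @export
pointInPolygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

segIntersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# proper (crossing) self-intersection between non-adjacent edges
polygonSelfIntersects <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (segIntersects(c(x[i], y[i]), c(x[i + 1], y[i + 1]),
                        c(x[j], y[j]), c(x[j %% n + 1], y[j %% n + 1])))
        return(TRUE)
    }
  }
  FALSE
}
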